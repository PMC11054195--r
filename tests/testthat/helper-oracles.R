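# Independent straight-line oracles used across the suite. These mirror
# the mathematical definitions with explicit loops and are kept free of
# any package internals beyond plain parameter access.

sig_ref <- function(x) 1 / (1 + exp(-x))

# five-equation LSTM step, scalar loops only
lstm_step_ref <- function(x, h_prev, c_prev, cell) {
  u <- nrow(cell$Wh)
  a <- numeric(4 * u)
  for (j in seq_len(4 * u)) {
    s <- cell$b[j]
    for (i in seq_along(x)) s <- s + x[i] * cell$Wx[i, j]
    for (i in seq_len(u)) s <- s + h_prev[i] * cell$Wh[i, j]
    a[j] <- s
  }
  ig <- sig_ref(a[1:u])
  fg <- sig_ref(a[(u + 1):(2 * u)])
  g <- tanh(a[(2 * u + 1):(3 * u)])
  og <- sig_ref(a[(3 * u + 1):(4 * u)])
  cc <- fg * c_prev + ig * g
  list(h = og * tanh(cc), c = cc)
}

# brute-force loss terms
diversity_ref <- function(P, threshold = 1) {
  K <- nrow(P)
  if (K < 2) return(0)
  m <- Inf
  for (i in seq_len(K - 1)) for (j in (i + 1):K)
    m <- min(m, sum((P[i, ] - P[j, ])^2))
  sig_ref(threshold - m)
}

r1_ref <- function(P, E) {
  out <- 0
  for (k in seq_len(nrow(P))) {
    best <- Inf
    for (j in seq_len(nrow(E))) best <- min(best, sum((P[k, ] - E[j, ])^2))
    out <- out + best
  }
  out
}

r2_ref <- function(P, E) {
  out <- 0
  for (j in seq_len(nrow(E))) {
    best <- Inf
    for (k in seq_len(nrow(P))) best <- min(best, sum((E[j, ] - P[k, ])^2))
    out <- out + best
  }
  out
}

# exhaustive nearest-exemplar scan: for each prototype row the index of
# the nearest embedding row (lowest index on ties) and that distance
project_ref <- function(P, E) {
  K <- nrow(P)
  idx <- integer(K); dd <- numeric(K)
  for (k in seq_len(K)) {
    best <- Inf; bi <- NA_integer_
    for (j in seq_len(nrow(E))) {
      d <- sqrt(sum((P[k, ] - E[j, ])^2))
      if (d < best) { best <- d; bi <- j }
    }
    idx[k] <- bi; dd[k] <- best
  }
  list(index = idx, distance = dd)
}

filter_ref <- function(E, P, dmin) {
  keep <- integer(0)
  for (j in seq_len(nrow(E))) {
    m <- Inf
    for (k in seq_len(nrow(P))) m <- min(m, sqrt(sum((E[j, ] - P[k, ])^2)))
    if (m >= dmin) keep <- c(keep, j)
  }
  keep
}

# small random model + batch factory for oracle and contract tests
toy_model <- function(seed = 1, C = 2, K = 3, L = 40, T_ = 4,
                      layers = 2, hidden = 3, d_alpha = 4, dropout = 0,
                      classes = NULL) {
  if (is.null(classes)) classes <- c("N", "A", "O")[seq_len(C)]
  proto_model(input_length = L, n_steps = T_, hidden_size = hidden,
              num_layers = layers, d_alpha = d_alpha, n_prototypes = K,
              classes = classes, dropout = dropout, seed = seed)
}

toy_batch <- function(seed, B = 5, L = 40, C = 2) {
  set.seed(seed)
  list(X = matrix(rnorm(B * L), B, L), y = sample(0:(C - 1), B, TRUE))
}

# central finite-difference gradient of the total loss wrt sampled
# coordinates of every parameter array
fd_check <- function(model, X, y, weights, eps = 1e-4, per_array = 4) {
  lg <- protobeat:::model_loss_grads(model, X, y, weights)
  params <- protobeat:::param_list(model)
  loss_at <- function(p) {
    m2 <- protobeat:::set_param_list(model, p)
    protobeat:::model_loss_grads(m2, X, y, weights)$breakdown$total
  }
  worst <- 0
  for (nm in names(params)) {
    n <- length(params[[nm]])
    for (i in unique(round(seq(1, n, length.out = min(per_array, n))))) {
      p1 <- params; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] - eps
      fd <- (loss_at(p1) - loss_at(p2)) / (2 * eps)
      an <- lg$grads[[nm]][i]
      worst <- max(worst, abs(fd - an) / max(1e-6, abs(fd) + abs(an)))
    }
  }
  worst
}
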