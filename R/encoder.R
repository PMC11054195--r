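#' Split a series into equal-length frames
#'
#' Splits a raw signal of length `L` into `T` contiguous frames of width
#' `n = floor(L / T)`; any trailing remainder samples are dropped so all
#' frames are homogeneous. Concatenating the frame rows reproduces the first
#' `T * n` input samples in order.
#'
#' @param series numeric vector (one beat).
#' @param n_steps number of frames `T`.
#' @return numeric matrix with `T` rows (frames) and `n` columns.
#' @export
segment_series <- function(series, n_steps) {
  series <- as.numeric(series)
  L <- length(series)
  n_steps <- as.integer(n_steps)
  if (n_steps < 1L || n_steps > L)
    stop_invalid("segment_series: cannot cut %d samples into %d frames",
                 L, n_steps)
  n <- L %/% n_steps
  matrix(series[seq_len(n_steps * n)], nrow = n_steps, ncol = n, byrow = TRUE)
}

# one LSTM cell: packed weights, gate column blocks ordered [i | f | g | o]
lstm_cell <- function(input_size, hidden_size) {
  u <- hidden_size
  init <- function(nr, nc, fan_in) {
    matrix(stats::runif(nr * nc, -1, 1) / sqrt(fan_in), nr, nc)
  }
  list(Wx = init(input_size, 4L * u, input_size),
       Wh = init(u, 4L * u, u),
       b = stats::runif(4L * u, -1, 1) / sqrt(u))
}

#' Construct encoder parameters
#'
#' A stacked (optionally bidirectional) LSTM. Layer 1 consumes frames of
#' width `input_size`; each further layer consumes the per-step output of
#' the previous layer (forward and backward states concatenated when
#' bidirectional, so the per-step state width is `u = 2 * hidden_size`).
#' Weights are initialized uniformly in `+-1/sqrt(fan-in)` from the seeded
#' stream.
#'
#' @param input_size frame width `n`.
#' @param hidden_size hidden units per direction; default 16.
#' @param num_layers stacked layers; default 3.
#' @param bidirectional run both temporal directions; default TRUE.
#' @param seed integer seed for initialization.
#' @return list of class `encoder_params`.
#' @export
encoder_params <- function(input_size, hidden_size = 16L, num_layers = 3L,
                           bidirectional = TRUE, seed = 1L) {
  stopifnot(input_size >= 1L, hidden_size >= 1L, num_layers >= 1L)
  with_seed(seed, {
    layers <- vector("list", num_layers)
    in_size <- input_size
    out_size <- hidden_size * (1L + bidirectional)
    for (l in seq_len(num_layers)) {
      layers[[l]] <- list(fwd = lstm_cell(in_size, hidden_size),
                          bwd = if (bidirectional)
                            lstm_cell(in_size, hidden_size))
      in_size <- out_size
    }
    structure(list(layers = layers, input_size = as.integer(input_size),
                   hidden_size = as.integer(hidden_size),
                   num_layers = as.integer(num_layers),
                   bidirectional = isTRUE(bidirectional),
                   output_size = as.integer(out_size)),
              class = "encoder_params")
  })
}

#' One LSTM recurrence step
#'
#' Computes the input, forget and output gates as sigmoids of affine maps of
#' `(x_t, h_prev)`, the candidate as a tanh of an affine map, then
#' `c_t = fg * c_prev + ig * g` and `h_t = og * tanh(c_t)`. Accepts a single
#' step as vectors or a batch as matrices (one row per sequence).
#'
#' @param x_t input frame, length-`n` vector or `B x n` matrix.
#' @param h_prev,c_prev previous hidden and cell state, length-`u` vectors
#'   or `B x u` matrices.
#' @param cell a cell from [encoder_params()] (`Wx`, `Wh`, `b`).
#' @return list with `h` and `c`, shaped like `h_prev`.
#' @export
lstm_step <- function(x_t, h_prev, c_prev, cell) {
  vec_in <- is.null(dim(x_t))
  X <- if (vec_in) matrix(x_t, nrow = 1L) else as.matrix(x_t)
  H <- if (is.null(dim(h_prev))) matrix(h_prev, nrow = 1L) else as.matrix(h_prev)
  Cp <- if (is.null(dim(c_prev))) matrix(c_prev, nrow = 1L) else as.matrix(c_prev)
  u <- nrow(cell$Wh)
  if (ncol(X) != nrow(cell$Wx) || ncol(H) != u || ncol(Cp) != u)
    stop_invalid("lstm_step: shape mismatch (x %d vs Wx %d, h %d vs u %d)",
                 ncol(X), nrow(cell$Wx), ncol(H), u)
  A <- X %*% cell$Wx + H %*% cell$Wh
  A <- sweep(A, 2L, cell$b, `+`)
  ig <- sigmoid(A[, 1:u, drop = FALSE])
  fg <- sigmoid(A[, (u + 1):(2 * u), drop = FALSE])
  g <- tanh(A[, (2 * u + 1):(3 * u), drop = FALSE])
  og <- sigmoid(A[, (3 * u + 1):(4 * u), drop = FALSE])
  cc <- fg * Cp + ig * g
  hh <- og * tanh(cc)
  if (vec_in) list(h = drop(hh), c = drop(cc)) else list(h = hh, c = cc)
}

# run one direction over a list of T frame matrices (B x n each); states
# are stored under their original time indices regardless of direction
lstm_run <- function(frames, cell, reverse = FALSE, keep_cache = FALSE) {
  T_ <- length(frames)
  B <- nrow(frames[[1L]])
  u <- nrow(cell$Wh)
  h <- matrix(0, B, u)
  cst <- matrix(0, B, u)
  H <- vector("list", T_)
  cache <- if (keep_cache)
    list(i = vector("list", T_), f = vector("list", T_),
         g = vector("list", T_), o = vector("list", T_),
         c = vector("list", T_), tc = vector("list", T_))
  steps <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  for (t in steps) {
    A <- frames[[t]] %*% cell$Wx + h %*% cell$Wh
    A <- sweep(A, 2L, cell$b, `+`)
    ig <- sigmoid(A[, 1:u, drop = FALSE])
    fg <- sigmoid(A[, (u + 1):(2 * u), drop = FALSE])
    g <- tanh(A[, (2 * u + 1):(3 * u), drop = FALSE])
    og <- sigmoid(A[, (3 * u + 1):(4 * u), drop = FALSE])
    cst <- fg * cst + ig * g
    tc <- tanh(cst)
    h <- og * tc
    if (any(!is.finite(h)))
      stop_invalid("encoder: non-finite hidden state at step %d", t)
    H[[t]] <- h
    if (keep_cache) {
      cache$i[[t]] <- ig; cache$f[[t]] <- fg; cache$g[[t]] <- g
      cache$o[[t]] <- og; cache$c[[t]] <- cst; cache$tc[[t]] <- tc
    }
  }
  list(H = H, final_c = cst, cache = cache)
}

# full stacked/bidirectional forward over a batch; frames is a list of T
# matrices (B x n). Returns top-layer per-step states and optional caches.
encoder_run <- function(enc, frames, keep_cache = FALSE) {
  T_ <- length(frames)
  inputs <- frames
  layer_caches <- vector("list", enc$num_layers)
  final_cells <- vector("list", enc$num_layers)
  for (l in seq_len(enc$num_layers)) {
    lay <- enc$layers[[l]]
    fw <- lstm_run(inputs, lay$fwd, reverse = FALSE, keep_cache = keep_cache)
    if (enc$bidirectional) {
      bw <- lstm_run(inputs, lay$bwd, reverse = TRUE, keep_cache = keep_cache)
      out <- lapply(seq_len(T_), function(t) cbind(fw$H[[t]], bw$H[[t]]))
    } else {
      bw <- NULL
      out <- fw$H
    }
    layer_caches[[l]] <- list(fwd = fw, bwd = bw, input = inputs)
    final_cells[[l]] <- list(fwd = fw$final_c, bwd = if (!is.null(bw)) bw$final_c)
    inputs <- out
  }
  list(H = inputs, caches = if (keep_cache) layer_caches,
       final_cells = final_cells)
}

#' Encode a framed series into per-step hidden states
#'
#' Runs the stacked (bi)directional recurrence over the `T` frames of one
#' series and returns the top layer's per-step states. With a bidirectional
#' encoder the forward and backward states are concatenated, so the state
#' width is `u = 2 * hidden_size`. Deterministic given parameters and input.
#'
#' @param frames `T x n` frame matrix from [segment_series()].
#' @param enc an [encoder_params()] object.
#' @return object of class `hidden_states`: list with `H` (`T x u` matrix)
#'   and `final_cells` (per layer and direction).
#' @export
encode <- function(frames, enc) {
  stopifnot(inherits(enc, "encoder_params"))
  frames <- as.matrix(frames)
  if (ncol(frames) != enc$input_size)
    stop_invalid("encode: frame width %d but encoder expects %d",
                 ncol(frames), enc$input_size)
  flist <- lapply(seq_len(nrow(frames)),
                  function(t) frames[t, , drop = FALSE])
  run <- encoder_run(enc, flist)
  H <- do.call(rbind, run$H)
  structure(list(H = H, final_cells = run$final_cells),
            class = "hidden_states")
}

#' Construct attention parameters
#'
#' Additive attention with a `u x D_alpha` first-layer matrix, a `D_alpha`
#' bias and a `D_alpha`-vector second layer. Initialized uniformly in
#' `+-1/sqrt(fan-in)` from the seeded stream.
#'
#' @param u per-step hidden-state width.
#' @param d_alpha attention hidden width; default 16.
#' @param seed integer seed.
#' @param score_tanh insert a tanh between the two attention layers
#'   (conventional additive-attention form); default FALSE, i.e. the score
#'   is the plain bilinear form `V' (W' h + b)`.
#' @return list of class `attention_params`.
#' @export
attention_params <- function(u, d_alpha = 16L, seed = 1L, score_tanh = FALSE) {
  stopifnot(u >= 1L, d_alpha >= 1L)
  with_seed(seed, {
    structure(list(
      W = matrix(stats::runif(u * d_alpha, -1, 1) / sqrt(u), u, d_alpha),
      b = stats::runif(d_alpha, -1, 1) / sqrt(d_alpha),
      V = stats::runif(d_alpha, -1, 1) / sqrt(d_alpha),
      d_alpha = as.integer(d_alpha), score_tanh = isTRUE(score_tanh)),
      class = "attention_params")
  })
}

# batched attention over a list of T state matrices (B x u); returns
# alpha (B x T), e (B x u) and the pre-activations needed for backprop
attend_batch <- function(H, att, keep_cache = FALSE) {
  T_ <- length(H)
  B <- nrow(H[[1L]])
  scores <- matrix(0, B, T_)
  pre <- if (keep_cache) vector("list", T_)
  for (t in seq_len(T_)) {
    P <- sweep(H[[t]] %*% att$W, 2L, att$b, `+`)
    if (att$score_tanh) P <- tanh(P)
    scores[, t] <- P %*% att$V
    if (keep_cache) pre[[t]] <- P
  }
  alpha <- softmax_rows(scores)
  u <- ncol(H[[1L]])
  e <- matrix(0, B, u)
  for (t in seq_len(T_)) e <- e + alpha[, t] * H[[t]]
  list(alpha = alpha, e = e, pre = pre)
}

#' Attention-pool hidden states into a fixed-length embedding
#'
#' Scores each per-step state as `V' (W' h_t + b)`, normalizes the `T`
#' scores with a softmax into weights `alpha`, and returns the weighted sum
#' `e = sum_t alpha_t h_t`. The weights are nonnegative and sum to one, so
#' `e` is a convex combination of the per-step states.
#'
#' @param hidden a `hidden_states` object from [encode()], or a `T x u`
#'   matrix of per-step states.
#' @param att an [attention_params()] object.
#' @return object of class `pooled_embedding`: list with `alpha` (length-`T`
#'   weights) and `e` (length-`u` embedding).
#' @export
attend <- function(hidden, att) {
  stopifnot(inherits(att, "attention_params"))
  H <- if (inherits(hidden, "hidden_states")) hidden$H else as.matrix(hidden)
  if (nrow(H) == 0L)
    stop_invalid("attend: no time steps to pool")
  if (ncol(H) != nrow(att$W))
    stop_invalid("attend: state width %d but attention expects %d",
                 ncol(H), nrow(att$W))
  Hl <- lapply(seq_len(nrow(H)), function(t) H[t, , drop = FALSE])
  out <- attend_batch(Hl, att)
  structure(list(alpha = drop(out$alpha), e = drop(out$e)),
            class = "pooled_embedding")
}
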