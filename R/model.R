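#' Construct a prototype classification model
#'
#' Assembles the full model: a stacked bidirectional LSTM encoder with
#' attention pooling, a set of `K` trainable prototype vectors living in the
#' encoder's latent space, and a `C x K` linear head that classifies from
#' the vector of prototype similarities. Defaults follow the reference
#' configuration: 3 encoder layers of 16 hidden units per direction,
#' bidirectional (so the latent width is `u = 32`), dropout 0.1 on the
#' pooled embedding, `K = 12` prototypes for `C = 3` classes.
#'
#' @param input_length raw beat length in samples; default 180.
#' @param n_steps number of frames `T` the beat is cut into; default 18
#'   (10-sample frames, about 33 ms at 300 Hz).
#' @param hidden_size,num_layers,bidirectional encoder shape, see
#'   [encoder_params()].
#' @param d_alpha attention hidden width.
#' @param n_prototypes number of prototypes `K`.
#' @param classes character vector of class names (its length sets `C`);
#'   default `c("N", "A", "O")`.
#' @param dropout dropout rate applied to the pooled embedding during
#'   training, before the prototype layer and head.
#' @param dist_squared use squared L2 embedding-prototype distances in the
#'   similarity (default FALSE: plain L2).
#' @param score_tanh see [attention_params()].
#' @param seed integer seed for parameter initialization.
#' @return object of class `proto_model`.
#' @export
proto_model <- function(input_length = 180L, n_steps = 18L, hidden_size = 16L,
                        num_layers = 3L, bidirectional = TRUE, d_alpha = 16L,
                        n_prototypes = 12L, classes = c("N", "A", "O"),
                        dropout = 0.1, dist_squared = FALSE,
                        score_tanh = FALSE, seed = 1L) {
  stopifnot(input_length >= n_steps, n_prototypes >= 1L, length(classes) >= 2L,
            dropout >= 0, dropout < 1)
  n <- input_length %/% n_steps
  enc <- encoder_params(n, hidden_size, num_layers, bidirectional,
                        seed = derive_seed(seed, "encoder"))
  u <- enc$output_size
  att <- attention_params(u, d_alpha, seed = derive_seed(seed, "attention"),
                          score_tanh = score_tanh)
  K <- as.integer(n_prototypes)
  C <- length(classes)
  pw <- with_seed(derive_seed(seed, "prototypes"), {
    list(P = matrix(stats::runif(K * u, -1, 1) / sqrt(u), K, u),
         W = matrix(stats::runif(C * K, -1, 1) / sqrt(K), C, K))
  })
  structure(list(
    encoder = enc, attention = att,
    prototypes = pw$P,
    proto_meta = new_proto_meta(K),
    W = pw$W,
    config = list(input_length = as.integer(input_length),
                  n_steps = as.integer(n_steps), frame_width = as.integer(n),
                  u = u, K = K, C = C, classes = as.character(classes),
                  dropout = dropout, dist_squared = isTRUE(dist_squared),
                  score_tanh = isTRUE(score_tanh), seed = as.integer(seed)),
    edit_log = list()),
    class = "proto_model")
}

new_proto_meta <- function(K, provenance = "learned") {
  data.frame(id = sprintf("p%02d", seq_len(K)),
             provenance = rep(provenance, K),
             validated = rep(FALSE, K),
             frozen = rep(FALSE, K),
             exemplar_id = rep(NA_character_, K),
             stringsAsFactors = FALSE)
}

#' @export
print.proto_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf(paste0(
    "<proto_model> %d-layer %sLSTM(%d) + attention -> u=%d; K=%d prototypes,",
    " %d classes (%s)\n"),
    x$encoder$num_layers, if (x$encoder$bidirectional) "Bi-" else "",
    x$encoder$hidden_size, cf$u, cf$K, cf$C,
    paste(cf$classes, collapse = ",")))
  nval <- sum(x$proto_meta$validated)
  nexp <- sum(x$proto_meta$provenance == "expert")
  cat(sprintf("  prototypes: %d expert-added, %d validated/frozen\n",
              nexp, nval))
  invisible(x)
}

check_model <- function(model) {
  stopifnot(inherits(model, "proto_model"))
  cf <- model$config
  if (nrow(model$prototypes) != ncol(model$W) ||
      nrow(model$prototypes) != cf$K ||
      nrow(model$proto_meta) != cf$K)
    stop_invalid("model invariant violated: K=%d prototypes, %d head columns, %d metadata rows",
                 nrow(model$prototypes), ncol(model$W), nrow(model$proto_meta))
  invisible(model)
}

#' Distances from an embedding to each prototype
#'
#' @param e embedding: length-`u` vector, or `B x u` matrix of embeddings.
#' @param prototypes `K x u` prototype matrix (or a `proto_model`, whose
#'   prototype set is used).
#' @param squared return squared L2 distances instead of plain L2.
#' @return length-`K` vector (or `B x K` matrix) of nonnegative distances.
#' @export
prototype_distances <- function(e, prototypes, squared = FALSE) {
  if (inherits(prototypes, "proto_model")) {
    squared <- prototypes$config$dist_squared
    prototypes <- prototypes$prototypes
  }
  P <- as.matrix(prototypes)
  vec_in <- is.null(dim(e))
  E <- if (vec_in) matrix(e, nrow = 1L) else as.matrix(e)
  if (ncol(E) != ncol(P))
    stop_invalid("prototype_distances: embedding width %d vs prototype width %d",
                 ncol(E), ncol(P))
  D2 <- outer(rowSums(E^2), rep(1, nrow(P))) +
    outer(rep(1, nrow(E)), rowSums(P^2)) - 2 * E %*% t(P)
  D2[D2 < 0] <- 0  # guard tiny negative round-off
  D <- if (squared) D2 else sqrt(D2)
  if (vec_in) drop(D) else D
}

#' Convert distances to similarities
#'
#' `s_k = exp(-d_k)`, mapping distance 0 to similarity 1 and strictly
#' decreasing in the distance, so `s_k` lies in `(0, 1]`.
#'
#' @param d nonnegative distances (vector or matrix).
#' @return similarities with the same shape.
#' @export
similarities <- function(d) {
  if (any(d < 0))
    stop_invalid("similarities: distances must be nonnegative")
  exp(-d)
}

#' Linear classifier head over prototype similarities
#'
#' @param s length-`K` similarity vector, or `B x K` matrix.
#' @param W `C x K` head matrix (or a `proto_model`).
#' @return length-`C` logit vector `z = W s` (or `B x C` matrix).
#' @export
classify <- function(s, W) {
  if (inherits(W, "proto_model")) W <- W$W
  vec_in <- is.null(dim(s))
  S <- if (vec_in) matrix(s, nrow = 1L) else as.matrix(s)
  if (ncol(S) != ncol(W))
    stop_invalid("classify: %d similarities for a head with %d columns",
                 ncol(S), ncol(W))
  Z <- S %*% t(W)
  if (vec_in) drop(Z) else Z
}

# batched forward over raw beats X (B x L); returns everything needed for
# interpretation and, optionally, the caches needed for backprop
model_forward_batch <- function(model, X, keep_cache = FALSE,
                                dropout_mask = NULL) {
  cf <- model$config
  X <- as.matrix(X)
  if (ncol(X) < cf$n_steps)
    stop_invalid("forward: series length %d shorter than T=%d",
                 ncol(X), cf$n_steps)
  n <- ncol(X) %/% cf$n_steps
  if (n != cf$frame_width)
    stop_invalid("forward: series length %d frames to width %d but model expects %d",
                 ncol(X), n, cf$frame_width)
  frames <- lapply(seq_len(cf$n_steps), function(t)
    X[, ((t - 1L) * n + 1L):(t * n), drop = FALSE])
  enc_out <- encoder_run(model$encoder, frames, keep_cache = keep_cache)
  att_out <- attend_batch(enc_out$H, model$attention, keep_cache = keep_cache)
  e <- att_out$e
  if (!is.null(dropout_mask)) e <- e * dropout_mask
  D <- prototype_distances(e, model$prototypes,
                           squared = cf$dist_squared)
  S <- similarities(D)
  Z <- classify(S, model$W)
  probs <- softmax_rows(Z)
  list(z = Z, probs = probs, s = S, d = D, e = e, alpha = att_out$alpha,
       frames = frames, enc_out = enc_out, att_out = att_out)
}

#' Full forward pass on one series
#'
#' Chains framing, encoding, attention pooling, prototype similarity and the
#' linear head, returning all intermediates so a prediction can be
#' explained. Dropout is inactive (inference mode).
#'
#' @param model a [proto_model()].
#' @param series numeric vector (raw beat).
#' @return object of class `proto_prediction`: list with logits `z`, class
#'   probabilities `probs`, zero-based `label`, predicted class name
#'   `class`, similarities `s`, distances `d`, attention weights `alpha` and
#'   embedding `e`.
#' @export
forward <- function(model, series) {
  check_model(model)
  out <- model_forward_batch(model, matrix(as.numeric(series), nrow = 1L))
  label <- which.max(out$z[1L, ]) - 1L
  structure(list(z = drop(out$z), probs = drop(out$probs),
                 label = label, class = model$config$classes[label + 1L],
                 s = drop(out$s), d = drop(out$d),
                 alpha = drop(out$alpha), e = drop(out$e)),
            class = "proto_prediction")
}

#' @export
print.proto_prediction <- function(x, ...) {
  cat(sprintf("<prediction> class %s (p=%.3f); top similarity %.3f\n",
              x$class, max(x$probs), max(x$s)))
  invisible(x)
}

#' Class label owned by each prototype
#'
#' Assigns each prototype the class whose head weight on it is largest
#' (`argmax` over the rows of the prototype's head column). Ties are broken
#' toward the lowest class index; an all-zero column is labeled class 0 and
#' flagged degenerate.
#'
#' @param model a [proto_model()].
#' @return integer vector of `K` zero-based class codes with attribute
#'   `degenerate` (logical vector marking all-zero columns).
#' @export
prototype_class_labels <- function(model) {
  check_model(model)
  W <- model$W
  lab <- apply(W, 2L, which.max) - 1L
  degen <- apply(W, 2L, function(col) all(col == 0))
  lab[degen] <- 0L
  structure(as.integer(lab), degenerate = degen)
}
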