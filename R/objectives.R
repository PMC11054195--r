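#' Loss weights for the composite training objective
#'
#' The total objective is
#' `CE + lambda * R + lambda1 * R1 + lambda2 * R2`, where `CE` is the
#' cross-entropy, `R` the diversity penalty on the minimum pairwise squared
#' prototype distance, `R1` the prototypicality term (each prototype near
#' some encoded instance) and `R2` the clustering term (each instance near
#' some prototype). Defaults are `lambda = 0.01`,
#' `lambda1 = lambda2 = 0.05`, diversity threshold 1.
#'
#' @param lambda diversity weight.
#' @param lambda1 prototypicality weight.
#' @param lambda2 clustering weight.
#' @param diversity_threshold the squared-distance level below which the
#'   diversity penalty exceeds 0.5.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(lambda = 0.01, lambda1 = 0.05, lambda2 = 0.05,
                         diversity_threshold = 1.0) {
  stopifnot(lambda >= 0, lambda1 >= 0, lambda2 >= 0)
  structure(list(lambda = lambda, lambda1 = lambda1, lambda2 = lambda2,
                 diversity_threshold = diversity_threshold),
            class = "loss_weights")
}

#' Diversity loss on a prototype set
#'
#' `R(P) = sigmoid(threshold - min_{i<j} ||p_i - p_j||^2)`: the closer the
#' two closest prototypes, the nearer the penalty is to 1, pushing
#' prototypes to keep a minimum mutual squared distance. With a single
#' prototype no pair exists and the loss is 0 by convention.
#'
#' @param P `K x u` prototype matrix (or a `proto_model`).
#' @param threshold squared-distance threshold; default 1.
#' @return scalar in `[0, 1)`.
#' @export
diversity_loss <- function(P, threshold = 1.0) {
  if (inherits(P, "proto_model")) P <- P$prototypes
  P <- as.matrix(P)
  if (nrow(P) < 2L) return(0)
  m <- min(stats::dist(P))^2
  sigmoid(threshold - m)
}

#' Prototypicality loss
#'
#' `R1(P, E) = sum_k min_j ||p_k - e_j||^2`: every prototype is pulled
#' toward its nearest encoded instance, so prototypes stay representable by
#' real data.
#'
#' @param P `K x u` prototype matrix (or a `proto_model`).
#' @param E `N x u` matrix of encoded instances.
#' @return nonnegative scalar; 0 iff every prototype coincides with some
#'   embedding.
#' @export
prototypicality_loss <- function(P, E) {
  if (inherits(P, "proto_model")) P <- P$prototypes
  E <- as.matrix(E)
  if (nrow(E) < 1L)
    stop_invalid("prototypicality_loss: empty embedding set")
  D2 <- prototype_distances(as.matrix(P), E, squared = TRUE)
  sum(apply(D2, 1L, min))
}

#' Clustering loss
#'
#' `R2(P, E) = sum_j min_k ||e_j - p_k||^2`: the mirror of the
#' prototypicality term, pulling every encoded instance toward its nearest
#' prototype so instances cluster around the prototype set.
#'
#' @inheritParams prototypicality_loss
#' @return nonnegative scalar; 0 iff every embedding coincides with some
#'   prototype.
#' @export
clustering_loss <- function(P, E) {
  if (inherits(P, "proto_model")) P <- P$prototypes
  P <- as.matrix(P)
  if (nrow(P) < 1L)
    stop_invalid("clustering_loss: empty prototype set")
  D2 <- prototype_distances(as.matrix(E), P, squared = TRUE)
  sum(apply(D2, 1L, min))
}

#' Cross-entropy loss
#'
#' Categorical cross-entropy summed over the mini-batch:
#' `CE = -sum_i log probs_i[y_i]`, with probabilities clipped to
#' `[1e-12, 1 - 1e-12]`. For two classes this equals the usual binary form.
#'
#' @param y_true integer vector of zero-based true labels.
#' @param probs `N x C` matrix of predicted class probabilities (rows sum
#'   to 1); a vector is treated as one instance.
#' @param mean_reduce divide by the batch size instead of summing; default
#'   FALSE (summed).
#' @return nonnegative scalar; 0 at perfect confident prediction.
#' @export
cross_entropy <- function(y_true, probs, mean_reduce = FALSE) {
  P <- if (is.null(dim(probs))) matrix(probs, nrow = 1L) else as.matrix(probs)
  y <- as.integer(y_true)
  if (length(y) != nrow(P))
    stop_invalid("cross_entropy: %d labels for %d probability rows",
                 length(y), nrow(P))
  if (any(y < 0L) || any(y >= ncol(P)))
    stop_invalid("cross_entropy: label outside [0, %d]", ncol(P) - 1L)
  p <- pmin(pmax(P[cbind(seq_len(nrow(P)), y + 1L)], 1e-12), 1 - 1e-12)
  ce <- -sum(log(p))
  if (mean_reduce) ce / length(y) else ce
}

#' Combine the four loss terms
#'
#' @param ce,r_div,r1,r2 the four term values.
#' @param weights a [loss_weights()].
#' @return list of class `loss_breakdown` with each term and
#'   `total = ce + lambda * r_div + lambda1 * r1 + lambda2 * r2`.
#' @export
total_loss <- function(ce, r_div, r1, r2, weights = loss_weights()) {
  structure(list(ce = ce, r_div = r_div, r1 = r1, r2 = r2,
                 total = ce + weights$lambda * r_div +
                   weights$lambda1 * r1 + weights$lambda2 * r2),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("loss %.5f = ce %.5f + div %.5f + proto %.5f + clust %.5f (weighted)\n",
              x$total, x$ce, x$r_div, x$r1, x$r2))
  invisible(x)
}
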