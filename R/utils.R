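#' @keywords internal
"_PACKAGE"

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_vec <- function(z) {
  z <- z - max(z)
  ez <- exp(z)
  ez / sum(ez)
}

# row-wise softmax of a matrix
softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  EZ <- exp(Z)
  EZ / rowSums(EZ)
}

#' Derive a named sub-seed from a run seed
#'
#' All randomness in the package flows from a single run seed fanned out to
#' named sub-seeds (data generation, splitting, parameter initialization,
#' batch shuffling), so each component is independently reproducible.
#'
#' @param seed integer run seed.
#' @param what character tag naming the consumer, e.g. `"split"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, what) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(what))
  h <- sum(utf8ToInt(what) * seq_along(utf8ToInt(what)))
  as.integer((abs(as.numeric(seed)) * 2654435 + h * 97) %% 2147483587)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
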