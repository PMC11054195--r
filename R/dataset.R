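#' Labeled beat dataset
#'
#' The package's native container for fixed-length labeled time-series
#' segments: a numeric matrix with one beat per row, an integer class code
#' per beat, and the class-name map. Class codes are zero-based and stored
#' explicitly with their names (by convention `N = 0`, `A = 1`, `O = 2`) so
#' artifacts written to disk can never silently permute classes.
#'
#' @param x numeric matrix, beats in rows, samples in columns.
#' @param y integer vector of zero-based class codes, one per row of `x`.
#' @param classes character vector of class names; `classes[code + 1]` names
#'   code `code`.
#' @param ids optional character identifiers, one per beat.
#' @return an object of class `beat_dataset`.
#' @export
beat_dataset <- function(x, y, classes, ids = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  if (nrow(x) != length(y))
    stop_invalid("beat_dataset: %d rows of x but %d labels", nrow(x), length(y))
  if (any(!is.finite(x)))
    stop_invalid("beat_dataset: non-finite sample values")
  if (length(y) && (any(y < 0L) || any(y >= length(classes))))
    stop_invalid("beat_dataset: label codes must lie in [0, %d]", length(classes) - 1L)
  if (is.null(ids)) ids <- sprintf("beat%05d", seq_len(nrow(x)))
  if (length(ids) != nrow(x))
    stop_invalid("beat_dataset: %d ids for %d beats", length(ids), nrow(x))
  structure(list(x = x, y = y, classes = as.character(classes),
                 ids = as.character(ids)),
            class = "beat_dataset")
}

#' @export
print.beat_dataset <- function(x, ...) {
  tab <- table(factor(x$classes[x$y + 1L], levels = x$classes))
  cat(sprintf("<beat_dataset> %d beats x %d samples; classes: %s\n",
              nrow(x$x), ncol(x$x),
              paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", ")))
  invisible(x)
}

#' Number of beats in a dataset
#' @param data a `beat_dataset`.
#' @return integer count.
#' @export
n_beats <- function(data) nrow(data$x)

#' Subset a beat dataset by row index
#' @param data a `beat_dataset`.
#' @param idx integer or logical index over beats.
#' @return a `beat_dataset` with the selected beats, order preserved.
#' @export
subset_beats <- function(data, idx) {
  beat_dataset(data$x[idx, , drop = FALSE], data$y[idx], data$classes,
               data$ids[idx])
}

# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
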