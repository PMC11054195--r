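#' Editing configuration
#'
#' @param candidate_distance_threshold embedding-space distance below which
#'   a signal is considered already represented by a prototype and excluded
#'   from candidate generation; default 2.
#' @param prune_score_threshold prototypes whose leave-one-out validation
#'   accuracy delta is at or below this value are prunable; default 0
#'   (removal does not hurt).
#' @param fine_tune_epochs epoch budget for post-edit fine-tuning.
#' @return list of class `editing_config`.
#' @export
editing_config <- function(candidate_distance_threshold = 2.0,
                           prune_score_threshold = 0.0,
                           fine_tune_epochs = 5L) {
  stopifnot(candidate_distance_threshold >= 0, fine_tune_epochs >= 0L)
  structure(list(candidate_distance_threshold = candidate_distance_threshold,
                 prune_score_threshold = prune_score_threshold,
                 fine_tune_epochs = as.integer(fine_tune_epochs)),
            class = "editing_config")
}

log_entry <- function(operation, prototype_id, note = "", pre_K, post_K,
                      extra = NULL) {
  e <- list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3%z"),
            operation = operation, prototype_id = prototype_id,
            note = note, pre_K = pre_K, post_K = post_K)
  if (!is.null(extra)) e <- c(e, extra)
  e
}

append_log <- function(model, entry) {
  model$edit_log[[length(model$edit_log) + 1L]] <- entry
  model
}

#' Project prototypes onto their nearest training exemplars
#'
#' For each prototype, finds the training beat whose embedding is nearest
#' (plain L2; ties broken toward the lowest index). With `snap = TRUE` the
#' prototype vector is overwritten by that exemplar's embedding, so every
#' prototype becomes the image of an observable waveform.
#'
#' @param model a [proto_model()].
#' @param train_data a [beat_dataset()].
#' @param snap overwrite prototype vectors with their exemplar embeddings.
#' @return list with `model` (exemplar map attached, vectors snapped if
#'   requested) and `map`: a data frame with one row per prototype
#'   (`id`, `exemplar_id`, `exemplar_index`, `distance`) carrying the
#'   exemplar waveform matrix as attribute `waveforms`.
#' @export
project_prototypes <- function(model, train_data, snap = FALSE) {
  check_model(model)
  stopifnot(inherits(train_data, "beat_dataset"), n_beats(train_data) > 0L)
  E <- embed_dataset(model, train_data)
  D <- prototype_distances(model$prototypes, E, squared = FALSE)  # K x N
  D <- matrix(D, nrow = model$config$K)
  jmin <- apply(D, 1L, which.min)
  map <- data.frame(id = model$proto_meta$id,
                    exemplar_id = train_data$ids[jmin],
                    exemplar_index = jmin,
                    exemplar_label = train_data$y[jmin],
                    distance = D[cbind(seq_len(nrow(D)), jmin)],
                    stringsAsFactors = FALSE)
  attr(map, "waveforms") <- train_data$x[jmin, , drop = FALSE]
  if (snap) model$prototypes <- E[jmin, , drop = FALSE]
  model$proto_meta$exemplar_id <- map$exemplar_id
  model$exemplar_map <- map
  list(model = model, map = map)
}

#' Explain one prediction
#'
#' Ranks prototypes by similarity to the query and decomposes the predicted
#' class's logit into per-prototype contributions `W[c, k] * s_k` (summing
#' over all `K` prototypes reconstructs the logit exactly). Exemplar
#' waveforms are included when an exemplar map is attached (see
#' [project_prototypes()]).
#'
#' @param model a [proto_model()].
#' @param series numeric query beat.
#' @param top_m number of prototypes to report; clamped to `K` with a
#'   warning if larger.
#' @return object of class `explanation_report`: predicted label/class,
#'   logits, attention weights, a ranked data frame of prototype rows, and
#'   the exact contribution total.
#' @export
explain <- function(model, series, top_m = 3L) {
  check_model(model)
  K <- model$config$K
  if (top_m > K) {
    warning(sprintf("top_m = %d clamped to K = %d", top_m, K))
    top_m <- K
  }
  pred <- forward(model, series)
  c1 <- pred$label + 1L
  contrib <- model$W[c1, ] * pred$s
  plab <- prototype_class_labels(model)
  rows <- data.frame(id = model$proto_meta$id,
                     similarity = pred$s,
                     contribution = contrib,
                     prototype_class = model$config$classes[plab + 1L],
                     exemplar_id = model$proto_meta$exemplar_id,
                     stringsAsFactors = FALSE)
  ord <- order(rows$similarity, decreasing = TRUE)
  rows <- rows[ord, , drop = FALSE]
  if (!is.null(model$exemplar_map)) {
    wf <- attr(model$exemplar_map, "waveforms")
    attr(rows, "exemplar_waveforms") <- wf[ord, , drop = FALSE]
  }
  structure(list(label = pred$label, class = pred$class, z = pred$z,
                 probs = pred$probs, alpha = pred$alpha,
                 rows = utils::head(rows, top_m),
                 all_rows = rows,
                 contribution_total = sum(contrib)),
            class = "explanation_report")
}

#' @export
print.explanation_report <- function(x, ...) {
  cat(sprintf("predicted %s (p=%.3f); top prototypes:\n", x$class,
              max(x$probs)))
  print(x$rows[, c("id", "similarity", "contribution", "prototype_class")],
        row.names = FALSE)
  invisible(x)
}

#' Filter signals that are candidates for new prototypes
#'
#' Keeps exactly the signals whose minimum embedding-space L2 distance to
#' every current prototype is at least `dmin`; signals closer than `dmin`
#' to some prototype are already represented and excluded. With an empty
#' prototype set every signal is retained (vacuous minimum).
#'
#' @param signals a [beat_dataset()] or raw beat matrix.
#' @param model a trained [proto_model()].
#' @param dmin distance threshold; default 2.
#' @return integer indices of the retained signals, with the per-signal
#'   minimum distance attached as attribute `min_distance`.
#' @export
filter_candidates <- function(signals, model, dmin = 2.0) {
  X <- if (inherits(signals, "beat_dataset")) signals$x else as.matrix(signals)
  if (nrow(model$prototypes) == 0L) {
    out <- seq_len(nrow(X))
    attr(out, "min_distance") <- rep(Inf, nrow(X))
    return(out)
  }
  E <- embed_dataset(model, X)
  D <- prototype_distances(E, model$prototypes, squared = FALSE)
  D <- matrix(D, nrow = nrow(X))
  mind <- apply(D, 1L, min)
  out <- which(mind >= dmin)
  attr(out, "min_distance") <- mind
  out
}

#' Add an expert prototype from a raw signal
#'
#' Embeds the signal and appends the embedding as a new prototype with
#' provenance `"expert"`. The head gains a zero-initialized column, so
#' every prediction is unchanged until fine-tuning. A duplicate of an
#' existing prototype (embedding distance below 1e-9) is rejected.
#'
#' @param model a [proto_model()].
#' @param series numeric beat to turn into a prototype.
#' @param class_hint optional class name recorded in the edit log.
#' @param note free-text actor note for the edit log.
#' @return the mutated model; the new [log][read_edit_log()] entry is the
#'   last element of `model$edit_log`.
#' @export
add_prototype <- function(model, series, class_hint = NULL, note = "") {
  check_model(model)
  e <- embed_dataset(model, matrix(as.numeric(series), nrow = 1L))[1L, ]
  # direct per-row distance: exact zero for a true duplicate
  d <- sqrt(rowSums(sweep(model$prototypes, 2L, e)^2))
  if (any(d < 1e-9))
    stop_invalid("add_prototype: duplicate of existing prototype %s (distance %.2e)",
                 model$proto_meta$id[which.min(d)], min(d))
  K0 <- model$config$K
  new_id <- sprintf("p%02d", max(0L, suppressWarnings(max(as.integer(
    sub("^p", "", model$proto_meta$id))))) + 1L)
  model$prototypes <- rbind(model$prototypes, e)
  rownames(model$prototypes) <- NULL
  model$W <- cbind(model$W, 0)
  meta <- new_proto_meta(1L, provenance = "expert")
  meta$id <- new_id
  model$proto_meta <- rbind(model$proto_meta, meta)
  model$config$K <- K0 + 1L
  model$exemplar_map <- NULL
  model <- append_log(model, log_entry(
    "add", new_id, note, K0, K0 + 1L,
    extra = list(class_hint = class_hint, series = as.numeric(series))))
  check_model(model)
}

#' Remove a prototype
#'
#' Deletes prototype `k` and its head column, so the logits lose exactly
#' the `W[, k] * s_k` term. The last remaining prototype cannot be removed;
#' a validated prototype is only removed with `force = TRUE`.
#'
#' @param model a [proto_model()].
#' @param k prototype index (1-based) or id string.
#' @param force allow removing a validated prototype.
#' @param note actor note for the edit log.
#' @param operation log operation tag (internal use by pruning).
#' @return the mutated model.
#' @export
remove_prototype <- function(model, k, force = FALSE, note = "",
                             operation = "remove") {
  check_model(model)
  k <- resolve_proto_index(model, k)
  if (model$config$K <= 1L)
    stop_invalid("remove_prototype: cannot remove the last prototype")
  if (model$proto_meta$validated[k] && !force)
    stop_invalid("remove_prototype: prototype %s is validated; use force = TRUE",
                 model$proto_meta$id[k])
  K0 <- model$config$K
  id <- model$proto_meta$id[k]
  model$prototypes <- model$prototypes[-k, , drop = FALSE]
  model$W <- model$W[, -k, drop = FALSE]
  model$proto_meta <- model$proto_meta[-k, , drop = FALSE]
  rownames(model$proto_meta) <- NULL
  model$config$K <- K0 - 1L
  model$exemplar_map <- NULL
  model <- append_log(model, log_entry(operation, id, note, K0, K0 - 1L))
  check_model(model)
}

#' Validate (and freeze) a prototype
#'
#' Marks prototype `k` as expert-validated: its vector is frozen and
#' excluded from subsequent gradient updates, and pruning will never remove
#' it. Its head column still trains.
#'
#' @inheritParams remove_prototype
#' @return the mutated model.
#' @export
validate_prototype <- function(model, k, note = "") {
  check_model(model)
  k <- resolve_proto_index(model, k)
  model$proto_meta$validated[k] <- TRUE
  model$proto_meta$frozen[k] <- TRUE
  append_log(model, log_entry("validate", model$proto_meta$id[k], note,
                              model$config$K, model$config$K))
}

resolve_proto_index <- function(model, k) {
  if (is.character(k)) {
    i <- match(k, model$proto_meta$id)
    if (is.na(i)) stop_invalid("unknown prototype id '%s'", k)
    return(i)
  }
  k <- as.integer(k)
  if (k < 1L || k > model$config$K)
    stop_invalid("prototype index %d outside 1..%d", k, model$config$K)
  k
}

#' Prune uninformative prototypes
#'
#' Scores each unvalidated prototype by its leave-one-out contribution:
#' `score(k) = accuracy(full model) - accuracy(model without k)` on the
#' validation data. Prototypes whose score is at or below
#' `prune_score_threshold` (their removal does not hurt) are removed
#' greedily one at a time, re-scoring after each removal. Validated
#' prototypes are never removed, the count never drops below one prototype
#' per currently-owned class label, and never below `C` in total.
#'
#' @param model a [proto_model()].
#' @param val_data validation [beat_dataset()].
#' @param config an [editing_config()].
#' @return the mutated model.
#' @export
prune_prototypes <- function(model, val_data, config = editing_config()) {
  check_model(model)
  stopifnot(inherits(val_data, "beat_dataset"))
  repeat {
    K <- model$config$K
    if (K <= model$config$C) break
    acc_full <- evaluate(model, val_data)$accuracy
    labels <- prototype_class_labels(model)
    degen <- attr(labels, "degenerate")
    scores <- rep(NA_real_, K)
    for (k in seq_len(K)) {
      if (model$proto_meta$validated[k]) next
      # class floor: keep at least one prototype per currently-owned label
      # (a degenerate all-zero head column owns nothing and is always fair game)
      if (!degen[k] && sum(labels == labels[k] & !degen) <= 1L) next
      trial <- suppressWarnings(
        remove_prototype(model, k, note = "loo-score"))
      scores[k] <- acc_full - evaluate(trial, val_data)$accuracy
    }
    cand <- which(!is.na(scores) & scores <= config$prune_score_threshold)
    if (!length(cand)) break
    # least informative first: lowest accuracy delta, then (on ties) the
    # smallest head-column norm, i.e. the least influence on any logit
    col_norm <- sqrt(colSums(model$W^2))
    cand <- cand[order(scores[cand], col_norm[cand])]
    drop_k <- cand[1L]
    model <- remove_prototype(model, drop_k, operation = "prune",
                              note = sprintf("loo score %.4f", scores[drop_k]))
  }
  model
}

#' Fine-tune after an edit
#'
#' Delegates to [fit()] with a reduced epoch budget, without
#' re-initializing prototypes, honoring frozen-prototype masking. Returns
#' the fine-tuned model (final state).
#'
#' @param model a [proto_model()].
#' @param train_data training [beat_dataset()].
#' @param epochs epoch budget; default 5.
#' @param config optional [training_config()]; its epoch count is
#'   overridden by `epochs`.
#' @return the fine-tuned model.
#' @export
fine_tune <- function(model, train_data, epochs = 5L,
                      config = training_config()) {
  if (epochs == 0L) return(model)
  config$epochs <- as.integer(epochs)
  res <- fit(model, train_data, val = NULL, config = config,
             init_prototypes = FALSE)
  res$final_model
}

#' Write / read / replay the edit log
#'
#' The edit log is an append-only JSON-lines file: one entry per line with
#' the operation, prototype id, actor note and pre/post prototype counts.
#' Replaying a log against the same base model reproduces the same
#' prototype count and metadata (and, absent fine-tuning, the same
#' predictions).
#'
#' @param model a [proto_model()] whose `edit_log` is written.
#' @param path file path.
#' @return `write_edit_log` returns the path invisibly; `read_edit_log`
#'   returns a list of entries; `replay_edit_log` returns the model after
#'   applying the entries in order.
#' @export
write_edit_log <- function(model, path) {
  lines <- vapply(model$edit_log, function(e)
    jsonlite::toJSON(e, auto_unbox = TRUE, digits = NA, null = "null"),
    character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_edit_log
#' @export
read_edit_log <- function(path) {
  lapply(readLines(path), jsonlite::fromJSON)
}

#' @rdname write_edit_log
#' @param entries a list of log entries from [read_edit_log()].
#' @export
replay_edit_log <- function(model, entries) {
  for (e in entries) {
    model <- switch(e$operation,
      add = add_prototype(model, e$series, class_hint = e$class_hint,
                          note = e$note),
      remove = remove_prototype(model, e$prototype_id, force = TRUE,
                                note = e$note),
      prune = remove_prototype(model, e$prototype_id, force = TRUE,
                               note = e$note, operation = "prune"),
      validate = validate_prototype(model, e$prototype_id, note = e$note),
      stop_invalid("replay_edit_log: unknown operation '%s'", e$operation))
  }
  model
}
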