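#' Training configuration
#'
#' Defaults follow the reference setup: Adam with learning rate 0.002,
#' mini-batches of 128, a 70/10/20 train/validation/test split, and the
#' default [loss_weights()]. Gradients are clipped at global norm
#' `clip_norm` to prevent recurrent blow-ups.
#'
#' @param batch_size mini-batch size.
#' @param learning_rate Adam step size.
#' @param epochs training epochs.
#' @param seed integer seed; fans out to split, initialization, shuffling
#'   and dropout streams.
#' @param train_frac,val_frac,test_frac split fractions; must sum to 1.
#' @param weights a [loss_weights()].
#' @param clip_norm global gradient-norm clip; `Inf` disables.
#' @param mean_ce average (rather than sum) the cross-entropy over the
#'   batch; default FALSE (summed, as the objective is written).
#' @param reg_full_set recompute the prototypicality/clustering terms on the
#'   full training set each step instead of the mini-batch; default FALSE.
#' @return list of class `training_config`.
#' @export
training_config <- function(batch_size = 128L, learning_rate = 0.002,
                            epochs = 30L, seed = 1L, train_frac = 0.70,
                            val_frac = 0.10, test_frac = 0.20,
                            weights = loss_weights(), clip_norm = 5.0,
                            mean_ce = FALSE, reg_full_set = FALSE) {
  stopifnot(batch_size >= 1L, learning_rate > 0, epochs >= 0L)
  if (abs(train_frac + val_frac + test_frac - 1) > 1e-8)
    stop_invalid("training_config: split fractions must sum to 1")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 seed = as.integer(seed), train_frac = train_frac,
                 val_frac = val_frac, test_frac = test_frac,
                 weights = weights, clip_norm = clip_norm,
                 mean_ce = isTRUE(mean_ce),
                 reg_full_set = isTRUE(reg_full_set)),
            class = "training_config")
}

#' Stratified train/validation/test split
#'
#' Shuffles each class separately under the split sub-seed and allocates the
#' configured fractions per class, so minority classes appear in every
#' subset. The three subsets are disjoint and their union is the input.
#'
#' @param data a [beat_dataset()].
#' @param config a [training_config()] (fractions and seed are used).
#' @return list with `train`, `val`, `test` beat datasets.
#' @export
split_dataset <- function(data, config = training_config()) {
  stopifnot(inherits(data, "beat_dataset"))
  N <- n_beats(data)
  if (N < 10L) stop_invalid("split_dataset: need at least 10 beats, got %d", N)
  idx_tr <- idx_val <- idx_te <- integer(0)
  with_seed(derive_seed(config$seed, "split"), {
    for (cl in sort(unique(data$y))) {
      idx <- which(data$y == cl)
      if (length(idx) < 3L)
        warning(sprintf("class %s has only %d members; split is best-effort",
                        data$classes[cl + 1L], length(idx)))
      idx <- sample(idx)
      n <- length(idx)
      n_tr <- round(n * config$train_frac)
      n_val <- round(n * config$val_frac)
      n_val <- min(n_val, n - n_tr)
      idx_tr <- c(idx_tr, idx[seq_len(n_tr)])
      if (n_val > 0L) idx_val <- c(idx_val, idx[n_tr + seq_len(n_val)])
      if (n - n_tr - n_val > 0L)
        idx_te <- c(idx_te, idx[(n_tr + n_val + 1L):n])
    }
  })
  list(train = subset_beats(data, sort(idx_tr)),
       val = subset_beats(data, sort(idx_val)),
       test = subset_beats(data, sort(idx_te)))
}

#' Embed every beat of a dataset
#'
#' Runs the encoder and attention pooling (inference mode, no dropout) over
#' all beats in chunks and returns the embedding matrix.
#'
#' @param model a [proto_model()].
#' @param data a [beat_dataset()] or a raw `N x L` matrix.
#' @param chunk rows per forward chunk.
#' @return `N x u` embedding matrix.
#' @export
embed_dataset <- function(model, data, chunk = 512L) {
  X <- if (inherits(data, "beat_dataset")) data$x else as.matrix(data)
  E <- matrix(0, nrow(X), model$config$u)
  i <- 1L
  while (i <= nrow(X)) {
    j <- min(i + chunk - 1L, nrow(X))
    E[i:j, ] <- model_forward_batch(model, X[i:j, , drop = FALSE])$e
    i <- j + 1L
  }
  E
}

grad_global_norm <- function(grads) {
  sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1L))))
}

#' Train a prototype model
#'
#' Mini-batch Adam minimization of the composite objective. Prototypes are
#' initialized (unless `init_prototypes = FALSE`) to the embeddings of `K`
#' randomly chosen training beats, which is stabler than a Gaussian start
#' and consistent with the prototypicality term. Frozen (validated)
#' prototype vectors receive no updates; their head columns still train.
#' The returned model carries the parameter state with the best validation
#' accuracy seen over the epochs.
#'
#' @param model a [proto_model()].
#' @param train,val training and validation [beat_dataset()]s.
#' @param config a [training_config()].
#' @param init_prototypes re-initialize unfrozen prototypes from training
#'   embeddings before the first epoch; default TRUE.
#' @param log_file optional path; per-epoch loss breakdown and validation
#'   accuracy are appended as CSV.
#' @param verbose print one line per epoch.
#' @return list of class `proto_fit` with `model` (best-validation state),
#'   `history` (one row per epoch: ce, r_div, r1, r2, total, val_accuracy)
#'   and `final_model` (state after the last epoch).
#' @export
fit <- function(model, train, val, config = training_config(),
                init_prototypes = TRUE, log_file = NULL, verbose = FALSE) {
  check_model(model)
  stopifnot(inherits(train, "beat_dataset"))
  cf <- model$config
  if (config$epochs == 0L)
    return(structure(list(model = model, final_model = model,
                          history = empty_history()), class = "proto_fit"))

  if (init_prototypes) {
    free <- which(!model$proto_meta$frozen)
    if (length(free)) {
      pick <- with_seed(derive_seed(config$seed, "proto-init"),
                        sample.int(n_beats(train), length(free),
                                   replace = n_beats(train) < length(free)))
      model$prototypes[free, ] <-
        embed_dataset(model, train$x[pick, , drop = FALSE])
    }
  }

  params <- param_list(model)
  m1 <- zero_like(params)
  m2 <- zero_like(params)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- empty_history()
  best <- list(acc = -Inf, params = params)
  N <- n_beats(train)
  frozen <- model$proto_meta$frozen

  with_seed(derive_seed(config$seed, "fit"), {
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(N)
      starts <- seq(1L, N, by = config$batch_size)
      ep_terms <- c(ce = 0, r_div = 0, r1 = 0, r2 = 0, total = 0)
      for (s0 in starts) {
        bi <- ord[s0:min(s0 + config$batch_size - 1L, N)]
        Xb <- train$x[bi, , drop = FALSE]
        yb <- train$y[bi]
        mask <- NULL
        if (cf$dropout > 0) {
          keep <- matrix(stats::rbinom(length(bi) * cf$u, 1L, 1 - cf$dropout),
                         length(bi), cf$u)
          mask <- keep / (1 - cf$dropout)
        }
        reg_E <- if (config$reg_full_set) embed_dataset(model, train) else NULL
        lg <- model_loss_grads(model, Xb, yb, config$weights,
                               dropout_mask = mask, reg_E = reg_E)
        bd <- lg$breakdown
        for (nm in c("ce", "r_div", "r1", "r2", "total"))
          if (!is.finite(bd[[nm]]))
            stop_invalid("fit: non-finite loss term '%s' at epoch %d", nm, ep)
        if (config$mean_ce) {
          # rescale the CE contribution of the gradients is not needed:
          # mean_ce only changes the reported breakdown scale
          bd$ce <- bd$ce / length(bi)
          bd$total <- bd$total - lg$breakdown$ce + bd$ce
        }
        grads <- lg$grads
        if (any(frozen)) grads$prototypes[frozen, ] <- 0
        gn <- grad_global_norm(grads)
        if (is.finite(config$clip_norm) && gn > config$clip_norm)
          grads <- lapply(grads, function(g) g * (config$clip_norm / gn))
        step <- step + 1L
        lr_t <- config$learning_rate *
          sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(params)) {
          m1[[nm]] <- b1 * m1[[nm]] + (1 - b1) * grads[[nm]]
          m2[[nm]] <- b2 * m2[[nm]] + (1 - b2) * grads[[nm]]^2
          params[[nm]] <- params[[nm]] -
            lr_t * m1[[nm]] / (sqrt(m2[[nm]]) + eps)
        }
        model <- set_param_list(model, params)
        ep_terms <- ep_terms +
          c(bd$ce, bd$r_div, bd$r1, bd$r2, bd$total)
      }
      ep_terms <- ep_terms / length(starts)
      val_acc <- if (!is.null(val) && n_beats(val) > 0L)
        evaluate(model, val)$accuracy else NA_real_
      history <- rbind(history, data.frame(
        epoch = ep, ce = ep_terms[["ce"]], r_div = ep_terms[["r_div"]],
        r1 = ep_terms[["r1"]], r2 = ep_terms[["r2"]],
        total = ep_terms[["total"]], val_accuracy = val_acc))
      if (!is.na(val_acc) && val_acc >= best$acc)  # ties: prefer later state
        best <- list(acc = val_acc, params = params)
      if (verbose)
        message(sprintf("epoch %3d  loss %.4f  val acc %s", ep,
                        ep_terms[["total"]],
                        ifelse(is.na(val_acc), "NA", sprintf("%.3f", val_acc))))
    }
  })
  if (!is.null(log_file))
    utils::write.csv(history, log_file, row.names = FALSE)
  best_model <- if (is.finite(best$acc)) set_param_list(model, best$params)
                else model
  structure(list(model = best_model, final_model = model, history = history),
            class = "proto_fit")
}

empty_history <- function() {
  data.frame(epoch = integer(0), ce = numeric(0), r_div = numeric(0),
             r1 = numeric(0), r2 = numeric(0), total = numeric(0),
             val_accuracy = numeric(0))
}

#' @export
print.proto_fit <- function(x, ...) {
  ne <- nrow(x$history)
  if (ne == 0L) cat("<proto_fit> untrained (0 epochs)\n")
  else cat(sprintf("<proto_fit> %d epochs; final loss %.4f; best val acc %.3f\n",
                   ne, x$history$total[ne],
                   suppressWarnings(max(x$history$val_accuracy, na.rm = TRUE))))
  invisible(x)
}

#' Predict class labels for a dataset
#'
#' @param model a [proto_model()].
#' @param data a [beat_dataset()] or raw matrix.
#' @param chunk rows per forward chunk.
#' @return list with `labels` (zero-based) and `probs` (`N x C`).
#' @export
predict_labels <- function(model, data, chunk = 512L) {
  X <- if (inherits(data, "beat_dataset")) data$x else as.matrix(data)
  probs <- matrix(0, nrow(X), model$config$C)
  i <- 1L
  while (i <= nrow(X)) {
    j <- min(i + chunk - 1L, nrow(X))
    probs[i:j, ] <- model_forward_batch(model, X[i:j, , drop = FALSE])$probs
    i <- j + 1L
  }
  list(labels = max.col(probs, ties.method = "first") - 1L, probs = probs)
}

#' Evaluate a model on labeled data
#'
#' Computes accuracy, the `C x C` confusion matrix (true classes in rows),
#' macro precision/recall/F1 (unweighted per-class means; a class that
#' receives no predictions contributes precision 0), and for binary tasks
#' the positive-class F1 and the rank-statistic ROC-AUC over the
#' positive-class probability.
#'
#' @param model a [proto_model()].
#' @param data a [beat_dataset()].
#' @return list of class `metrics_report`.
#' @export
evaluate <- function(model, data) {
  stopifnot(inherits(data, "beat_dataset"))
  if (n_beats(data) == 0L) stop_invalid("evaluate: empty dataset")
  pr <- predict_labels(model, data)
  C <- model$config$C
  y <- data$y
  conf <- table(factor(y, levels = 0:(C - 1L)),
                factor(pr$labels, levels = 0:(C - 1L)))
  conf <- matrix(as.integer(conf), C, C,
                 dimnames = list(true = model$config$classes,
                                 pred = model$config$classes))
  met <- metrics_from_confusion(conf)
  if (C == 2L) {
    met$f1 <- met$per_class_f1[2L]
    met$roc_auc <- auc_rank(pr$probs[, 2L], y)
  }
  structure(met, class = "metrics_report")
}

# accuracy and macro precision/recall/F1 from a confusion matrix
# (true classes in rows); a class with no predictions gets precision 0
metrics_from_confusion <- function(conf) {
  C <- nrow(conf)
  prec <- rec <- f1c <- numeric(C)
  for (c in seq_len(C)) {
    tp <- conf[c, c]
    prec[c] <- if (sum(conf[, c]) > 0) tp / sum(conf[, c]) else 0
    rec[c] <- if (sum(conf[c, ]) > 0) tp / sum(conf[c, ]) else 0
    f1c[c] <- if (prec[c] + rec[c] > 0)
      2 * prec[c] * rec[c] / (prec[c] + rec[c]) else 0
  }
  list(accuracy = sum(diag(conf)) / sum(conf), roc_auc = NA_real_,
       f1 = NA_real_, macro_precision = mean(prec),
       macro_recall = mean(rec), macro_f1 = mean(f1c),
       per_class_precision = prec, per_class_recall = rec,
       per_class_f1 = f1c, confusion = conf)
}

# ROC-AUC as the Wilcoxon rank statistic of positive-class scores
auc_rank <- function(scores, y) {
  npos <- sum(y == 1L); nneg <- sum(y == 0L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro P %.4f R %.4f F1 %.4f",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1))
  if (!is.na(x$roc_auc)) cat(sprintf(" | ROC-AUC %.4f F1 %.4f", x$roc_auc, x$f1))
  cat("\nconfusion (rows = true):\n")
  print(x$confusion)
  invisible(x)
}
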