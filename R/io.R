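#' Write a beat dataset to CSV
#'
#' Native exchange format: a comment line declaring the class-code map
#' (`# classes: 0=N,1=A,2=O`), then a header `id,s1..sL,label` and one beat
#' per row with the integer class code in the final column.
#'
#' @param data a [beat_dataset()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_dataset_csv <- function(data, path) {
  stopifnot(inherits(data, "beat_dataset"))
  L <- ncol(data$x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# classes: %s",
                     paste(sprintf("%d=%s", seq_along(data$classes) - 1L,
                                   data$classes), collapse = ",")), con)
  df <- data.frame(id = data$ids, data$x, label = data$y,
                   stringsAsFactors = FALSE)
  names(df) <- c("id", sprintf("s%d", seq_len(L)), "label")
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a beat dataset from CSV
#'
#' Inverse of [write_dataset_csv()]. The file must be rectangular with a
#' numeric body; parse problems are reported with the offending row number.
#'
#' @param path input file.
#' @return a [beat_dataset()] with rows in file order.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("read_dataset_csv: no such file '%s'", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_invalid("read_dataset_csv: empty file '%s'", path)
  classes <- NULL
  if (grepl("^#\\s*classes:", lines[1L])) {
    spec <- sub("^#\\s*classes:\\s*", "", lines[1L])
    parts <- strsplit(strsplit(spec, ",")[[1L]], "=")
    codes <- vapply(parts, function(p) as.integer(p[1L]), integer(1L))
    classes <- character(max(codes) + 1L)
    classes[codes + 1L] <- vapply(parts, function(p) trimws(p[2L]), character(1L))
    lines <- lines[-1L]
  }
  if (length(lines) < 2L)
    stop_invalid("read_dataset_csv: '%s' has a header but no data rows", path)
  df <- tryCatch(
    utils::read.csv(text = lines, stringsAsFactors = FALSE,
                    check.names = FALSE),
    error = function(e) stop_invalid("read_dataset_csv: parse error: %s",
                                     conditionMessage(e)))
  if (!"label" %in% names(df))
    stop_invalid("read_dataset_csv: missing 'label' column")
  has_id <- "id" %in% names(df)
  samp_cols <- setdiff(names(df), c("id", "label"))
  body <- df[, samp_cols, drop = FALSE]
  for (j in seq_along(body)) {
    v <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(v) & !is.na(body[[j]]))
    if (length(bad) || anyNA(body[[j]]))
      stop_invalid("read_dataset_csv: non-numeric or missing cell in row %d, column %s",
                   c(bad, which(is.na(body[[j]])))[1L], samp_cols[j])
    body[[j]] <- v
  }
  y <- suppressWarnings(as.integer(df$label))
  if (anyNA(y))
    stop_invalid("read_dataset_csv: non-integer label in row %d",
                 which(is.na(y))[1L])
  if (is.null(classes)) classes <- as.character(sort(unique(y)))
  beat_dataset(as.matrix(body), y, classes,
               ids = if (has_id) df$id else NULL)
}

# ---- checkpoints ----------------------------------------------------------

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding `manifest.json` (format version,
#' model shape and configuration, prototype metadata, edit log, and the
#' name/dimension index of every parameter array) plus `params.bin`, all
#' parameter arrays concatenated as little-endian doubles. The round trip
#' `load_model(save_model(m, path))` reproduces every array bit-exactly and
#' all prototype metadata.
#'
#' @param model a [proto_model()].
#' @param path checkpoint directory (created if needed).
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored model.
#' @export
save_model <- function(model, path) {
  check_model(model)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  params <- param_list(model)
  index <- lapply(names(params), function(nm) {
    p <- params[[nm]]
    list(name = nm, dim = if (is.null(dim(p))) length(p) else dim(p))
  })
  manifest <- list(
    format_version = 1L,
    package = "protobeat",
    config = model$config,
    encoder = model$encoder[c("input_size", "hidden_size", "num_layers",
                              "bidirectional")],
    attention = list(d_alpha = model$attention$d_alpha,
                     score_tanh = model$attention$score_tanh),
    proto_meta = model$proto_meta,
    edit_log = model$edit_log,
    arrays = index)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  con <- file(file.path(path, "params.bin"), "wb")
  on.exit(close(con))
  for (nm in names(params))
    writeBin(as.double(params[[nm]]), con, size = 8L, endian = "little")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!file.exists(mf)) stop_invalid("load_model: no manifest at '%s'", mf)
  man <- jsonlite::fromJSON(mf, simplifyDataFrame = TRUE,
                            simplifyVector = TRUE)
  cf <- man$config
  model <- proto_model(
    input_length = cf$input_length, n_steps = cf$n_steps,
    hidden_size = man$encoder$hidden_size,
    num_layers = man$encoder$num_layers,
    bidirectional = man$encoder$bidirectional,
    d_alpha = man$attention$d_alpha, n_prototypes = cf$K,
    classes = cf$classes, dropout = cf$dropout,
    dist_squared = cf$dist_squared, score_tanh = cf$score_tanh,
    seed = cf$seed)
  con <- file(file.path(path, "params.bin"), "rb")
  on.exit(close(con))
  params <- list()
  arr <- man$arrays
  for (i in seq_len(nrow(arr))) {
    dims <- unlist(arr$dim[i])
    vals <- readBin(con, "double", n = prod(dims), size = 8L,
                    endian = "little")
    params[[arr$name[i]]] <- if (length(dims) == 2L)
      matrix(vals, dims[1L], dims[2L]) else vals
  }
  model <- set_param_list(model, params)
  meta <- as.data.frame(man$proto_meta, stringsAsFactors = FALSE)
  meta$exemplar_id <- if (is.null(meta$exemplar_id)) NA_character_
                      else as.character(meta$exemplar_id)
  model$proto_meta <- meta
  model$edit_log <- man$edit_log %||% list()
  if (is.data.frame(model$edit_log))
    model$edit_log <- lapply(seq_len(nrow(model$edit_log)),
                             function(i) as.list(model$edit_log[i, ]))
  check_model(model)
}

# ---- run configuration ----------------------------------------------------

#' Default run configuration
#'
#' The flat key/value document driving the command-line interface: data
#' generation, model shape, training and editing settings in one place.
#' Unknown keys are rejected by [validate_config()].
#'
#' @return named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    samples_per_beat = 180L, n_per_class = 600L,
    classes = c("N", "A", "O"), noise_sd = 0.03,
    n_steps = 18L, hidden_size = 16L, num_layers = 3L, bidirectional = TRUE,
    d_alpha = 16L, n_prototypes = 12L, dropout = 0.1,
    dist_squared = FALSE, score_tanh = FALSE,
    batch_size = 128L, learning_rate = 0.002, epochs = 30L,
    train_frac = 0.70, val_frac = 0.10, test_frac = 0.20,
    lambda = 0.01, lambda1 = 0.05, lambda2 = 0.05,
    diversity_threshold = 1.0, clip_norm = 5.0,
    dmin = 2.0, prune_score_threshold = 0.0, fine_tune_epochs = 5L),
    class = "run_config")
}

#' Validate and normalize a run configuration
#'
#' @param cfg named list of configuration values.
#' @return a complete `run_config` with defaults filled in; unknown keys
#'   raise an error.
#' @export
validate_config <- function(cfg) {
  base <- default_config()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    stop_invalid("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (nm in names(cfg)) {
    tmpl <- base[[nm]]
    val <- cfg[[nm]]
    base[[nm]] <- if (is.integer(tmpl)) as.integer(val)
      else if (is.numeric(tmpl)) as.numeric(val)
      else if (is.logical(tmpl)) as.logical(val)
      else as.character(val)
  }
  if (abs(base$train_frac + base$val_frac + base$test_frac - 1) > 1e-8)
    stop_invalid("config: split fractions must sum to 1")
  base
}

#' Read / write a run configuration as YAML
#'
#' @param path file path.
#' @return `read_config` returns a validated `run_config`; `write_config`
#'   returns the path invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_invalid("read_config: no such file '%s'", path)
  validate_config(yaml::read_yaml(path))
}

#' @rdname read_config
#' @param cfg a `run_config`.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(validate_config(cfg)), path)
  invisible(path)
}

# ---- WFDB reader (optional external interface) ----------------------------

#' Read single-lead WFDB recordings with challenge-style labels
#'
#' Minimal reader for the PhysioNet 2017 challenge layout: each record has
#' a text header `<record>.hea` (record name, signal count, sampling
#' frequency, sample count; then per-signal file name, format and
#' gain/units) and a binary signal file in format 16 (little-endian 16-bit
#' integers), with reference labels in `REFERENCE.csv` (`record,label`,
#' labels in `N`, `A`, `O`, `~`). Signals are returned in physical units
#' (ADC values divided by the gain), unresampled.
#'
#' @param directory path containing `.hea`/`.dat` files and `REFERENCE.csv`.
#' @return list of class `wfdb_recordings`: `records` (each with `id`,
#'   `signal`, `label` code and `fs`) and the label map `classes`
#'   (`N=0, A=1, O=2, ~=3`).
#' @export
read_cinc_wfdb <- function(directory) {
  ref_path <- file.path(directory, "REFERENCE.csv")
  if (!file.exists(ref_path))
    stop_invalid("read_cinc_wfdb: missing annotation file '%s'", ref_path)
  ref <- utils::read.csv(ref_path, header = FALSE, stringsAsFactors = FALSE,
                         col.names = c("record", "label"))
  classes <- c("N", "A", "O", "~")
  if (!all(ref$label %in% classes))
    stop_invalid("read_cinc_wfdb: unknown label(s): %s",
                 paste(setdiff(ref$label, classes), collapse = ", "))
  records <- lapply(seq_len(nrow(ref)), function(i) {
    rec <- ref$record[i]
    hea <- file.path(directory, paste0(rec, ".hea"))
    if (!file.exists(hea))
      stop_invalid("read_cinc_wfdb: missing header '%s'", hea)
    hl <- readLines(hea)
    hl <- hl[!grepl("^#", hl)]
    top <- strsplit(trimws(hl[1L]), "\\s+")[[1L]]
    fs <- as.numeric(top[3L])
    nsamp <- as.integer(top[4L])
    sig <- strsplit(trimws(hl[2L]), "\\s+")[[1L]]
    sig_file <- file.path(directory, sig[1L])
    fmt <- sub("x.*$", "", sig[2L])
    if (fmt != "16")
      stop_invalid("read_cinc_wfdb: unsupported signal format '%s'", sig[2L])
    gain <- as.numeric(sub("[(/].*$", "", sig[3L]))
    if (!is.finite(gain) || gain == 0) gain <- 200  # WFDB default gain
    con <- file(sig_file, "rb")
    on.exit(close(con))
    adc <- readBin(con, "integer", n = nsamp, size = 2L, signed = TRUE,
                   endian = "little")
    list(id = rec, signal = adc / gain, fs = fs,
         label = match(ref$label[i], classes) - 1L)
  })
  structure(list(records = records, classes = classes),
            class = "wfdb_recordings")
}
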