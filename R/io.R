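# Readers and writers for the canonical on-disk segment store: one
# delimited-text file per segment (one mV value per row) plus a labels table
# (segment_id, label), and delimited outputs for predictions and reports.

#' Write segments to a directory
#'
#' @param segments Named list of [ecg_segment()]s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest `data.frame` (segment_id, label).
#' @export
write_segment_dir <- function(segments, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ids <- names(segments)
  if (is.null(ids)) ids <- sprintf("seg_%05d", seq_along(segments))
  for (i in seq_along(segments)) {
    writeLines(sprintf("%.17g", segments[[i]]$values),
               file.path(dir, paste0(ids[i], ".txt")))
  }
  manifest <- data.frame(
    segment_id = ids,
    label = vapply(segments, function(s)
      if (is.null(s$label)) NA_character_ else s$label, character(1)))
  write.csv(manifest, file.path(dir, "labels.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read segments from a directory
#'
#' Reads every segment listed in the directory's `labels.csv` manifest,
#' validating length and labels; write-then-read round-trips values to full
#' precision.
#'
#' @param dir Directory written by [write_segment_dir()].
#' @param fs_hz Sampling rate of the stored segments.
#' @param duration_s Expected duration; a file with any other sample count
#'   is a parse error naming the offender.
#' @return Named list of [ecg_segment()]s.
#' @export
read_segment_dir <- function(dir, fs_hz = 250L, duration_s = 20) {
  manifest_path <- file.path(dir, "labels.csv")
  if (!file.exists(manifest_path))
    stop("no labels.csv manifest in ", dir, call. = FALSE)
  manifest <- read.csv(manifest_path, stringsAsFactors = FALSE)
  n_expect <- as.integer(round(fs_hz * duration_s))
  segs <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    path <- file.path(dir, paste0(manifest$segment_id[i], ".txt"))
    txt <- readLines(path)
    v <- suppressWarnings(as.numeric(txt))
    if (anyNA(v) && any(is.na(v) != (txt %in% c("NA", "NaN"))))
      stop(sprintf("parse error in %s: non-numeric value at line %d",
                   path, which(is.na(v) & !txt %in% c("NA", "NaN"))[1]),
           call. = FALSE)
    if (length(v) != n_expect)
      stop(sprintf("parse error in %s: expected %d samples, found %d",
                   path, n_expect, length(v)), call. = FALSE)
    lab <- manifest$label[i]
    segs[[i]] <- ecg_segment(v, fs_hz,
                             label = if (is.na(lab)) NULL else lab)
  }
  names(segs) <- manifest$segment_id
  attr(segs, "manifest") <- manifest
  segs
}

#' Write a predictions table
#'
#' @param pred Factor/character vector of predicted labels.
#' @param probs Matrix of class probabilities with columns named by class.
#' @param segment_ids Segment identifiers.
#' @param path Output CSV path.
#' @return Invisibly, the written `data.frame`.
#' @export
write_predictions <- function(pred, probs, segment_ids, path) {
  stopifnot(length(pred) == nrow(probs),
            length(segment_ids) == length(pred))
  df <- data.frame(segment_id = segment_ids,
                   predicted_label = as.character(pred),
                   p_acceptable = probs[, "acceptable"],
                   p_unacceptable = probs[, "unacceptable"],
                   p_uncertain = if ("uncertain" %in% colnames(probs))
                     probs[, "uncertain"] else NA_real_)
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write an evaluation report as JSON
#'
#' @param report An `eval_report` from [evaluate_predictions()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  out <- list(
    n = report$n,
    cm3 = unclass(report$cm3), cm2 = unclass(report$cm2),
    precision3 = as.list(report$metrics3$precision),
    recall3 = as.list(report$metrics3$recall),
    accuracy3 = report$accuracy3,
    precision2 = as.list(report$metrics2$precision),
    recall2 = as.list(report$metrics2$recall),
    accuracy2 = report$accuracy2)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", matrix = "rowmajor")
  invisible(path)
}

# Defaults for a full pipeline run; every threshold carries the study
# default and every stage has an explicit seed.
default_run_config <- function() {
  list(
    fs_hz = 250L, duration_s = 20,
    blank_s = 0.5, clip_mv = 5,
    n_train = c(190, 30, 30), n_test = c(95, 15, 15),
    model = "rf", mode = "two-step",
    k_best = 43L,
    rf = list(estimators_increment = 50L, n_repetitions = 20L),
    cnn = list(n_steps = 5L, epochs_per_step = 2L),
    seeds = list(data = 1L, train = 2L),
    log_level = "info"
  )
}

#' Read a pipeline run configuration
#'
#' YAML configuration merged over the package defaults; see the methods
#' vignette for the available keys.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    for (nm in names(user)) {
      cfg[[nm]] <- if (is.list(user[[nm]]) && is.list(cfg[[nm]]))
        utils::modifyList(cfg[[nm]], user[[nm]]) else user[[nm]]
    }
  }
  cfg
}

#' Run the full quality-assessment pipeline
#'
#' Generate (synthetic) -> preprocess -> extract features or transform ->
#' train -> classify -> evaluate, from one configuration list. Intended both
#' as the `run-all` CLI backend and as a one-call smoke test of the whole
#' flow.
#'
#' @param config Configuration list from [read_run_config()].
#' @param out_dir Optional directory for predictions and report files.
#' @return Invisibly, a list with the trained model(s), predictions and the
#'   [evaluate_predictions()] report.
#' @export
run_pipeline <- function(config = read_run_config(), out_dir = NULL) {
  train_raw <- generate_dataset(config$n_train, fs_hz = config$fs_hz,
                                seed = config$seeds$data)
  test_raw <- generate_dataset(config$n_test, fs_hz = config$fs_hz,
                               seed = derive_seed(config$seeds$data, 1L))
  pp_train <- preprocess_batch(train_raw, blank_s = config$blank_s,
                               clip_mv = config$clip_mv,
                               duration_s = config$duration_s)
  pp_test <- preprocess_batch(test_raw, blank_s = config$blank_s,
                              clip_mv = config$clip_mv,
                              duration_s = config$duration_s)
  y_train <- segment_labels(pp_train$kept)
  y_test <- segment_labels(pp_test$kept)

  if (config$model == "rf") {
    ftr <- extract_features_batch(pp_train$kept)
    fte <- extract_features_batch(pp_test$kept)
    keep <- select_k_best(ftr[, -1], y_train, k = config$k_best)
    x_train <- as.matrix(ftr[, keep, drop = FALSE])
    x_test <- as.matrix(fte[, keep, drop = FALSE])
    cfg <- rf_config(estimators_increment = config$rf$estimators_increment,
                     n_repetitions = config$rf$n_repetitions,
                     seed = config$seeds$train)
    trainer <- train_rf
  } else {
    mode_tr <- if (config$mode == "one-step") "stft" else "fft"
    x_train <- transform_batch(pp_train$kept, mode_tr)
    x_test <- transform_batch(pp_test$kept, mode_tr)
    cfg <- cnn_config(n_steps = config$cnn$n_steps,
                      epochs_per_step = config$cnn$epochs_per_step,
                      n_classes = if (config$mode == "one-step") 3L else 2L,
                      seed = config$seeds$train)
    trainer <- train_cnn
  }

  if (config$mode == "one-step") {
    if (config$model == "cnn") cfg$n_classes <- 3L
    model <- trainer(x_train, y_train, cfg)
    pred <- one_step_classify(model, x_test)
    probs <- predict_proba(model, x_test)
  } else {
    model <- train_cascade(x_train, y_train, cfg, trainer = trainer)
    pred <- two_step_classify(model, x_test)
    p1 <- predict_proba(model$step1, x_test)
    p2 <- predict_proba(model$step2, x_test)
    probs <- cbind(acceptable = p1[, "acceptable"],
                   unacceptable = (1 - p1[, "acceptable"]) *
                     p2[, "unacceptable"],
                   uncertain = (1 - p1[, "acceptable"]) *
                     (1 - p2[, "unacceptable"]))
  }
  report <- evaluate_predictions(y_test, pred)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_predictions(pred, probs, names(pp_test$kept),
                      file.path(out_dir, "predictions.csv"))
    write_report(report, file.path(out_dir, "report.json"))
  }
  invisible(list(model = model, predictions = pred, probs = probs,
                 report = report,
                 exclusions = list(train = pp_train$fraction_excluded,
                                   test = pp_test$fraction_excluded)))
}
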