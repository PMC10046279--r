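#' One-step 3-class classification
#'
#' Argmax over the three class probabilities, with a fixed deterministic
#' tie-break order: acceptable > unacceptable > uncertain.
#'
#' @param model A fitted 3-class model with a [predict_proba()] method.
#' @param x Feature rows or images matching the model's training inputs.
#' @return Factor of predicted labels over [quality_classes()], one per
#'   input row, order-preserving.
#' @export
one_step_classify <- function(model, x) {
  p <- predict_proba(model, x)
  if (!all(quality_classes() %in% colnames(p)))
    stop("model does not predict all three quality classes", call. = FALSE)
  p <- p[, quality_classes(), drop = FALSE]  # tie-break via column order
  factor(quality_classes()[max.col(p, ties.method = "first")],
         levels = quality_classes())
}

#' Assemble a two-step cascade
#'
#' @param step1 Binary model separating acceptable from unacceptable (used
#'   at inference as acceptable vs other).
#' @param step2 Binary model separating unacceptable from uncertain.
#' @return An object of class `cascade_model`.
#' @export
cascade_model <- function(step1, step2) {
  structure(list(step1 = step1, step2 = step2), class = "cascade_model")
}

#' Two-step binary sequential classification
#'
#' Step 1 decides acceptable vs other at probability threshold 0.5 (a
#' segment with acceptable-probability >= 0.5 is final, step 2 is never
#' consulted). Segments classified as other go to step 2, which decides
#' unacceptable vs uncertain at 0.5 (ties resolve to unacceptable,
#' consistent with the global tie-break order).
#'
#' @param cascade A [cascade_model()].
#' @param x Feature rows or images matching the step models' inputs.
#' @return Factor of predicted labels over [quality_classes()].
#' @export
two_step_classify <- function(cascade, x) {
  stopifnot(inherits(cascade, "cascade_model"))
  p1 <- predict_proba(cascade$step1, x)
  if (!"acceptable" %in% colnames(p1))
    stop("step1 must predict an 'acceptable' class", call. = FALSE)
  n <- nrow(p1)
  out <- rep("uncertain", n)
  acc <- p1[, "acceptable"] >= 0.5
  out[acc] <- "acceptable"
  if (any(!acc)) {
    p2 <- predict_proba(cascade$step2, subset_inputs(x, which(!acc)))
    if (!"unacceptable" %in% colnames(p2))
      stop("step2 must predict an 'unacceptable' class", call. = FALSE)
    out[!acc][p2[, "unacceptable"] >= 0.5] <- "unacceptable"
  }
  factor(out, levels = quality_classes())
}

# Row/element subsetting across the supported input containers.
subset_inputs <- function(x, idx) {
  if (is.matrix(x) || is.data.frame(x)) return(x[idx, , drop = FALSE])
  if (is.array(x) && length(dim(x)) == 3) return(x[, , idx, drop = FALSE])
  if (is.list(x)) return(x[idx])
  stop("unsupported input container", call. = FALSE)
}

#' Build the three training sets of the study design
#'
#' From a labelled dataset, builds the index sets for (a) the balanced
#' 3-class training set, (b) step 1 of the cascade (acceptable +
#' unacceptable only; uncertain segments are excluded from its training) and
#' (c) step 2 (unacceptable + uncertain only). Each set is balanced by
#' random undersampling to its minority-class count.
#'
#' @param labels Label vector over [quality_classes()] (or a dataset list,
#'   from which labels are taken).
#' @param seed Integer seed for the undersampling draws.
#' @return List with integer index vectors `threeclass`, `step1`, `step2`,
#'   each carrying a `labels` attribute with the corresponding labels.
#' @export
build_training_sets <- function(labels, seed = 1L) {
  if (is.list(labels)) labels <- segment_labels(labels)
  labels <- as_quality_factor(labels)
  counts <- table(labels)
  if (any(counts == 0))
    stop("a required class is empty: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  withr::with_seed(as.integer(seed), {
    three <- draw_balanced(labels)
    s1_pool <- labels %in% c("acceptable", "unacceptable")
    s1 <- which(s1_pool)[draw_balanced(droplevels(labels[s1_pool]))]
    s2_pool <- labels %in% c("unacceptable", "uncertain")
    s2 <- which(s2_pool)[draw_balanced(droplevels(labels[s2_pool]))]
  })
  wrap <- function(idx) {
    attr(idx, "labels") <- labels[idx]
    idx
  }
  list(threeclass = wrap(three), step1 = wrap(s1), step2 = wrap(s2))
}

#' Train a two-step cascade
#'
#' Trains step 1 only on acceptable + unacceptable segments and step 2 only
#' on unacceptable + uncertain segments, using the supplied trainer (the
#' warm-start random forest by default; each trainer performs its own
#' per-step balanced resampling).
#'
#' @param x Feature matrix/data.frame or image container for the full
#'   dataset.
#' @param labels Labels over [quality_classes()].
#' @param cfg Model configuration ([rf_config()] or [cnn_config()]); step
#'   seeds are derived from `cfg$seed`. For CNN configs `n_classes` is
#'   forced to 2 for both steps.
#' @param trainer Training function, [train_rf()] or [train_cnn()].
#' @return A [cascade_model()].
#' @export
train_cascade <- function(x, labels, cfg = rf_config(), trainer = train_rf) {
  labels <- as_quality_factor(labels)
  counts <- table(labels)
  if (any(counts == 0))
    stop("a required class is empty: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  fit_step <- function(classes, offset) {
    keep <- labels %in% classes
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(cfg$seed, offset)
    if (inherits(cfg_i, "cnn_config")) cfg_i$n_classes <- 2L
    trainer(subset_inputs(x, which(keep)), droplevels(labels[keep]), cfg_i)
  }
  cascade_model(step1 = fit_step(c("acceptable", "unacceptable"), 1L),
                step2 = fit_step(c("unacceptable", "uncertain"), 2L))
}
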