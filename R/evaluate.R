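#' 3x3 confusion matrix
#'
#' Rows are the truth, columns the prediction, both in the canonical class
#' order acceptable / unacceptable / uncertain.
#'
#' @param truth,pred Equal-length label vectors over [quality_classes()].
#' @return 3x3 integer matrix of counts.
#' @export
confusion_3x3 <- function(truth, pred) {
  truth <- as_quality_factor(truth)
  pred <- as_quality_factor(pred)
  if (length(truth) != length(pred))
    stop("truth and pred must have equal length", call. = FALSE)
  m <- table(truth = truth, pred = pred)
  matrix(as.integer(m), 3, 3,
         dimnames = list(truth = quality_classes(),
                         pred = quality_classes()))
}

#' Merge to the 2x2 usable-vs-unacceptable matrix
#'
#' Collapses acceptable + uncertain into one "usable" class against
#' unacceptable, reflecting the practical data-selection goal; each 2x2 cell
#' is the sum of the corresponding 3x3 block, so the total count is
#' preserved.
#'
#' @param cm3 A 3x3 confusion matrix in canonical order (see
#'   [confusion_3x3()]).
#' @return 2x2 matrix with classes `acceptable+uncertain` and
#'   `unacceptable`.
#' @export
merge_2x2 <- function(cm3) {
  stopifnot(is.matrix(cm3), all(dim(cm3) == c(3, 3)))
  a <- 1L; b <- 2L; u <- 3L  # acceptable, unacceptable, uncertain
  m <- matrix(c(cm3[a, a] + cm3[a, u] + cm3[u, a] + cm3[u, u],
                cm3[b, a] + cm3[b, u],
                cm3[a, b] + cm3[u, b],
                cm3[b, b]),
              2, 2,
              dimnames = list(truth = c("acceptable+uncertain", "unacceptable"),
                              pred = c("acceptable+uncertain", "unacceptable")))
  m
}

#' Per-class precision/recall and overall accuracy
#'
#' Precision of class j is `cm[j, j] / colsum_j`, recall of class i is
#' `cm[i, i] / rowsum_i`, accuracy is `trace / total`. An empty denominator
#' yields `NA` (an explicit undefined marker), never a silent 0.
#'
#' @param cm Square nonnegative confusion matrix (rows = truth).
#' @return List with named `precision` and `recall` vectors and `accuracy`.
#' @export
cm_metrics <- function(cm) {
  stopifnot(is.matrix(cm))
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square",
                                 call. = FALSE)
  d <- diag(cm)
  cs <- colSums(cm); rs <- rowSums(cm); tot <- sum(cm)
  prec <- ifelse(cs > 0, d / cs, NA_real_)
  rec <- ifelse(rs > 0, d / rs, NA_real_)
  names(prec) <- names(rec) <- rownames(cm)
  list(precision = prec, recall = rec,
       accuracy = if (tot > 0) sum(d) / tot else NA_real_)
}

#' Full evaluation report
#'
#' Computes the 3x3 confusion matrix, the merged 2x2 matrix, and per-class
#' precision/recall plus overall accuracy for both.
#'
#' @param truth,pred Label vectors over [quality_classes()].
#' @return An object of class `eval_report` with elements `cm3`, `cm2`,
#'   `metrics3`, `metrics2`, `accuracy3`, `accuracy2`, `n`.
#' @export
evaluate_predictions <- function(truth, pred) {
  cm3 <- confusion_3x3(truth, pred)
  cm2 <- merge_2x2(cm3)
  m3 <- cm_metrics(cm3)
  m2 <- cm_metrics(cm2)
  structure(list(cm3 = cm3, cm2 = cm2, metrics3 = m3, metrics2 = m2,
                 accuracy3 = m3$accuracy, accuracy2 = m2$accuracy,
                 n = sum(cm3)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>", x$n, "segments\n\n3x3 confusion (rows = truth):\n")
  print(x$cm3)
  cat(sprintf("accuracy: %.3f\n", x$accuracy3))
  cat("\nmerged 2x2 (acceptable+uncertain vs unacceptable):\n")
  print(x$cm2)
  cat(sprintf("accuracy: %.3f\n", x$accuracy2))
  cat("\nper-class precision (3x3):",
      paste(sprintf("%s=%.3f", names(x$metrics3$precision),
                    x$metrics3$precision), collapse = ", "), "\n")
  cat("per-class recall (3x3):   ",
      paste(sprintf("%s=%.3f", names(x$metrics3$recall),
                    x$metrics3$recall), collapse = ", "), "\n")
  invisible(x)
}
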