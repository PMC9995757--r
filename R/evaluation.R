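#' One-vs-rest confusion counts
#'
#' For each class `c`: TP = units predicted and annotated `c`; FP =
#' predicted `c` but annotated otherwise; FN = annotated `c` but
#' predicted otherwise; TN = the rest.  Every row sums to the number of
#' evaluation units.
#'
#' @param pred,truth Equal-length label vectors (factor or character).
#' @param classes Classes to report (default [activity_classes()]).
#' @return Tibble with columns `class`, `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(pred, truth, classes = activity_classes()) {
  if (length(pred) != length(truth))
    abort("pred and truth must have the same length",
          class = "nearfallr_validation_error")
  pred <- as.character(pred)
  truth <- as.character(truth)
  n <- length(pred)
  purrr::map_dfr(classes, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    tibble(class = cl, tp = tp, fp = fp, tn = n - tp - fp - fn, fn = fn)
  })
}

safe_ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Per-class classification statistics
#'
#' Sensitivity (TPR), specificity (TNR), positive and negative
#' predictive value, and accuracy from one-vs-rest counts.  A zero
#' denominator yields `NA` (rendered "NA" in reports, never 0).
#'
#' @param counts Tibble from [confusion_counts()] (columns `class`,
#'   `tp`, `fp`, `tn`, `fn`).
#' @return The input with columns `tpr`, `tnr`, `ppv`, `npv`, `acc`
#'   appended.
#' @export
classification_stats <- function(counts) {
  counts <- as_tibble(counts)
  need <- c("tp", "fp", "tn", "fn")
  if (!all(need %in% names(counts)))
    abort("counts need columns tp, fp, tn, fn",
          class = "nearfallr_validation_error")
  if (any(as.matrix(counts[, need]) < 0))
    abort("counts must be non-negative", class = "nearfallr_validation_error")
  dplyr::mutate(counts,
    tpr = safe_ratio(.data$tp, .data$tp + .data$fn),
    tnr = safe_ratio(.data$tn, .data$tn + .data$fp),
    ppv = safe_ratio(.data$tp, .data$tp + .data$fp),
    npv = safe_ratio(.data$tn, .data$tn + .data$fn),
    acc = safe_ratio(.data$tp + .data$tn,
                     .data$tp + .data$fp + .data$tn + .data$fn))
}

#' One-vs-rest ROC curve and AUC
#'
#' Sweeps a threshold over the unique scores, from predicting nothing
#' positive to everything positive, and integrates the (FPR, TPR)
#' polyline by the trapezoid rule.  Tied scores move together, so the
#' AUC equals the Mann-Whitney concordance probability with half credit
#' for ties.
#'
#' @param scores Numeric score for the positive class, one per unit.
#' @param truth Logical (or 0/1) positive indicator, one per unit.
#' @return A list of class `roc_curve`: `points` (tibble `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_curve_auc <- function(scores, truth) {
  truth <- as.logical(truth)
  if (length(scores) != length(truth))
    abort("scores and truth must have the same length",
          class = "nearfallr_validation_error")
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos == 0 || n_neg == 0)
    abort("ROC needs at least one positive and one negative unit",
          class = "nearfallr_validation_error")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- truth[ord]
  keep <- c(diff(s) != 0, TRUE)  # last index of each tied block
  tp <- cumsum(y)[keep]
  fp <- cumsum(!y)[keep]
  points <- tibble(threshold = c(Inf, s[keep]),
                   fpr = c(0, fp / n_neg),
                   tpr = c(0, tp / n_pos))
  auc <- sum(diff(points$fpr) *
               (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d points, AUC = %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' Published reference confusion counts and statistics
#'
#' One-vs-rest counts (and the derived statistics as printed) for the
#' ten activity classes from a video-validated in-home deployment of
#' the five-sensor system (14,389 evaluation units over ten subjects).
#' Bundled as a regression fixture for [classification_stats()]: the
#' statistics recomputed from the counts must agree with the printed
#' values to their printed precision.
#'
#' @return Tibble with `class`, the four counts, and printed `tpr`,
#'   `tnr`, `ppv`, `npv`, `acc`.
#' @export
reference_activity_stats <- function() {
  path <- system.file("extdata", "reference_activity_stats.csv",
                      package = "nearfallr")
  readr::read_csv(path, col_types = readr::cols(
    class = readr::col_character(), .default = readr::col_double()),
    progress = FALSE)
}
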