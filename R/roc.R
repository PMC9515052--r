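#' ROC curve for regular-vs-aberrant discrimination
#'
#' Builds the receiver operating characteristic of a per-surgery score
#' (e.g. FT-group count or FT-frame count) against a binary aberrant-course
#' flag. Higher scores predict the aberrant class. Candidate thresholds sit
#' at the midpoints between consecutive distinct observed scores, with
#' infinite sentinels at the extremes, so on integer counts the operating
#' cutoff comes out as a half-integer.
#'
#' @param scores Numeric score per surgery.
#' @param aberrant Logical per surgery, `TRUE` for an aberrant course.
#' @return A list of class `roc_result`: `points` (data frame with
#'   `threshold`, `fpr`, `tpr`, ordered by increasing false-positive rate),
#'   `auc`, `best_cutoff`, `sensitivity_at_cutoff`, `specificity_at_cutoff`,
#'   `youden_j`.
#' @examples
#' res <- roc_curve(c(7, 8, 7, 12, 13), c(FALSE, FALSE, FALSE, TRUE, TRUE))
#' res$auc          # 1: perfect separation
#' res$best_cutoff  # midpoint between the classes
#' @export
roc_curve <- function(scores, aberrant) {
  if (length(scores) != length(aberrant)) {
    stop("scores and aberrant flags must have equal length")
  }
  aberrant <- as.logical(aberrant)
  if (anyNA(scores) || anyNA(aberrant)) stop("missing values are not allowed")
  if (!any(aberrant) || all(aberrant)) {
    stop("degenerate labels: both a regular and an aberrant class are required")
  }
  r <- pROC::roc(controls = scores[!aberrant], cases = scores[aberrant],
                 direction = "<", quiet = TRUE)
  pts <- data.frame(
    threshold = r$thresholds,
    fpr = 1 - r$specificities,
    tpr = r$sensitivities
  )
  pts <- pts[order(-pts$threshold), , drop = FALSE]
  rownames(pts) <- NULL

  best <- youden_best(pts, scores)
  structure(
    list(
      points = pts,
      auc = as.numeric(r$auc),
      best_cutoff = best$threshold,
      sensitivity_at_cutoff = best$tpr,
      specificity_at_cutoff = 1 - best$fpr,
      youden_j = best$j
    ),
    class = "roc_result"
  )
}

# Youden-J maximizer over all curve thresholds (midpoints plus the infinite
# sentinels); ties broken toward higher specificity, then toward the higher
# threshold. A winning +Inf sentinel — the flag-nothing classifier, reached
# when no midpoint improves on J = 0 — is reported as the maximum observed
# score, which classifies identically under the strict ">" rule.
youden_best <- function(pts, scores) {
  j <- pts$tpr - pts$fpr
  best <- which(j == max(j))
  if (length(best) > 1L) best <- best[pts$fpr[best] == min(pts$fpr[best])]
  if (length(best) > 1L) best <- best[which.max(pts$threshold[best])]
  threshold <- pts$threshold[best]
  if (!is.finite(threshold)) threshold <- max(scores)
  list(threshold = threshold, fpr = pts$fpr[best],
       tpr = pts$tpr[best], j = j[best])
}

#' Area under the ROC curve
#'
#' @param result A `roc_result` from [roc_curve()].
#' @return The trapezoidal area, equal to the Mann-Whitney probability that
#'   a random aberrant surgery outscores a random regular one (ties counted
#'   half).
#' @export
roc_auc <- function(result) {
  stopifnot(inherits(result, "roc_result"))
  result$auc
}

#' Operating cutoff of a calibrated ROC curve
#'
#' The threshold maximizing Youden's J (sensitivity + specificity - 1),
#' reported as the midpoint between the adjacent observed scores; ties are
#' broken toward higher specificity.
#'
#' @param result A `roc_result` from [roc_curve()].
#' @return The cutoff value.
#' @export
optimal_cutoff <- function(result) {
  stopifnot(inherits(result, "roc_result"))
  result$best_cutoff
}

#' Calibrate flicker-alert cutoffs on a profiled cohort
#'
#' Runs the ROC analysis of one flicker statistic against the cohort's
#' ground-truth aberrance flags and returns the calibrated curve.
#'
#' @param profiles List of [flicker_profile()] objects.
#' @param aberrant Logical ground-truth flag per profile.
#' @param score Which statistic to score surgeries by: `"groups"`
#'   (FT-group count) or `"frames"` (total FT-frame count).
#' @return A `roc_result`; its `best_cutoff` is the calibrated critical
#'   value for [flicker_alert()].
#' @export
roc_calibrate <- function(profiles, aberrant,
                          score = c("groups", "frames")) {
  score <- match.arg(score)
  field <- if (score == "groups") "n_ft_groups" else "n_ft_frames"
  x <- vapply(profiles, function(p) as.numeric(p[[field]]), numeric(1))
  out <- roc_curve(x, aberrant)
  out$score <- score
  out
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result>%s AUC %.3f; cutoff %g (sens %.2f, spec %.2f, J %.2f)\n",
    if (!is.null(x$score)) paste0(" score=", x$score) else "",
    x$auc, x$best_cutoff, x$sensitivity_at_cutoff, x$specificity_at_cutoff,
    x$youden_j
  ))
  invisible(x)
}
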