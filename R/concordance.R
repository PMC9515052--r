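#' Frame-level concordance of two annotations
#'
#' Compares a predicted annotation (e.g. the network's) against a ground
#' truth (e.g. the expert's) frame by frame: overall accuracy with an exact
#' (Clopper-Pearson) 95% binomial interval, the 8x8 confusion matrix with
#' ground truth in columns and prediction in rows, and per-phase accuracy
#' (column-wise recall).
#'
#' @param pred,truth [annotation_sequence()] objects of equal length and
#'   frame rate. Unequal lengths are an error; no alignment is attempted.
#' @return A list of class `concordance_result`: `accuracy`, `ci_low`,
#'   `ci_high`, `n_frames`, `confusion` (8x8 integer matrix, rows = PRED,
#'   columns = GT), `per_phase_accuracy` (named, `NaN` for phases absent
#'   from the truth).
#' @export
frame_accuracy <- function(pred, truth) {
  stopifnot(inherits(pred, "annotation_sequence"),
            inherits(truth, "annotation_sequence"))
  if (length(pred$labels) != length(truth$labels)) {
    stop(sprintf("alignment error: %d predicted vs %d truth frames",
                 length(pred$labels), length(truth$labels)))
  }
  if (pred$fps != truth$fps) stop("alignment error: frame rates differ")
  confusion <- table(
    factor(pred$labels, levels = 0:7),
    factor(truth$labels, levels = 0:7),
    dnn = c("PRED", "GT")
  )
  concordance_from_confusion(unclass(confusion))
}

concordance_from_confusion <- function(confusion) {
  n <- sum(confusion)
  hits <- sum(diag(confusion))
  ci <- stats::binom.test(hits, n)$conf.int
  col_tot <- colSums(confusion)
  per_phase <- diag(confusion) / col_tot     # NaN where the phase is absent
  names(per_phase) <- names(PHASE_LABELS)
  structure(
    list(
      accuracy = hits / n,
      ci_low = ci[1L],
      ci_high = ci[2L],
      n_frames = n,
      confusion = confusion,
      per_phase_accuracy = per_phase
    ),
    class = "concordance_result"
  )
}

#' Pool concordance across surgeries
#'
#' Merges the per-surgery confusion counts before computing accuracy and
#' its interval, so the pooled accuracy is the frame-weighted mean of the
#' per-surgery accuracies.
#'
#' @param pairs List of `list(pred =, truth =)` pairs of
#'   [annotation_sequence()] objects, each length-matched.
#' @return A `concordance_result` over the merged frames.
#' @export
pool_concordance <- function(pairs) {
  if (length(pairs) == 0L) stop("insufficient data: no annotation pairs")
  confusions <- lapply(pairs, function(p) {
    frame_accuracy(p$pred, p$truth)$confusion
  })
  concordance_from_confusion(Reduce(`+`, confusions))
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf(
    "<concordance_result> accuracy %.3f (95%% CI %.3f-%.3f) on %d frames\n",
    x$accuracy, x$ci_low, x$ci_high, x$n_frames
  ))
  invisible(x)
}
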