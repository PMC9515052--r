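#' Per-phase durations of one surgery
#'
#' The duration of a phase is the total number of frames carrying its label
#' divided by the frame rate — robust to non-contiguous (flickered)
#' annotations. Phases absent from the sequence get duration 0.
#'
#' @param seq An [annotation_sequence()].
#' @return Named numeric vector of length 8 (names `"P0"` ... `"P7"`),
#'   seconds. The durations always sum to [duration_seconds()] exactly.
#' @export
phase_durations <- function(seq) {
  stopifnot(inherits(seq, "annotation_sequence"))
  counts <- tabulate(seq$labels + 1L, nbins = 8L)
  stats::setNames(counts / seq$fps, names(PHASE_LABELS))
}

#' Reference phase-duration statistics of a cohort
#'
#' Per-phase 25th percentile, median and 75th percentile across surgeries,
#' computed with the linear-interpolation quantile (type 7, R's default).
#' These quartiles are the reference band for the duration alert.
#'
#' @param durations A list of per-surgery duration vectors as returned by
#'   [phase_durations()], or a numeric matrix with one row per surgery and
#'   8 phase columns. At least two surgeries are required.
#' @return A data frame of class `phase_duration_stats` with one row per
#'   phase and columns `phase`, `q25`, `median`, `q75` (seconds), plus an
#'   attribute `n_surgeries`.
#' @export
cohort_stats <- function(durations) {
  if (is.list(durations)) durations <- do.call(rbind, durations)
  if (!is.matrix(durations) || ncol(durations) != 8L) {
    stop("durations must be a list of 8-phase vectors or an n x 8 matrix")
  }
  if (nrow(durations) < 2L) {
    stop("insufficient data: cohort statistics need at least 2 surgeries")
  }
  q <- apply(durations, 2L, stats::quantile,
             probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  out <- data.frame(
    phase = 0:7,
    q25 = q[1L, ],
    median = q[2L, ],
    q75 = q[3L, ]
  )
  attr(out, "n_surgeries") <- nrow(durations)
  class(out) <- c("phase_duration_stats", "data.frame")
  out
}

#' Interquartile-range duration alerts for one surgery
#'
#' A phase raises `ALERT_SHORT` when its duration falls strictly below the
#' cohort's 25th percentile and `ALERT_LONG` when it strictly exceeds the
#' 75th percentile; a duration exactly on either quartile is within the
#' reference band (`OK`).
#'
#' @param durations Named 8-phase duration vector from [phase_durations()].
#' @param stats A `phase_duration_stats` from [cohort_stats()].
#' @return A data frame of class `alert_decision` with columns `phase`,
#'   `duration`, `q25`, `q75`, `status` (`"OK"`, `"ALERT_SHORT"`,
#'   `"ALERT_LONG"`).
#' @export
duration_alerts <- function(durations, stats) {
  stopifnot(inherits(stats, "phase_duration_stats"))
  if (length(durations) != 8L) stop("durations must cover all 8 phases")
  status <- rep("OK", 8L)
  status[durations < stats$q25] <- "ALERT_SHORT"
  status[durations > stats$q75] <- "ALERT_LONG"
  out <- data.frame(
    phase = 0:7,
    duration = as.numeric(durations),
    q25 = stats$q25,
    q75 = stats$q75,
    status = status
  )
  class(out) <- c("alert_decision", "data.frame")
  out
}

#' Header flicker alert
#'
#' Raised when a surgery's flicker profile exceeds the calibrated critical
#' values: strictly more FT groups than `cutoff_groups` and/or strictly more
#' FT frames than `cutoff_frames`. The defaults are the reference cutoffs
#' for 2 fps cholecystectomy annotations (11.5 groups, 212 frames); for a
#' new cohort they should be recalibrated with [roc_calibrate()].
#'
#' @param profile A [flicker_profile()].
#' @param cutoff_groups Critical FT-group count (default 11.5).
#' @param cutoff_frames Critical FT-frame count (default 212).
#' @return `TRUE` if either branch exceeds its cutoff.
#' @export
flicker_alert <- function(profile, cutoff_groups = 11.5,
                          cutoff_frames = 212) {
  stopifnot(inherits(profile, "flicker_profile"))
  profile$n_ft_groups > cutoff_groups || profile$n_ft_frames > cutoff_frames
}
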