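#' Configuration of the synthetic cohort simulator
#'
#' The simulator emulates the statistical structure of per-frame phase
#' annotations of laparoscopic cholecystectomy: the eight phases in order,
#' log-normal per-phase duration spread, clean single-step transitions for
#' regular courses, and — for aberrant courses — a prolonged affected phase
#' carrying bursts of flickering (contiguous frames relabeled to wrong
#' phases), mimicking the disordered annotation seen around adverse events.
#'
#' @param n_surgeries Cohort size (default 15).
#' @param fps Frame rate of generated annotations (default 2).
#' @param median_seconds Per-phase median durations in seconds, length 8.
#'   The defaults are plausible elective-cholecystectomy scales chosen for
#'   illustration; they are configuration, not reference values.
#' @param sdlog Log-scale standard deviation of the per-phase duration
#'   distribution (default 0.35).
#' @param min_phase_seconds Lower bound on a sampled phase duration;
#'   draws below it are resampled (default 20 s, which keeps phase runs
#'   long enough that transition activity never merges across phases at
#'   the default detector settings).
#' @param aberrant_fraction Fraction of the cohort with an aberrant course
#'   (default 0.4, mirroring a cohort with 6 of 15 divergent).
#' @param n_bursts_range Integer range (min, max) of flicker bursts
#'   injected per aberrant surgery; the count is uniform on the range
#'   (default 3..7).
#' @param burst_len_range Range of burst lengths in frames (default 8..30).
#' @param duration_multiplier Factor applied to the affected phase's
#'   duration in aberrant courses (default 2).
#' @param seed Optional integer seed for [generate_cohort()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_surgeries = 15L,
                         fps = 2,
                         median_seconds = c(45, 420, 150, 900, 180,
                                            240, 150, 60),
                         sdlog = 0.35,
                         min_phase_seconds = 20,
                         aberrant_fraction = 0.4,
                         n_bursts_range = c(3L, 7L),
                         burst_len_range = c(8L, 30L),
                         duration_multiplier = 2,
                         seed = NULL) {
  stopifnot(length(median_seconds) == 8L, all(median_seconds > 0),
            sdlog >= 0, min_phase_seconds > 0,
            aberrant_fraction >= 0, aberrant_fraction <= 1,
            length(n_bursts_range) == 2L, n_bursts_range[1] >= 1,
            length(burst_len_range) == 2L, burst_len_range[1] >= 1,
            duration_multiplier > 0, fps > 0)
  structure(
    list(n_surgeries = as.integer(n_surgeries), fps = fps,
         median_seconds = as.numeric(median_seconds), sdlog = sdlog,
         min_phase_seconds = min_phase_seconds,
         aberrant_fraction = aberrant_fraction,
         n_bursts_range = as.integer(n_bursts_range),
         burst_len_range = as.integer(burst_len_range),
         duration_multiplier = duration_multiplier, seed = seed),
    class = "synth_config"
  )
}

# Uniform integer draw(s) on a closed range; safe for collapsed ranges
# (sample() would misread a scalar as 1:n).
sample_range <- function(range, k = 1L) {
  if (range[1] == range[2]) rep(range[1], k)
  else sample(range[1]:range[2], k, replace = TRUE)
}

# One log-normal duration draw >= the floor, with bounded resampling.
sample_duration <- function(median_s, sdlog, min_s, retries = 100L) {
  for (i in seq_len(retries)) {
    d <- stats::rlnorm(1L, meanlog = log(median_s), sdlog = sdlog)
    if (d >= min_s) return(d)
  }
  stop(sprintf(
    "could not sample a phase duration >= %g s from median %g s", min_s,
    median_s))
}

#' Simulate one annotated surgery
#'
#' A regular course runs through phases P0..P7 in order, each a constant
#' run of its sampled duration with single-frame boundaries. An aberrant
#' course additionally has its longest phase prolonged by the configured
#' multiplier and carries the configured number of flicker bursts inside
#' that phase, placed far enough from the phase boundaries and from each
#' other that every burst forms its own FT group at the default detector
#' settings.
#'
#' Draws come from the current RNG stream; seed the session (or use
#' [generate_cohort()], which seeds from its config) for reproducibility.
#'
#' @param cfg A [synth_config()].
#' @param aberrant Logical; simulate an aberrant course?
#' @param surgery_id Identifier for the generated sequence.
#' @return A list with `sequence` (an [annotation_sequence()] with source
#'   `"SYNTH"`) and `truth` (list: `aberrant`, `affected_phase`,
#'   `n_bursts`, `bursts` data frame of start frames and lengths,
#'   `phase_start` frame of each phase).
#' @export
generate_surgery <- function(cfg, aberrant = FALSE,
                             surgery_id = "synthetic") {
  stopifnot(inherits(cfg, "synth_config"))
  dur <- vapply(cfg$median_seconds, sample_duration, numeric(1),
                sdlog = cfg$sdlog, min_s = cfg$min_phase_seconds)
  affected <- NA_integer_
  if (aberrant) {
    affected <- which.max(dur)                # complications prolong the
    dur[affected] <- dur[affected] * cfg$duration_multiplier  # longest phase
  }
  frames <- pmax(seconds_to_frames(dur, cfg$fps), 1L)
  labels <- rep(0:7, times = frames)
  phase_start <- cumsum(c(1L, frames[-8L]))

  bursts <- data.frame(start = integer(), length = integer())
  if (aberrant) {
    k <- sample_range(cfg$n_bursts_range)
    bursts <- place_bursts(cfg, k,
                           seg_start = phase_start[affected],
                           seg_end = phase_start[affected] +
                             frames[affected] - 1L)
    phase_lab <- affected - 1L
    others <- setdiff(0:7, phase_lab)
    for (i in seq_len(nrow(bursts))) {
      idx <- bursts$start[i]:(bursts$start[i] + bursts$length[i] - 1L)
      labels[idx] <- sample(others, length(idx), replace = TRUE)
    }
  }

  list(
    sequence = annotation_sequence(labels, surgery_id = surgery_id,
                                   fps = cfg$fps, source = "SYNTH"),
    truth = list(aberrant = aberrant,
                 affected_phase = if (aberrant) affected - 1L else NA_integer_,
                 n_bursts = nrow(bursts), bursts = bursts,
                 phase_start = phase_start)
  )
}

# Place k bursts inside [seg_start, seg_end] so that each stays an isolated
# FT group: margins and pairwise spacing exceed the activity halo of a
# burst (buffer width on each side) plus the 10 s merge gap.
place_bursts <- function(cfg, k, seg_start, seg_end) {
  w <- 6L
  merge_frames <- seconds_to_frames(10, cfg$fps)
  lmax <- cfg$burst_len_range[2]
  sep <- merge_frames + 2L * w + 2L           # min start-to-start slack
  margin <- merge_frames + 2L * w + 2L        # from the phase boundaries
  lo <- seg_start + margin
  hi <- seg_end - margin - lmax
  slot <- (hi - lo + 1L) %/% k
  if (slot < sep + lmax) {
    stop(sprintf(
      "affected phase too short (%d frames) to hold %d separated bursts",
      seg_end - seg_start + 1L, k))
  }
  len <- sample_range(cfg$burst_len_range, k)
  jitter <- floor(stats::runif(k) * (slot - sep - lmax + 1L))
  start <- lo + (seq_len(k) - 1L) * slot + as.integer(jitter)
  data.frame(start = as.integer(start), length = as.integer(len))
}

#' Simulate a cohort with ground-truth aberrance flags
#'
#' `round(aberrant_fraction * n_surgeries)` members are aberrant; which
#' ones is randomized. When the config carries a seed the whole cohort is
#' reproducible bit for bit.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_cohort` with `sequences` (list of
#'   [annotation_sequence()]), `truth` (data frame: `surgery_id`,
#'   `aberrant`, `affected_phase`, `n_bursts`) and `details` (per-surgery
#'   truth records).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (cfg$n_surgeries < 2L) stop("a cohort needs at least 2 surgeries")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_surgeries
  n_ab <- round(cfg$aberrant_fraction * n)
  flags <- logical(n)
  flags[sample.int(n, n_ab)] <- TRUE
  ids <- sprintf("synth-%02d", seq_len(n))
  out <- lapply(seq_len(n), function(i) {
    generate_surgery(cfg, aberrant = flags[i], surgery_id = ids[i])
  })
  structure(
    list(
      sequences = lapply(out, `[[`, "sequence"),
      truth = data.frame(
        surgery_id = ids,
        aberrant = flags,
        affected_phase = vapply(out, function(x) x$truth$affected_phase,
                                integer(1)),
        n_bursts = vapply(out, function(x) x$truth$n_bursts, integer(1))
      ),
      details = lapply(out, `[[`, "truth")
    ),
    class = "synth_cohort"
  )
}
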