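#' Configuration of the flicker detector
#'
#' @param buffer_width Width of the sliding frame buffer, in frames
#'   (default 6). Must be at least 2.
#' @param merge_gap_seconds Maximum separation, in seconds, at which
#'   consecutive spans of flicker/transition activity are embraced into one
#'   FT group (default 10 s). Converted to frames as
#'   `round(merge_gap_seconds * fps)`; a gap of at most that many inactive
#'   frames merges.
#' @return A list of class `flicker_config`.
#' @export
flicker_config <- function(buffer_width = 6L, merge_gap_seconds = 10) {
  if (!is.numeric(buffer_width) || length(buffer_width) != 1L ||
      buffer_width != floor(buffer_width) || buffer_width < 2) {
    stop("buffer_width must be an integer >= 2")
  }
  if (!is.numeric(merge_gap_seconds) || length(merge_gap_seconds) != 1L ||
      merge_gap_seconds < 0) {
    stop("merge_gap_seconds must be a non-negative number")
  }
  structure(list(buffer_width = as.integer(buffer_width),
                 merge_gap_seconds = as.numeric(merge_gap_seconds)),
            class = "flicker_config")
}

#' Classify one frame buffer as uniform, transition or flicker
#'
#' A window is `UNIFORM` when it holds a single distinct label, `TRANSITION`
#' when it holds exactly two distinct labels with every copy of the smaller
#' label preceding every copy of the larger (an ascending block order, the
#' signature of a regular phase change), and `FLICKER` otherwise — more than
#' two labels, unsorted order, or a backward jump.
#'
#' @param window Integer vector of phase labels, of length equal to the
#'   configured buffer width.
#' @param cfg A [flicker_config()].
#' @return One of `"UNIFORM"`, `"TRANSITION"`, `"FLICKER"`.
#' @examples
#' classify_window(c(1, 1, 1, 1, 1, 1))  # UNIFORM
#' classify_window(c(1, 1, 1, 2, 2, 2))  # TRANSITION
#' classify_window(c(2, 3, 1, 1, 2, 4))  # FLICKER
#' @export
classify_window <- function(window, cfg = flicker_config()) {
  window <- check_phase_labels(window)
  if (length(window) != cfg$buffer_width) {
    stop(sprintf("window length %d does not match buffer width %d",
                 length(window), cfg$buffer_width))
  }
  d <- diff(window)
  if (all(d == 0L)) return("UNIFORM")
  if (all(d >= 0L) && sum(d > 0L) == 1L) return("TRANSITION")
  "FLICKER"
}

#' Slide the buffer along a sequence and classify every window
#'
#' @param seq An [annotation_sequence()], at least as long as the buffer.
#' @param cfg A [flicker_config()].
#' @return Character vector of window states, one per window start position
#'   (stride 1); length is `length(seq) - buffer_width + 1`.
#' @export
scan_sequence <- function(seq, cfg = flicker_config()) {
  stopifnot(inherits(seq, "annotation_sequence"))
  w <- cfg$buffer_width
  n <- length(seq$labels)
  if (n < w) {
    stop(sprintf("sequence of %d frames is shorter than the %d-frame buffer",
                 n, w))
  }
  d <- diff(seq$labels)                       # n - 1 adjacent differences
  m <- n - w + 1L                             # number of windows
  if (w == 2L) {
    dmin <- dmax <- d
    pos <- as.integer(d > 0L)
  } else {
    dm <- stats::embed(d, w - 1L)             # row i = diffs of window i, reversed
    dmin <- do.call(pmin, as.data.frame(dm))
    dmax <- do.call(pmax, as.data.frame(dm))
    pos <- rowSums(dm > 0L)
  }
  states <- rep("FLICKER", m)
  states[dmin == 0L & dmax == 0L] <- "UNIFORM"
  states[dmin >= 0L & pos == 1L] <- "TRANSITION"
  states
}

#' Frames touched by flicker or transition activity
#'
#' A frame is active ("concerned") when at least one non-uniform window
#' covers it; window at start position `s` (1-based) covers frames
#' `s .. s + buffer_width - 1`.
#'
#' @param states Window states from [scan_sequence()].
#' @param cfg The [flicker_config()] used for the scan.
#' @param seq_length Number of frames in the scanned sequence.
#' @param which Which window states count as active; by default any
#'   non-uniform window.
#' @return Logical mask over the frames, `TRUE` where active.
#' @export
mark_active_frames <- function(states, cfg, seq_length,
                               which = c("TRANSITION", "FLICKER")) {
  w <- cfg$buffer_width
  if (length(states) != seq_length - w + 1L) {
    stop("states length does not match the sequence/buffer geometry")
  }
  starts <- base::which(states %in% which)
  mask_from_windows(starts, w, seq_length)
}

# Union of windows [s, s + w - 1] as a logical frame mask.
mask_from_windows <- function(starts, w, n) {
  delta <- integer(n + 1L)
  if (length(starts)) {
    add <- tabulate(starts, nbins = n)
    sub <- tabulate(pmin(starts + w, n + 1L), nbins = n + 1L)
    delta <- c(add, 0L) - sub
  }
  cumsum(delta)[seq_len(n)] > 0L
}

#' Segment a surgery into FT groups
#'
#' Maximal runs of active frames (any frame covered by a transition or
#' flicker window) are merged when separated by at most
#' `round(merge_gap_seconds * fps)` inactive frames; each merged run becomes
#' one FT group spanning its first through last active frame. A group
#' contains flicker when any flicker window lies inside its span.
#'
#' @param seq An [annotation_sequence()].
#' @param cfg A [flicker_config()].
#' @return A data frame with one row per group and columns `start_frame`
#'   (1-based, inclusive), `end_frame` (inclusive), `n_frames`,
#'   `contains_flicker`. Groups are disjoint and sorted. A clean ordered
#'   course with single-step phase boundaries yields exactly
#'   (number of phases - 1) groups, none containing flicker.
#' @export
extract_ft_groups <- function(seq, cfg = flicker_config()) {
  states <- scan_sequence(seq, cfg)
  n <- length(seq$labels)
  w <- cfg$buffer_width
  active <- mark_active_frames(states, cfg, n)
  flicker_mask <- mask_from_windows(which(states == "FLICKER"), w, n)

  groups <- data.frame(start_frame = integer(), end_frame = integer(),
                       n_frames = integer(), contains_flicker = logical())
  if (!any(active)) return(groups)

  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  run_start <- starts[r$values]
  run_end <- ends[r$values]

  gap_frames <- seconds_to_frames(cfg$merge_gap_seconds, seq$fps)
  k <- length(run_start)
  if (k > 1L) {
    gaps <- run_start[-1L] - run_end[-k] - 1L
    grp <- cumsum(c(1L, as.integer(gaps > gap_frames)))
  } else {
    grp <- 1L
  }
  start_frame <- tapply(run_start, grp, min)
  end_frame <- tapply(run_end, grp, max)
  data.frame(
    start_frame = as.integer(start_frame),
    end_frame = as.integer(end_frame),
    n_frames = as.integer(end_frame - start_frame + 1L),
    contains_flicker = mapply(function(a, b) any(flicker_mask[a:b]),
                              start_frame, end_frame),
    row.names = NULL
  )
}

#' Flicker profile of one surgery
#'
#' The per-surgery summary used as the aberrance score: the number of FT
#' groups, the total number of frames inside them, and the frames inside
#' groups that contain flicker.
#'
#' @param seq An [annotation_sequence()].
#' @param cfg A [flicker_config()].
#' @return A list of class `flicker_profile` with `surgery_id`,
#'   `n_ft_groups`, `n_ft_frames`, `n_flicker_frames` and the `groups`
#'   data frame from [extract_ft_groups()].
#' @examples
#' seq <- annotation_sequence(rep(0:7, each = 60), source = "SYNTH")
#' flicker_profile(seq)   # 7 groups, no flicker: a regular course
#' @export
flicker_profile <- function(seq, cfg = flicker_config()) {
  groups <- extract_ft_groups(seq, cfg)
  structure(
    list(
      surgery_id = seq$surgery_id,
      n_ft_groups = nrow(groups),
      n_ft_frames = sum(groups$n_frames),
      n_flicker_frames = sum(groups$n_frames[groups$contains_flicker]),
      groups = groups
    ),
    class = "flicker_profile"
  )
}

#' @export
print.flicker_profile <- function(x, ...) {
  cat(sprintf(
    "<flicker_profile> %s: %d FT groups, %d frames (%d in flicker groups)\n",
    x$surgery_id, x$n_ft_groups, x$n_ft_frames, x$n_flicker_frames
  ))
  invisible(x)
}
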