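#' Phase labels of laparoscopic cholecystectomy
#'
#' Eight operative phases, coded 0 to 7, following the Cholec80 convention:
#' transition start, preparation, clipping, dissection, hemostasis part I,
#' retrieval of the gallbladder, hemostasis part II, transition end.
#'
#' @format Integer vector `0:7`, named by phase code (`"P0"` ... `"P7"`).
#' @export
PHASE_LABELS <- stats::setNames(0:7, paste0("P", 0:7))

.PHASE_NAMES <- c(
  "Transition start",
  "Preparation",
  "Clipping",
  "Dissection",
  "Hemostasis part I",
  "Retrieval of the gallbladder",
  "Hemostasis part II",
  "Transition end"
)

#' Human-readable name of a phase label
#'
#' @param label Integer phase label(s) in `0:7`.
#' @return Character vector of phase names, e.g. `phase_name(2)` is
#'   `"Clipping"`.
#' @examples
#' phase_name(0)      # "Transition start"
#' phase_name(0:7)
#' @export
phase_name <- function(label) {
  label <- check_phase_labels(label)
  .PHASE_NAMES[label + 1L]
}

#' Phase label from a name
#'
#' Inverse of [phase_name()]; matching is exact.
#'
#' @param name Character vector of phase names.
#' @return Integer labels in `0:7`.
#' @export
phase_label <- function(name) {
  idx <- match(name, .PHASE_NAMES)
  if (anyNA(idx)) {
    stop("unknown phase name(s): ",
         paste(unique(name[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

# Validate a vector of phase labels; returns them as integer.
check_phase_labels <- function(label) {
  if (length(label) == 0L) stop("at least one phase label is required")
  if (!is.numeric(label) || anyNA(label) || any(label != floor(label))) {
    stop("phase labels must be integers in 0..7")
  }
  if (any(label < 0L | label > 7L)) {
    bad <- unique(label[label < 0L | label > 7L])
    stop("invalid phase label(s): ", paste(bad, collapse = ", "),
         " (must be in 0..7)")
  }
  as.integer(label)
}

#' Per-frame phase annotation of one surgery
#'
#' The universal input of the pipeline: an ordered sequence of per-frame
#' phase labels for a single surgery, recorded at a known frame rate.
#'
#' @param labels Integer vector of phase labels in `0:7`, one per frame,
#'   in frame order.
#' @param surgery_id Identifier string for the surgery.
#' @param fps Frames per second (positive; default 2, the usual inference
#'   resolution for phase-recognition output).
#' @param source Provenance tag, one of `"CNN"` (network annotation),
#'   `"HE"` (human expert), `"HA"` (human annotator, algorithm based),
#'   `"SYNTH"` (simulated).
#' @return An object of class `annotation_sequence`: a list with elements
#'   `surgery_id`, `fps`, `labels`, `source`.
#' @examples
#' seq <- annotation_sequence(c(0, 0, 1, 1, 1, 2), surgery_id = "demo")
#' duration_seconds(seq)
#' @export
annotation_sequence <- function(labels, surgery_id = "surgery", fps = 2,
                                source = c("CNN", "HE", "HA", "SYNTH")) {
  source <- match.arg(source)
  labels <- check_phase_labels(labels)
  if (!is.character(surgery_id) || length(surgery_id) != 1L) {
    stop("surgery_id must be a single string")
  }
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0) {
    stop("fps must be a single positive number")
  }
  structure(
    list(surgery_id = surgery_id, fps = as.numeric(fps),
         labels = labels, source = source),
    class = "annotation_sequence"
  )
}

#' @export
length.annotation_sequence <- function(x) length(x$labels)

#' Duration of an annotated surgery in seconds
#'
#' @param seq An [annotation_sequence()].
#' @return Frame count divided by the frame rate.
#' @export
duration_seconds <- function(seq) {
  stopifnot(inherits(seq, "annotation_sequence"))
  length(seq$labels) / seq$fps
}

#' @export
print.annotation_sequence <- function(x, ...) {
  cat(sprintf(
    "<annotation_sequence> %s [%s]: %d frames @ %g fps (%.1f s), phases %s\n",
    x$surgery_id, x$source, length(x$labels), x$fps,
    duration_seconds(x),
    paste(sort(unique(x$labels)), collapse = ",")
  ))
  invisible(x)
}

# Seconds -> frames at a given rate, rounded to the nearest frame.
seconds_to_frames <- function(seconds, fps) {
  as.integer(round(seconds * fps))
}
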