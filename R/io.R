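#' Read a per-frame annotation CSV
#'
#' The annotation interchange format is a headered CSV with columns
#' `frame` (0-based, consecutive integers) and `phase` (integer 0-7), one
#' file per surgery. A sidecar JSON next to the CSV (same stem, `.json`)
#' may carry `surgery_id`, `fps` and `source`; without it the file stem,
#' 2 fps and source `"CNN"` are assumed.
#'
#' @param path Path of the annotation CSV.
#' @param surgery_id,fps,source Overrides for the sidecar/default metadata.
#' @return An [annotation_sequence()].
#' @export
read_annotation <- function(path, surgery_id = NULL, fps = NULL,
                            source = NULL) {
  df <- utils::read.csv(path, colClasses = "numeric")
  if (!all(c("frame", "phase") %in% names(df))) {
    stop("parse error in ", path, ": columns 'frame' and 'phase' required")
  }
  if (nrow(df) == 0L) stop("parse error in ", path, ": no frames")
  expected <- seq(0L, nrow(df) - 1L)
  if (!isTRUE(all.equal(df$frame, as.numeric(expected)))) {
    bad <- which(df$frame != expected)[1L]
    stop(sprintf(
      "parse error in %s, line %d: frame indices must be 0-based and consecutive (found %g)",
      path, bad + 1L, df$frame[bad]))
  }
  if (any(df$phase < 0 | df$phase > 7 | df$phase != floor(df$phase))) {
    bad <- which(df$phase < 0 | df$phase > 7 | df$phase != floor(df$phase))[1L]
    stop(sprintf("parse error in %s, line %d: invalid label %g",
                 path, bad + 1L, df$phase[bad]))
  }

  meta <- list(surgery_id = sub("\\.[^.]*$", "", basename(path)),
               fps = 2, source = "CNN")
  sidecar <- sub("\\.[^.]*$", ".json", path)
  if (file.exists(sidecar)) {
    meta[names(jsonlite::read_json(sidecar, simplifyVector = TRUE))] <-
      jsonlite::read_json(sidecar, simplifyVector = TRUE)
  }
  if (!is.null(surgery_id)) meta$surgery_id <- surgery_id
  if (!is.null(fps)) meta$fps <- fps
  if (!is.null(source)) meta$source <- source
  annotation_sequence(as.integer(df$phase), surgery_id = meta$surgery_id,
                      fps = meta$fps, source = meta$source)
}

#' Write a per-frame annotation CSV (with metadata sidecar)
#'
#' @param seq An [annotation_sequence()].
#' @param path Destination CSV path; the sidecar JSON is written next to it.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(seq, path) {
  stopifnot(inherits(seq, "annotation_sequence"))
  utils::write.csv(
    data.frame(frame = seq_along(seq$labels) - 1L, phase = seq$labels),
    path, row.names = FALSE, quote = FALSE
  )
  jsonlite::write_json(
    list(surgery_id = seq$surgery_id, fps = seq$fps, source = seq$source),
    sub("\\.[^.]*$", ".json", path), auto_unbox = TRUE
  )
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest is a JSON array of member records: `file` (annotation CSV,
#' relative to the manifest), `surgery_id`, `fps`, `source` and an optional
#' ground-truth `aberrant` flag used for ROC calibration.
#'
#' @param path Manifest JSON path.
#' @return A list with `sequences` (list of [annotation_sequence()]) and
#'   `aberrant` (logical vector, `NA` where no truth is recorded).
#' @export
read_manifest <- function(path) {
  entries <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(entries) == 0L) {
    stop("insufficient data: empty cohort manifest")
  }
  ids <- vapply(entries, function(e) e$surgery_id %||% "", character(1))
  if (anyDuplicated(ids[nzchar(ids)])) {
    stop("manifest error: duplicate surgery_id")
  }
  base <- dirname(path)
  sequences <- lapply(entries, function(e) {
    read_annotation(file.path(base, e$file),
                    surgery_id = e$surgery_id, fps = e$fps,
                    source = e$source)
  })
  aberrant <- vapply(entries, function(e) {
    if (is.null(e$aberrant)) NA else isTRUE(e$aberrant)
  }, logical(1))
  list(sequences = sequences, aberrant = aberrant)
}

#' Write a synthetic cohort to disk
#'
#' One annotation CSV + sidecar per surgery and a `manifest.json` carrying
#' the ground-truth aberrance flags, in the manifest format read back by
#' [read_manifest()].
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(seq_along(cohort$sequences), function(i) {
    s <- cohort$sequences[[i]]
    f <- paste0(s$surgery_id, ".csv")
    write_annotation(s, file.path(dir, f))
    list(file = f, surgery_id = s$surgery_id, fps = s$fps,
         source = s$source, aberrant = cohort$truth$aberrant[i])
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(entries, manifest, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the whole pipeline over a cohort
#'
#' Deterministic composition of the stages: flicker profiling of every
#' surgery, cohort phase-duration statistics (computed from the cohort
#' itself unless reference `stats` are supplied), per-phase IQR alerts,
#' the header flicker alert at the given cutoffs, and a report document
#' per surgery.
#'
#' @param sequences List of [annotation_sequence()] objects (at least 2
#'   when `stats` is not supplied).
#' @param cfg A [flicker_config()].
#' @param cutoff_groups,cutoff_frames Flicker-alert cutoffs (see
#'   [flicker_alert()]).
#' @param template A [report_template()].
#' @param stats Optional [cohort_stats()] reference; defaults to statistics
#'   of `sequences` themselves.
#' @param comments Optional list of per-surgery comment lists, named by
#'   surgery id (see [build_report()]).
#' @return A list of class `pipeline_result` with `stats` and `surgeries`
#'   (per surgery: `profile`, `alerts`, `flicker_alert`, `report`).
#' @export
run_pipeline <- function(sequences, cfg = flicker_config(),
                         cutoff_groups = 11.5, cutoff_frames = 212,
                         template = default_report_template(),
                         stats = NULL, comments = list()) {
  if (length(sequences) == 0L) stop("insufficient data: empty cohort")
  durations <- lapply(sequences, phase_durations)
  if (is.null(stats)) stats <- cohort_stats(durations)
  surgeries <- lapply(seq_along(sequences), function(i) {
    s <- sequences[[i]]
    res <- tryCatch({
      profile <- flicker_profile(s, cfg)
      alerts <- duration_alerts(durations[[i]], stats)
      fa <- flicker_alert(profile, cutoff_groups, cutoff_frames)
      report <- build_report(alerts, template,
                             comments = comments[[s$surgery_id]] %||% list(),
                             flicker_alert = fa, surgery_id = s$surgery_id)
      list(surgery_id = s$surgery_id, profile = profile, alerts = alerts,
           flicker_alert = fa, report = report)
    }, error = function(e) {
      stop(sprintf("surgery %s: %s", s$surgery_id, conditionMessage(e)),
           call. = FALSE)
    })
    res
  })
  names(surgeries) <- vapply(sequences, `[[`, character(1), "surgery_id")
  structure(list(stats = stats, surgeries = surgeries),
            class = "pipeline_result")
}
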