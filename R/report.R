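#' Report text template
#'
#' A template holds one standard text snippet per phase, a header template
#' (the placeholder `{surgery_id}` is substituted at build time) and the
#' prompt text shown with a raised flicker alert. The snippets shipped by
#' [default_report_template()] are generic English placeholders and are
#' meant to be replaced by institution-specific wording.
#'
#' @param header Header template string.
#' @param phases Character vector of exactly 8 standard snippets, in phase
#'   order P0..P7.
#' @param alert_prompt Text of the header flicker alert.
#' @return A list of class `report_template`.
#' @export
report_template <- function(header, phases, alert_prompt) {
  if (!is.character(phases) || length(phases) != 8L || anyNA(phases)) {
    stop("template error: exactly 8 phase snippets are required")
  }
  if (any(!nzchar(phases))) stop("template error: empty phase snippet")
  stopifnot(is.character(header), length(header) == 1L,
            is.character(alert_prompt), length(alert_prompt) == 1L)
  structure(list(header = header, phases = phases,
                 alert_prompt = alert_prompt),
            class = "report_template")
}

#' Default operative-note template
#'
#' @return A [report_template()] with placeholder snippets for the eight
#'   phases of laparoscopic cholecystectomy.
#' @export
default_report_template <- function() {
  report_template(
    header = "Operative note for laparoscopic cholecystectomy {surgery_id}.",
    phases = c(
      "The patient was positioned and the pneumoperitoneum was established; trocars were placed under vision.",
      "The hepatocystic triangle was exposed and the cystic duct and artery were dissected to obtain the critical view of safety.",
      "The cystic duct and the cystic artery were clipped and divided.",
      "The gallbladder was dissected from the liver bed using electrocautery.",
      "Hemostasis of the liver bed was verified; irrigation was performed as needed.",
      "The gallbladder was placed in a retrieval bag and extracted through the umbilical port.",
      "Final inspection confirmed hemostasis; the operative field was clean.",
      "Trocars were removed under vision and the incisions were closed; the patient tolerated the procedure well."
    ),
    alert_prompt = "Irregular phase annotation detected: please comment on the suspected intraoperative complication."
  )
}

#' Read or write a template as JSON
#'
#' @param path File path of a JSON object with keys `header`, `phases`
#'   (array of 8 strings) and `alert_prompt`.
#' @return `read_report_template()` returns a [report_template()];
#'   `write_report_template()` returns `path` invisibly.
#' @export
read_report_template <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  report_template(x$header, x$phases, x$alert_prompt)
}

#' @rdname read_report_template
#' @param template A [report_template()].
#' @export
write_report_template <- function(template, path) {
  stopifnot(inherits(template, "report_template"))
  jsonlite::write_json(unclass(template), path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' Build a report document from alerts, durations and comments
#'
#' Each phase becomes a section: `GREEN` when its duration alert is `OK`
#' (carrying the standard snippet verbatim), `RED` otherwise. A red section
#' carries the surgeon's comment when one is supplied; without a comment it
#' still carries the standard snippet but is flagged as requiring an edit.
#' A raised flicker alert goes to the header with the template's prompt and
#' likewise requires a comment. The document's `complete` flag is computed:
#' it is `TRUE` only when every red section and a raised flicker alert have
#' non-empty surgeon text.
#'
#' @param alerts An `alert_decision` from [duration_alerts()].
#' @param template A [report_template()].
#' @param comments Named list/character vector of surgeon comments; names
#'   are phase codes `"P0"` ... `"P7"`. A comment under `"flicker"`
#'   addresses the header alert.
#' @param flicker_alert Logical; whether the header flicker alert is raised
#'   (see [flicker_alert()]).
#' @param surgery_id Identifier substituted into the header.
#' @return A list of class `report_document` with `surgery_id`, `header`
#'   (`text`, `flicker_alert`, `comment`), `sections` (data frame: `phase`,
#'   `name`, `duration`, `status`, `text`, `edited`, `requires_edit`) and
#'   `complete`.
#' @export
build_report <- function(alerts, template = default_report_template(),
                         comments = list(), flicker_alert = FALSE,
                         surgery_id = "surgery") {
  stopifnot(inherits(alerts, "alert_decision"),
            inherits(template, "report_template"))
  comments <- as.list(comments)

  status <- ifelse(alerts$status == "OK", "GREEN", "RED")
  keys <- names(PHASE_LABELS)
  text <- template$phases
  edited <- logical(8L)
  for (i in seq_len(8L)) {
    cm <- comments[[keys[i]]]
    if (status[i] == "RED" && !is.null(cm) && nzchar(cm)) {
      text[i] <- cm
      edited[i] <- TRUE
    }
  }
  requires_edit <- status == "RED" & !edited

  fl_comment <- comments[["flicker"]]
  if (is.null(fl_comment)) fl_comment <- ""
  header_text <- gsub("{surgery_id}", surgery_id, template$header,
                      fixed = TRUE)

  complete <- !any(requires_edit) &&
    (!flicker_alert || nzchar(fl_comment))

  structure(
    list(
      surgery_id = surgery_id,
      header = list(text = header_text,
                    flicker_alert = isTRUE(flicker_alert),
                    alert_prompt = if (isTRUE(flicker_alert))
                      template$alert_prompt else "",
                    comment = fl_comment),
      sections = data.frame(
        phase = 0:7,
        name = phase_name(0:7),
        duration = alerts$duration,
        status = status,
        text = text,
        edited = edited,
        requires_edit = requires_edit
      ),
      complete = complete
    ),
    class = "report_document"
  )
}

#' Render a report document as text
#'
#' Two deterministic styles: `narrative` concatenates the section texts as
#' prose paragraphs in phase order; `synoptic` emits a labeled field list
#' (phase, duration, status, text). The same document and style always
#' render to identical bytes.
#'
#' @param doc A [build_report()] document.
#' @param style `"narrative"` or `"synoptic"`.
#' @return A single string (UTF-8, Markdown-flavored).
#' @export
render_report <- function(doc, style = c("narrative", "synoptic")) {
  stopifnot(inherits(doc, "report_document"))
  style <- match.arg(style)
  s <- doc$sections
  header <- doc$header$text
  if (doc$header$flicker_alert) {
    header <- paste0(header, "\n\n**ALERT:** ", doc$header$alert_prompt)
    if (nzchar(doc$header$comment)) {
      header <- paste0(header, "\nSurgeon's comment: ", doc$header$comment)
    }
  }
  body <- if (style == "narrative") {
    paste(sprintf("%s (%.0f s). %s", s$name, s$duration, s$text),
          collapse = "\n\n")
  } else {
    paste(sprintf(
      "Phase: P%d %s\nDuration: %.0f s\nStatus: %s\nText: %s",
      s$phase, s$name, s$duration,
      ifelse(s$status == "GREEN", "OK", "ALERT"), s$text
    ), collapse = "\n\n")
  }
  footer <- if (doc$complete) "" else
    "\n\n[INCOMPLETE: sections flagged for surgeon comment remain unedited]"
  paste0(header, "\n\n", body, footer, "\n")
}

#' @export
print.report_document <- function(x, ...) {
  cat(sprintf(
    "<report_document> %s: %d/8 sections green, flicker alert %s, %s\n",
    x$surgery_id, sum(x$sections$status == "GREEN"),
    if (x$header$flicker_alert) "RAISED" else "clear",
    if (x$complete) "complete" else "INCOMPLETE"
  ))
  invisible(x)
}
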