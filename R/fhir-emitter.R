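# Decision-rule XML generation. Each individual decision rule carries an
# individual action and gets its own XML file, organized per the
# decision-support-rule resource as five elements: action, condition,
# moduleMetadata, library, trigger. The element set is frozen as a local
# schema (inst/schemas/decision_rule.xsd); this avoids tracking drift in
# live FHIR releases, and element-level fidelity — not byte fidelity to
# any particular rendering — is the contract. XML is the one output
# format; JSON and Turtle renderings are deliberately not implemented.

ACTION_APPLY <- "Rule can be applied"
ACTION_NO_APPLY <- "Rule cannot be applied"

#' Structured decision-rule (ELM-style) document
#'
#' @param action_text `"Rule can be applied"` (the procedure is
#'   appropriate) or `"Rule cannot be applied"` (it is not).
#' @param condition_ref name of the final CQL define that gates the
#'   action (normally `MeetsInclusionCriteria`).
#' @param module_metadata a [source_meta()].
#' @param library_ref name of the CQL library holding the logic.
#' @param trigger descriptor of the clinical order/event that fires the
#'   rule; an opaque string, defined by the implementation environment
#'   rather than by CQL.
#' @return object of class `elm_document`.
#' @export
elm_document <- function(action_text, condition_ref, module_metadata,
                         library_ref, trigger) {
  if (!action_text %in% c(ACTION_APPLY, ACTION_NO_APPLY))
    cels_error(sprintf("invalid action text %s", deparse(action_text)),
               "elm_error")
  structure(list(action_text = action_text, condition_ref = condition_ref,
                 module_metadata = module_metadata, library_ref = library_ref,
                 trigger = trigger),
            class = "elm_document")
}

#' Emit the decision-rule document for a compiled CELS
#'
#' A recommending CELS ("Then") yields action "Rule can be applied"; a
#' non-recommending one ("Then Not") yields "Rule cannot be applied".
#' The condition element references the CQL document's final define and
#' the library element its library name; the trigger is the action
#' procedure term.
#'
#' @param x the [cels] the document was compiled from.
#' @param doc the [cql_document()] emitted from `x` (pairing is checked).
#' @param meta optional [source_meta()]; defaults to the CELS metadata
#'   or a placeholder.
#' @return an [elm_document()].
#' @export
emit_elm <- function(x, doc, meta = NULL) {
  if (!identical(doc$library_name, slugify(x$id, sep = "")))
    cels_error(sprintf(
      "CQL document (library %s) was not emitted from CELS %s",
      doc$library_name, x$id), "elm_error")
  meta <- meta %||% x$metadata %||%
    source_meta("Unspecified evidence source")
  final_define <- names(doc$defines)[length(doc$defines)]
  elm_document(
    action_text = if (x$polarity == "recommend") ACTION_APPLY else ACTION_NO_APPLY,
    condition_ref = final_define,
    module_metadata = meta,
    library_ref = doc$library_name,
    trigger = x$action$procedure
  )
}

#' Render a decision-rule document as XML
#'
#' Deterministic serialization: UTF-8, 2-space indent, fixed element
#' order. The result is well-formed and valid against the packaged
#' schema; rendering the same document twice gives identical bytes.
#'
#' @param elm an [elm_document()].
#' @return a single XML string.
#' @export
render_xml <- function(elm) {
  m <- elm$module_metadata
  xml <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    "<decisionSupportRule>",
    sprintf("  <action>%s</action>", xml_escape(elm$action_text)),
    sprintf("  <condition value=\"%s\"/>", xml_escape(elm$condition_ref)),
    "  <moduleMetadata>",
    sprintf("    <title>%s</title>", xml_escape(m$source_title)),
    sprintf("    <authors>%s</authors>", xml_escape(m$authors %||% "")),
    sprintf("    <year>%s</year>", xml_escape(m$year %||% "")),
    sprintf("    <evidenceKind>%s</evidenceKind>",
            xml_escape(m$evidence_kind %||% "guideline")),
    "  </moduleMetadata>",
    sprintf("  <library>%s</library>", xml_escape(elm$library_ref)),
    sprintf("  <trigger>%s</trigger>", xml_escape(elm$trigger)),
    "</decisionSupportRule>"
  )
  paste0(paste(xml, collapse = "\n"), "\n")
}

#' Validate decision-rule XML against the packaged schema
#'
#' @param text XML text (or a file path to an XML document).
#' @return `TRUE` when valid; otherwise `FALSE` with the schema errors
#'   attached as attribute `"errors"`.
#' @export
validate_decision_rule_xml <- function(text) {
  schema_path <- system.file("schemas", "decision_rule.xsd", package = "celsify")
  schema <- xml2::read_xml(schema_path)
  doc <- xml2::read_xml(text)
  xml2::xml_validate(doc, schema)
}

#' Parse decision-rule XML back into its structured form
#'
#' Inverse of [render_xml()]: `parse_elm_xml(render_xml(e))` is
#' structurally identical to `e`.
#'
#' @param text XML text or path.
#' @return an [elm_document()].
#' @export
parse_elm_xml <- function(text) {
  doc <- xml2::read_xml(text)
  grab <- function(xp) xml2::xml_text(xml2::xml_find_first(doc, xp))
  meta <- source_meta(
    source_title = grab("/decisionSupportRule/moduleMetadata/title"),
    authors = grab("/decisionSupportRule/moduleMetadata/authors"),
    year = grab("/decisionSupportRule/moduleMetadata/year"),
    evidence_kind = grab("/decisionSupportRule/moduleMetadata/evidenceKind"))
  elm_document(
    action_text = grab("/decisionSupportRule/action"),
    condition_ref = xml2::xml_attr(
      xml2::xml_find_first(doc, "/decisionSupportRule/condition"), "value"),
    module_metadata = meta,
    library_ref = grab("/decisionSupportRule/library"),
    trigger = grab("/decisionSupportRule/trigger"))
}

#' Compile an evidence unit into its artifact bundle
#'
#' Compiles every CELS of a unit and writes exactly one `.cql` and one
#' `.xml` file per statement plus a `manifest.json` listing the pairs.
#' Compile failures are collected with per-CELS attribution and
#' re-signalled together.
#'
#' @param unit list of [cels] (one evidence unit; possibly empty).
#' @param t a [terminology].
#' @param meta optional shared [source_meta()].
#' @param out_dir output directory (created if missing).
#' @return invisibly, the manifest: a list with one
#'   `list(id, cql, xml)` entry per CELS.
#' @export
bundle_artifacts <- function(unit, t, meta = NULL, out_dir = ".") {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  failures <- character(0)
  for (x in unit) {
    res <- tryCatch({
      doc <- emit_cql(x, t, meta = meta)
      elm <- emit_elm(x, doc, meta = meta)
      cql_file <- paste0(x$id, ".cql")
      xml_file <- paste0(x$id, ".xml")
      writeLines(render_cql(doc), file.path(out_dir, cql_file),
                 sep = "", useBytes = TRUE)
      writeLines(render_xml(elm), file.path(out_dir, xml_file),
                 sep = "", useBytes = TRUE)
      list(id = x$id, cql = cql_file, xml = xml_file)
    }, cels_compile_error = function(e) {
      failures <<- c(failures, sprintf("%s: %s", x$id, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) manifest[[length(manifest) + 1L]] <- res
  }
  if (length(failures))
    compile_error(paste0("bundle failed for ", length(failures), " CELS:\n  ",
                         paste(failures, collapse = "\n  ")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
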