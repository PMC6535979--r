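# CQL generation. A CELS compiles to one CQL library organized into the
# six customary categories: Library, Using, Code System, Value Set,
# Context, Define. One define per condition, then a final define
# ("MeetsInclusionCriteria") that conjoins them all: the conditions that
# must hold for the "Then" portion to apply.
#
# The data model named in the "using" header is QUICK; retrieve
# expressions are emitted as opaque templated strings, not a full QUICK
# field mapping, and no CQL engine execution or type-checking is
# attempted.

CQL_VERSION <- "1.4"
QUICK_VERSION <- "3.3.0"
SNOMED_URL <- "http://snomed.info/sct"

#' Structured CQL document
#'
#' @param library_name library identifier.
#' @param version library version string.
#' @param using_model,using_version data model reference.
#' @param code_systems list of `list(name=, id=)`.
#' @param value_sets list of [value_set()] objects.
#' @param context `"Patient"` or `"Population"`.
#' @param defines named ordered list of define expressions; the last
#'   entry must conjoin all condition defines.
#' @return object of class `cql_document`.
#' @export
cql_document <- function(library_name, version = "1.0.0",
                         using_model = "QUICK", using_version = QUICK_VERSION,
                         code_systems = list(), value_sets = list(),
                         context = c("Patient", "Population"),
                         defines = list()) {
  context <- match.arg(context)
  if (anyDuplicated(names(defines)))
    cels_error("define names must be unique", "cql_error")
  structure(list(library_name = library_name, version = version,
                 using_model = using_model, using_version = using_version,
                 code_systems = code_systems, value_sets = value_sets,
                 context = context, defines = defines),
            class = "cql_document")
}

#' @export
print.cql_document <- function(x, ...) {
  cat(render_cql(x))
  invisible(x)
}

#' Error signalled when a CELS cannot compile
#' @keywords internal
compile_error <- function(msg, unmapped = character(0)) {
  stop(structure(
    class = c("cels_compile_error", "cels_error", "error", "condition"),
    list(message = msg, call = NULL, unmapped = unmapped)
  ))
}

# Unique define name for a condition term: slugified, de-duplicated with
# numeric suffixes ("NoduleSize", "NoduleSize2", ...).
define_name <- function(term, taken) {
  base <- slugify(term)
  name <- base
  k <- 1L
  while (name %in% taken) {
    k <- k + 1L
    name <- paste0(base, k)
  }
  name
}

condition_expression <- function(cond, vs_name) {
  expr <- sprintf("exists ([Condition: \"%s\"])", vs_name)
  if (!is.null(cond$comparator)) {
    unit <- if (is.null(cond$unit)) "" else sprintf(" '%s'", cond$unit)
    expr <- sprintf(
      "exists ([Observation: \"%s\"] O where O.value %s %s%s)",
      vs_name, cond$comparator, format_num(cond$value), unit)
  }
  if (!is.null(cond$temporal) && cond$temporal$direction == "past") {
    seg <- cond$temporal$segments[[1L]]
    expr <- sprintf(
      "exists ([Procedure: \"%s\"] P where P.performed during Interval[Today() - %s months, Today()])",
      vs_name, format_num(seg[2]))
  }
  if (cond$negated) expr <- paste("not", expr)
  expr
}

#' Compile a CELS into a CQL document
#'
#' Every condition term and the action procedure term must map in the
#' terminology; otherwise a compile error carrying the unmapped terms is
#' signalled. Each mapped term contributes a value set holding its
#' concept ids and a define; the final define, `MeetsInclusionCriteria`,
#' conjoins every condition define with the statement's connectives.
#' Past-looking condition temporals render as lookback clauses. A
#' future-temporal action is rejected here: representing it is exactly
#' what the CQL framework cannot do, and diagnosing that is the
#' auditor's job, not the emitter's.
#'
#' @param x a [cels].
#' @param t a [terminology].
#' @param meta optional [source_meta()] (defaults to the CELS metadata).
#' @return a [cql_document()].
#' @examples
#' t <- terminology(data.frame(
#'   term = c("Suspected PE", "VQ SPECT"),
#'   concept_ids = c("417113001", "900000000001"),
#'   match_type = "precoordinated"))
#' doc <- emit_cql(parse_cels("If [Suspected PE] Then [VQ SPECT]"), t)
#' names(doc$defines)
#' @export
emit_cql <- function(x, t, meta = NULL) {
  issues <- validate_cels(x)
  if (length(issues))
    compile_error(paste0("invalid CELS: ", paste(issues, collapse = "; ")))
  meta <- meta %||% x$metadata
  terms <- c(vapply(x$conditions, `[[`, character(1), "term"),
             x$action$procedure)
  matches <- lapply(terms, map_term, t = t)
  unmapped <- terms[vapply(matches, inherits, logical(1), "unmapped_term")]
  if (length(unmapped))
    compile_error(sprintf("unmapped term(s): %s",
                          paste(unique(unmapped), collapse = ", ")),
                  unmapped = unique(unmapped))
  if (!is.null(x$action$temporal) && x$action$temporal$direction == "future")
    compile_error(sprintf(
      "action '%s %s' has a future temporal component, which CQL cannot express",
      x$action$procedure, render_temporal(x$action$temporal)))

  value_sets <- list()
  defines <- list()
  cond_names <- character(0)
  for (i in seq_along(x$conditions)) {
    cond <- x$conditions[[i]]
    cm <- matches[[i]]
    vs <- value_set(normalize_term(cond$term), "extensional",
                    members = cm$concept_ids)
    # one value set per distinct term
    if (!vs$name %in% vapply(value_sets, `[[`, character(1), "name"))
      value_sets <- c(value_sets, list(vs))
    nm <- define_name(cond$term, names(defines))
    defines[[nm]] <- condition_expression(cond, vs$name)
    cond_names <- c(cond_names, nm)
  }
  final <- paste(sprintf("\"%s\"", cond_names),
                 collapse = NULL)
  ops <- if (length(cond_names) > 1L) tolower(x$connectives) else character(0)
  expr <- final[1L]
  for (i in seq_along(ops)) expr <- paste(expr, ops[i], final[i + 1L])
  defines[["MeetsInclusionCriteria"]] <- expr

  cql_document(
    library_name = slugify(x$id, sep = ""),
    code_systems = list(list(name = "SNOMED-CT", id = SNOMED_URL)),
    value_sets = value_sets,
    context = "Patient",
    defines = defines
  )
}

#' Render a CQL document as text
#'
#' Deterministic, byte-stable rendering in the fixed section order
#' Library, Using, Code System, Value Set, Context, Define. Extensional
#' value-set members are listed inline; UTF-8 with LF line endings.
#'
#' @param doc a [cql_document()].
#' @return a single string ending in a newline.
#' @export
render_cql <- function(doc) {
  if (length(doc$defines) == 0L)
    cels_error("cannot render a CQL document with no defines", "cql_error")
  lines <- c(
    sprintf("// cql-version %s", CQL_VERSION),
    sprintf("library %s version '%s'", doc$library_name, doc$version),
    "",
    sprintf("using %s version '%s'", doc$using_model, doc$using_version),
    "",
    vapply(doc$code_systems, function(cs)
      sprintf("codesystem \"%s\": '%s'", cs$name, cs$id), character(1))
  )
  if (length(doc$value_sets)) {
    lines <- c(lines, "", vapply(doc$value_sets, function(vs) {
      if (vs$kind == "extensional")
        sprintf("valueset \"%s\": { %s }", vs$name,
                paste(sprintf("'%s'", vs$members), collapse = ", "))
      else
        sprintf("valueset \"%s\": descendants-of '%s'", vs$name, vs$root)
    }, character(1)))
  }
  lines <- c(lines, "", sprintf("context %s", doc$context), "")
  for (nm in names(doc$defines)) {
    lines <- c(lines, sprintf("define \"%s\":", nm),
               sprintf("  %s", doc$defines[[nm]]), "")
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Split rendered CQL text back into its six categories
#'
#' A light section splitter used to check that rendered documents carry
#' every category; not a CQL parser.
#'
#' @param text CQL text from [render_cql()].
#' @return named list of character vectors, one per category found
#'   (`library`, `using`, `codesystem`, `valueset`, `context`, `define`).
#' @export
split_cql_sections <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  picks <- function(rx) grep(rx, lines, value = TRUE)
  list(library = picks("^library "),
       using = picks("^using "),
       codesystem = picks("^codesystem "),
       valueset = picks("^valueset "),
       context = picks("^context "),
       define = picks("^define "))
}
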