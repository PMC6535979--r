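# Representability audit. A CELS is fully represented when (a) every
# surface term — each condition term and the action procedure term —
# maps in the terminology, and (b) the action carries no future temporal
# component. Failures are classified into a three-way taxonomy:
#   clinical_term   — a clinical term (typically a named score or rule)
#                     absent from the terminology;
#   english_phrase  — an ordinary-English phrase ("vehicle rollover")
#                     that a clinical ontology does not model;
#   temporal_action — a future-looking or recurring action schedule
#                     ("CT chest in 6-12 months", "annually for 3
#                     years") that CQL/ELM cannot express. Past
#                     lookbacks on conditions are fine; the gap is
#                     specific to running an action at a future time.
# The first two make a statement partially represented with respect to
# the terminology (partial_snomed); the third with respect to the logic
# language (partial_cql). The flags are non-exclusive.

#' Detect a future temporal component on an action
#'
#' Fires on future windows ("in 12 months", "in 6-12 months"),
#' multi-point schedules ("in 3 months, 9 months, And 24 months") and
#' recurrences ("annually for 3 years"), whether carried as a structured
#' [temporal_spec()] or embedded in the procedure string. A phrase that
#' looks temporal but does not parse yields a `raw_unparsed` finding.
#'
#' @param a an [action_spec()].
#' @return `NULL` when the action has no future temporal component;
#'   otherwise a `temporal_finding`: a list with `category`
#'   (`"temporal_action"` or `"raw_unparsed"`), `text` (the offending
#'   phrase) and `temporal` (the parsed [temporal_spec()], or `NULL`
#'   when unparseable).
#' @examples
#' detect_future_temporal(action_spec("VQ SPECT"))
#' detect_future_temporal(parse_cels(
#'   "If [high risk] Then [CT chest in 12 months]")$action)
#' @export
detect_future_temporal <- function(a) {
  finding <- function(category, text, temporal = NULL) {
    structure(list(category = category, text = text, temporal = temporal),
              class = "temporal_finding")
  }
  if (!is.null(a$temporal) && a$temporal$direction == "future")
    return(finding("temporal_action",
                   paste(a$procedure, render_temporal(a$temporal)),
                   a$temporal))
  sp <- split_action_temporal(a$procedure)
  if (identical(sp$temporal, "raw"))
    return(finding("raw_unparsed", a$procedure))
  if (!is.null(sp$temporal) && sp$temporal$direction == "future")
    return(finding("temporal_action", a$procedure, sp$temporal))
  NULL
}

# Procedure term with any temporal phrase stripped, for terminology
# lookup ("CT chest in 12 months" -> "CT chest": the procedure itself
# may well map even when its schedule cannot be expressed).
action_lookup_term <- function(a) {
  sp <- split_action_temporal(a$procedure)
  if (identical(sp$temporal, "raw")) {
    m <- regmatches(a$procedure,
                    regexec("^(.*[^ ]) in ", a$procedure))[[1]]
    if (length(m)) return(m[2])
  }
  sp$procedure
}

#' Audit one CELS for representability
#'
#' @param x a [cels].
#' @param t a [terminology].
#' @return an `audit_result`: list with `cels_id`, logical flags
#'   `fully_represented`, `partial_snomed`, `partial_cql`, and `reasons`
#'   — a list of `list(category, text)` entries, empty iff fully
#'   represented.
#' @examples
#' t <- terminology(data.frame(term = c("Suspected PE", "VQ SPECT"),
#'                             concept_ids = c("417113001", "900000000001"),
#'                             match_type = "precoordinated"))
#' audit_cels(parse_cels("If [Suspected PE] Then [VQ SPECT]"), t)$fully_represented
#' @export
audit_cels <- function(x, t) {
  reasons <- list()
  seen <- character(0)
  for (cond in x$conditions) {
    if (term_key(cond$term) %in% seen) next
    seen <- c(seen, term_key(cond$term))
    m <- map_term(cond$term, t)
    if (inherits(m, "unmapped_term"))
      reasons <- c(reasons, list(list(category = m$reason, text = cond$term)))
  }
  act_term <- action_lookup_term(x$action)
  act_match <- map_term(act_term, t)
  if (inherits(act_match, "unmapped_term"))
    reasons <- c(reasons, list(list(category = act_match$reason,
                                    text = act_term)))
  partial_snomed <- length(reasons) > 0L

  tf <- detect_future_temporal(x$action)
  if (!is.null(tf))
    reasons <- c(reasons, list(list(category = "temporal_action",
                                    text = tf$text)))
  partial_cql <- !is.null(tf)

  structure(
    list(cels_id = x$id,
         fully_represented = !partial_snomed && !partial_cql,
         partial_snomed = partial_snomed,
         partial_cql = partial_cql,
         action_term_mapped = inherits(act_match, "concept_match"),
         reasons = reasons),
    class = "audit_result"
  )
}

#' @export
print.audit_result <- function(x, ...) {
  status <- if (x$fully_represented) "fully represented" else
    paste(c(if (x$partial_snomed) "partial (terminology)",
            if (x$partial_cql) "partial (temporal action)"), collapse = " + ")
  cat(sprintf("<audit> %s: %s\n", x$cels_id, status))
  for (r in x$reasons)
    cat(sprintf("  - %s: %s\n", r$category, r$text))
  invisible(x)
}

#' Audit a CELS corpus and tally representability
#'
#' Flags are tallied independently (they are non-exclusive, so category
#' counts may sum to more than the total). Percentages are
#' `100 * n / total`, rounded half-up to one decimal. The action-term
#' representability metric is the fraction of statements whose action
#' procedure term (temporal phrase stripped) maps in the terminology,
#' independent of any temporal finding.
#'
#' @param corpus non-empty list of [cels].
#' @param t a [terminology].
#' @return a `corpus_report`: counts `total`, `n_full`,
#'   `n_partial_snomed`, `n_partial_cql`, `n_action_mapped`; percentages
#'   `pct_full`, `pct_partial_snomed`, `pct_partial_cql`,
#'   `pct_action_terms_representable`; and `results`, the per-statement
#'   `audit_result` list.
#' @export
audit_corpus <- function(corpus, t) {
  if (length(corpus) == 0L)
    cels_error("cannot audit an empty corpus", "cels_invalid_error")
  results <- lapply(corpus, audit_cels, t = t)
  n <- length(results)
  n_full <- sum(vapply(results, `[[`, logical(1), "fully_represented"))
  n_snomed <- sum(vapply(results, `[[`, logical(1), "partial_snomed"))
  n_cql <- sum(vapply(results, `[[`, logical(1), "partial_cql"))
  n_act <- sum(vapply(results, `[[`, logical(1), "action_term_mapped"))
  structure(
    list(total = n, n_full = n_full, n_partial_snomed = n_snomed,
         n_partial_cql = n_cql, n_action_mapped = n_act,
         pct_full = round_half_up(100 * n_full / n, 1),
         pct_partial_snomed = round_half_up(100 * n_snomed / n, 1),
         pct_partial_cql = round_half_up(100 * n_cql / n, 1),
         pct_action_terms_representable = round_half_up(100 * n_act / n, 1),
         results = results),
    class = "corpus_report"
  )
}

report_row_labels <- c(
  "CELS fully represented using SNOMED CT, CQL, and FHIR",
  "CELS partially represented using SNOMED CT",
  "CELS partially represented due to CQL"
)

#' Corpus report as a three-row summary table
#'
#' @param report a `corpus_report`.
#' @return data frame with columns `type`, `n`, `pct`; one row per
#'   representability category.
#' @export
report_table <- function(report) {
  data.frame(
    type = report_row_labels,
    n = c(report$n_full, report$n_partial_snomed, report$n_partial_cql),
    pct = c(report$pct_full, report$pct_partial_snomed, report$pct_partial_cql),
    stringsAsFactors = FALSE
  )
}

#' @export
print.corpus_report <- function(x, ...) {
  cat(sprintf("<corpus report> N=%d\n", x$total))
  tab <- report_table(x)
  for (i in seq_len(nrow(tab)))
    cat(sprintf("  %-55s %4d (%.1f%%)\n", tab$type[i], tab$n[i], tab$pct[i]))
  cat(sprintf("  %-55s %4d (%.1f%%)\n", "Action terms representable",
              x$n_action_mapped, x$pct_action_terms_representable))
  invisible(x)
}

#' Write a corpus report to JSON and/or TSV
#'
#' @param report a `corpus_report`.
#' @param json_path,tsv_path output paths (`NULL` to skip either).
#' @return invisibly, the report.
#' @export
write_report <- function(report, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- report[c("total", "n_full", "n_partial_snomed", "n_partial_cql",
                        "n_action_mapped", "pct_full", "pct_partial_snomed",
                        "pct_partial_cql", "pct_action_terms_representable")]
    payload$statements <- lapply(report$results, function(r)
      list(cels_id = r$cels_id, fully_represented = r$fully_represented,
           partial_snomed = r$partial_snomed, partial_cql = r$partial_cql,
           reasons = r$reasons))
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(report_table(report), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(report)
}
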