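# Evidence units come in three logic variants: single-decision
# statements, branching statements, and score-based statements.
# Branching units are authored as binary decision trees whose leaves
# each become one CELS; score-based units are authored as banded rules
# over an evidence-based score, one CELS per band.

# ---- decision trees ---------------------------------------------------------

#' Decision-tree leaf: a recommendation end point
#' @param action an [action_spec()] (a bare string is coerced).
#' @param polarity `"recommend"` or `"not_recommend"`.
#' @return object of class `decision_leaf`/`decision_tree`.
#' @export
decision_leaf <- function(action, polarity = c("recommend", "not_recommend")) {
  polarity <- match.arg(polarity)
  if (is.character(action)) action <- action_spec(action)
  structure(list(action = action, polarity = polarity),
            class = c("decision_leaf", "decision_tree"))
}

#' Decision-tree internal node: a condition with true/false branches
#' @param cond a [condition()] (a bare string is coerced to a term-only
#'   condition).
#' @param yes subtree taken when the condition holds.
#' @param no subtree taken when it does not.
#' @return object of class `decision_node`/`decision_tree`.
#' @export
decision_node <- function(cond, yes, no) {
  if (is.character(cond)) cond <- condition(cond)
  stopifnot(inherits(yes, "decision_tree"), inherits(no, "decision_tree"))
  structure(list(condition = cond, yes = yes, no = no),
            class = c("decision_node", "decision_tree"))
}

#' Read a decision tree from JSON
#'
#' Nodes are objects `{"condition": {...}, "yes": ..., "no": ...}`;
#' leaves are `{"action": {"procedure": ...}, "polarity": ...}`.
#' Condition and action objects use the CELS JSON field names.
#'
#' @param x a file path or an already-parsed list.
#' @return a `decision_tree`.
#' @export
tree_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  build <- function(node) {
    if (!is.null(node$action)) {
      act <- action_spec(node$action$procedure,
                         temporal = temporal_from_list(node$action$temporal),
                         flagged = isTRUE(node$action$flagged))
      return(decision_leaf(act, node$polarity %||% "recommend"))
    }
    if (is.null(node$condition) || is.null(node$yes) || is.null(node$no))
      cels_error("malformed decision-tree node: need condition, yes, no",
                 "cels_invalid_error")
    cond <- node$condition
    decision_node(
      condition(cond$term, comparator = cond$comparator, value = cond$value,
                unit = cond$unit, negated = isTRUE(cond$negated),
                flagged = isTRUE(cond$flagged)),
      build(node$yes), build(node$no))
  }
  build(x)
}

negate_condition <- function(cond) {
  cond$negated <- !cond$negated
  cond
}

#' Flatten a decision tree into one CELS per leaf
#'
#' Each root-to-leaf path becomes one CELS whose conditions are the
#' conditions met along the path, with false-branch conditions negated
#' (condition-level `Not`). Leaves are emitted depth-first, true branch
#' first, so the output order is deterministic.
#'
#' @param tree a `decision_tree`.
#' @param id_prefix prefix for generated CELS ids (`<prefix>-1`, ...).
#' @param metadata optional [source_meta()] shared by all leaves.
#' @return list of [cels], one per leaf.
#' @examples
#' tree <- decision_node("Pregnant",
#'                       decision_leaf("VQ SPECT"),
#'                       decision_leaf("CTPA"))
#' length(flatten_decision_tree(tree))
#' @export
flatten_decision_tree <- function(tree, id_prefix = "leaf", metadata = NULL) {
  if (!inherits(tree, "decision_tree"))
    cels_error("not a decision tree", "cels_invalid_error")
  out <- list()
  walk <- function(node, path) {
    if (inherits(node, "decision_leaf")) {
      if (length(path) == 0L)
        cels_error("a single-leaf tree has no conditions to flatten into a CELS",
                   "cels_invalid_error")
      out[[length(out) + 1L]] <<- cels(
        path, node$action, polarity = node$polarity,
        id = sprintf("%s-%d", id_prefix, length(out) + 1L),
        metadata = metadata)
      return(invisible(NULL))
    }
    walk(node$yes, c(path, list(node$condition)))
    walk(node$no, c(path, list(negate_condition(node$condition))))
  }
  if (inherits(tree, "decision_leaf")) {
    # Degenerate tree: one unconditional recommendation. Rendered with the
    # vacuous condition "Any patient" so it is still a well-formed CELS.
    return(list(cels(list(condition("Any patient")), tree$action,
                     polarity = tree$polarity, id = paste0(id_prefix, "-1"),
                     metadata = metadata)))
  }
  walk(tree, list())
  out
}

#' Count the leaves of a decision tree
#' @param tree a `decision_tree`.
#' @return integer leaf count.
#' @export
count_leaves <- function(tree) {
  if (inherits(tree, "decision_leaf")) return(1L)
  count_leaves(tree$yes) + count_leaves(tree$no)
}

# ---- score rules ------------------------------------------------------------

#' One band of a score-based rule
#' @param action an [action_spec()] or procedure string.
#' @param polarity `"recommend"` or `"not_recommend"`.
#' @param lower,upper band bounds (may be `-Inf`/`Inf`; at least one
#'   must be finite).
#' @param lower_incl,upper_incl logical; whether each bound is included.
#' @return object of class `score_band`.
#' @export
score_band <- function(action, polarity = c("recommend", "not_recommend"),
                       lower = -Inf, upper = Inf,
                       lower_incl = TRUE, upper_incl = TRUE) {
  polarity <- match.arg(polarity)
  if (is.character(action)) action <- action_spec(action)
  if (!is.finite(lower) && !is.finite(upper))
    cels_error("a score band needs at least one finite bound", "cels_invalid_error")
  lo <- if (is.finite(lower)) lower else -Inf
  hi <- if (is.finite(upper)) upper else Inf
  if (lo > hi || (lo == hi && !(lower_incl && upper_incl)))
    cels_error("score band bounds are not well-ordered", "cels_invalid_error")
  structure(list(lower = lower, upper = upper,
                 lower_incl = isTRUE(lower_incl), upper_incl = isTRUE(upper_incl),
                 action = action, polarity = polarity),
            class = "score_band")
}

band_key <- function(b) {
  # ordering key treating an excluded bound as shifted infinitesimally
  c(b$lower, if (b$lower_incl) 0 else 1)
}

bands_overlap <- function(a, b) {
  # overlap test on two bands (a before b by lower bound)
  if (b$lower > a$upper) return(FALSE)
  if (b$lower < a$upper) return(TRUE)
  a$upper_incl && b$lower_incl
}

#' A score-based evidence unit
#'
#' @param score_term surface term of the evidence-based score (e.g.
#'   `"Alvarado score"`).
#' @param bands list of [score_band()]s; must be pairwise non-overlapping.
#' @param shared_conditions list of [condition()]s prepended to every
#'   emitted CELS.
#' @param flagged logical; asterisk-annotate the score term (the usual
#'   case: named scores rarely exist in standard terminologies).
#' @return object of class `score_rule`.
#' @export
score_rule <- function(score_term, bands, shared_conditions = list(),
                       flagged = FALSE) {
  if (length(bands) == 0L)
    cels_error("a score rule needs at least one band", "cels_invalid_error")
  ord <- order(vapply(bands, function(b) b$lower, numeric(1)),
               vapply(bands, function(b) !b$lower_incl, logical(1)))
  sorted <- bands[ord]
  if (length(sorted) > 1L) {
    for (i in seq_len(length(sorted) - 1L)) {
      if (bands_overlap(sorted[[i]], sorted[[i + 1L]]))
        cels_error(sprintf("score bands %d and %d overlap", i, i + 1L),
                   "cels_invalid_error")
    }
  }
  structure(list(score_term = normalize_term(score_term), bands = bands,
                 shared_conditions = shared_conditions,
                 flagged = isTRUE(flagged)),
            class = "score_rule")
}

#' Read a score rule from JSON
#' @param x a file path or parsed list with fields `score_term`,
#'   `bands` (each with `lower`, `upper`, `lower_incl`, `upper_incl`,
#'   `action`, `polarity`), optional `shared_conditions` and `flagged`.
#' @return a `score_rule`.
#' @export
score_rule_from_json <- function(x) {
  if (is.character(x)) x <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  bands <- lapply(x$bands, function(b) {
    score_band(action_spec(b$action$procedure,
                           flagged = isTRUE(b$action$flagged)),
               polarity = b$polarity %||% "recommend",
               lower = if (is.null(b$lower)) -Inf else as.numeric(b$lower),
               upper = if (is.null(b$upper)) Inf else as.numeric(b$upper),
               lower_incl = isTRUE(b$lower_incl %||% TRUE),
               upper_incl = isTRUE(b$upper_incl %||% TRUE))
  })
  shared <- lapply(x$shared_conditions %||% list(), function(cond) {
    condition(cond$term, comparator = cond$comparator, value = cond$value,
              unit = cond$unit, negated = isTRUE(cond$negated),
              flagged = isTRUE(cond$flagged))
  })
  score_rule(x$score_term, bands, shared_conditions = shared,
             flagged = isTRUE(x$flagged))
}

#' Expand a score rule into one CELS per band
#'
#' A band's bounds become one or two comparator conditions on the score
#' term: an included lower bound renders as `>=`, an excluded one as
#' `>`, and symmetrically `<=`/`<` for the upper bound. Shared
#' conditions are prepended. Bands are emitted in ascending order.
#'
#' @param rule a [score_rule()].
#' @param id_prefix prefix for generated CELS ids.
#' @param metadata optional shared [source_meta()].
#' @return list of [cels], one per band.
#' @examples
#' r <- score_rule("Alvarado score", list(
#'   score_band("CT Abdomen", "not_recommend", upper = 4, upper_incl = FALSE),
#'   score_band("CT abdomen", "recommend", lower = 4, upper = 6),
#'   score_band("CT Abdomen", "not_recommend", lower = 6, lower_incl = FALSE)),
#'   flagged = TRUE)
#' vapply(expand_score_rule(r), serialize_cels, character(1))
#' @export
expand_score_rule <- function(rule, id_prefix = "band", metadata = NULL) {
  ord <- order(vapply(rule$bands, function(b) b$lower, numeric(1)),
               vapply(rule$bands, function(b) !b$lower_incl, logical(1)))
  out <- vector("list", length(rule$bands))
  for (i in seq_along(ord)) {
    b <- rule$bands[[ord[i]]]
    conds <- rule$shared_conditions
    if (is.finite(b$lower))
      conds <- c(conds, list(condition(
        rule$score_term, comparator = if (b$lower_incl) ">=" else ">",
        value = b$lower, flagged = rule$flagged)))
    if (is.finite(b$upper))
      conds <- c(conds, list(condition(
        rule$score_term, comparator = if (b$upper_incl) "<=" else "<",
        value = b$upper, flagged = rule$flagged)))
    out[[i]] <- cels(conds, b$action, polarity = b$polarity,
                     id = sprintf("%s-%d", id_prefix, i), metadata = metadata)
  }
  out
}

#' Evaluate a CELS's score conditions at a score value
#'
#' `TRUE` when every comparator condition on `score_term` in the CELS is
#' satisfied by `score`. Used to check by brute force that exactly one
#' band of an expanded score rule fires for any given score.
#'
#' @param x a [cels].
#' @param score_term the score's surface term.
#' @param score numeric score value.
#' @return logical.
#' @export
score_conditions_hold <- function(x, score_term, score) {
  key <- term_key(score_term)
  ok <- TRUE
  for (cond in x$conditions) {
    if (term_key(cond$term) != key || is.null(cond$comparator)) next
    hold <- switch(cond$comparator,
                   "<"  = score <  cond$value,
                   "<=" = score <= cond$value,
                   ">"  = score >  cond$value,
                   ">=" = score >= cond$value,
                   "="  = score == cond$value)
    if (cond$negated) hold <- !hold
    ok <- ok && hold
  }
  ok
}

# ---- classification ---------------------------------------------------------

#' Classify an evidence unit into its logic variant
#'
#' The three variants are `single_decision` (one If-Then statement),
#' `branching` (a decision tree or a multi-statement set without a
#' shared score), and `score_based` (bands over a shared score term).
#'
#' @param unit a `decision_tree`, a `score_rule`, a single [cels], or a
#'   list of [cels].
#' @return one of `"single_decision"`, `"branching"`, `"score_based"`.
#' @export
classify_statement <- function(unit) {
  if (inherits(unit, "decision_tree")) return("branching")
  if (inherits(unit, "score_rule")) return("score_based")
  if (inherits(unit, "cels")) unit <- list(unit)
  if (!is.list(unit) || length(unit) == 0L)
    cels_error("empty evidence unit", "cels_invalid_error")
  if (!all(vapply(unit, inherits, logical(1), "cels")))
    cels_error("evidence unit must contain CELS", "cels_invalid_error")
  if (length(unit) == 1L) return("single_decision")
  # score-based: some term carries a threshold comparator in every statement
  threshold_terms <- lapply(unit, function(x) {
    unique(vapply(
      Filter(function(cond) !is.null(cond$comparator), x$conditions),
      function(cond) term_key(cond$term), character(1)))
  })
  shared <- Reduce(intersect, threshold_terms)
  if (length(shared) > 0L) "score_based" else "branching"
}
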