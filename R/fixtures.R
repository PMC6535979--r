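# Packaged worked examples and a seeded synthetic-corpus generator.
#
# The examples are the canonical evidence units of the problem domain:
# a single-decision statement (VQ SPECT for suspected PE), a score-based
# set (Alvarado score for suspected appendicitis, whose score term has
# no standard-ontology concept), a follow-up set whose actions carry
# future temporal components (small-nodule CT surveillance), and a
# two-leaf pregnancy branching tree. All concept identifiers in the
# packaged terminology other than the published suspected-PE code are
# synthetic placeholders, and the files are named accordingly.

fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "celsify")
  if (!nzchar(p)) cels_error(sprintf("missing packaged fixture %s",
                                     paste(c(...), collapse = "/")))
  p
}

#' Packaged worked examples
#'
#' @return a list with elements:
#'   \describe{
#'     \item{pe}{the suspected-PE single-decision [cels];}
#'     \item{alvarado}{three score-band [cels] over the (deliberately
#'       unmapped) Alvarado score;}
#'     \item{alvarado_rule}{the same unit as a [score_rule()];}
#'     \item{fleischner}{three nodule-surveillance [cels] whose actions
#'       carry future temporal components;}
#'     \item{pregnancy_tree}{a two-leaf branching `decision_tree`
#'       (VQ SPECT if pregnant, CTPA otherwise);}
#'     \item{terminology}{the packaged [terminology] subset (with
#'       hierarchy);}
#'     \item{known_gaps}{named scores/rules the terminology deliberately
#'       lacks.}
#'   }
#' @examples
#' ex <- paper_examples()
#' audit_cels(ex$pe, ex$terminology)$fully_represented
#' @export
paper_examples <- function() {
  gaps <- readLines(fixture_path("known_gaps.txt"), warn = FALSE)
  gaps <- trimws(gaps)
  gaps <- gaps[nzchar(gaps) & !startsWith(gaps, "#")]
  list(
    pe = read_cels_file(fixture_path("pe.cels"))[[1L]],
    alvarado = read_cels_file(fixture_path("alvarado.cels")),
    alvarado_rule = score_rule_from_json(fixture_path("alvarado_rule.json")),
    fleischner = read_cels_file(fixture_path("fleischner.cels")),
    pregnancy_tree = tree_from_json(fixture_path("pregnancy_tree.json")),
    terminology = load_terminology(
      fixture_path("terminology_synthetic_subset.tsv"),
      hierarchy_path = fixture_path("hierarchy_synthetic.tsv")),
    known_gaps = gaps
  )
}

# Generator vocabulary. Every in-vocabulary term gets a deterministic
# synthetic concept id; out-of-vocabulary terms come from the known-gaps
# list plus generated score names.
generator_vocab <- function() {
  conditions <- c(
    "Suspected PE", "Pregnant", "Head trauma", "Acute appendicitis",
    "Chest pain", "Low back pain", "Neck pain", "Syncope", "Minor head injury",
    "Pulmonary nodule on chest CT", "Renal colic", "Suspected stroke",
    "Abdominal pain", "Shortness of breath", "Hematuria", "Seizure",
    "Fever of unknown origin", "Weight loss", "Chronic cough", "Headache")
  numeric_conditions <- c("Nodule size", "Age", "Heart rate", "GCS")
  actions <- c(
    "VQ SPECT", "CTPA", "CT abdomen", "CT chest", "CT head", "MRI brain",
    "MRI lumbar spine", "X-ray knee", "Ultrasound abdomen", "Low-dose CT",
    "Bone scan", "PET CT")
  all_terms <- c(conditions, numeric_conditions, actions)
  entries <- data.frame(
    term = all_terms,
    concept_ids = sprintf("91%07d", seq_along(all_terms)),
    match_type = "precoordinated",
    stringsAsFactors = FALSE)
  oov <- c(
    "AIR score", "Alvarado score", "Canadian CT Head Rule",
    "Canadian Cervical Spine Rule", "New Orleans/Charity head trauma rule",
    "NEXUS head trauma rule", "Revised Geneva score", "OPTIMAP score",
    "SCORE score", "Simplified Motor Score", "STONE score",
    "Vehicle rollover", "New feature", "Suitable candidate",
    "Time-of-flight MRA")
  list(conditions = conditions, numeric_conditions = numeric_conditions,
       actions = actions, entries = entries, oov = oov)
}

random_units <- c("mm", "cm", "bpm")

random_condition <- function(vocab) {
  kind <- sample.int(3L, 1L, prob = c(0.7, 0.2, 0.1))
  if (kind == 1L) {
    condition(sample(vocab$conditions, 1L),
              negated = stats::runif(1) < 0.1)
  } else if (kind == 2L) {
    condition(sample(vocab$numeric_conditions, 1L),
              comparator = sample(c("<", "<=", ">", ">=", "="), 1L),
              value = sample(c(1:20, 2.5, 7.5), 1L),
              unit = if (stats::runif(1) < 0.3) sample(random_units, 1L) else NULL)
  } else {
    condition(sample(vocab$actions, 1L),
              temporal = temporal_spec("past",
                                       segments = list(c(sample(c(3, 6, 12, 24), 1L)))))
  }
}

random_future_temporal <- function() {
  kind <- sample.int(4L, 1L)
  switch(kind,
    temporal_spec("future", segments = list(c(sample(c(3, 6, 9, 12, 18, 24), 1L)))),
    temporal_spec("future", segments = list(sort(sample(3:24, 2L)))),
    temporal_spec("future", segments = lapply(sort(sample(c(3, 6, 9, 12, 18, 24), 3L)), identity)),
    temporal_spec("future", recurrence = list(interval_months = 12,
                                              duration_months = 12 * sample(2:5, 1L)))
  )
}

#' Generate a synthetic CELS corpus with planted ground truth
#'
#' Builds `n` random statements from a fixed in-vocabulary term pool
#' (every term mapped in the returned terminology), then plants exact
#' numbers of representability failures: `floor(frac_unmapped * n)`
#' statements get one term replaced by an out-of-vocabulary term, and
#' `floor(frac_temporal * n)` statements get a future temporal component
#' on their action. Planted counts are exact integers, not Bernoulli
#' draws, so an auditor must reproduce them exactly. With
#' `nested = TRUE` (default) the temporal statements are a subset of the
#' unmapped ones, so `fully = total - unmapped`; with `nested = FALSE`
#' the two sets are sampled independently.
#'
#' @param n corpus size.
#' @param frac_unmapped fraction in `[0, 1]` of statements with an
#'   unmapped term.
#' @param frac_temporal fraction in `[0, 1]` with a future-temporal
#'   action (at most `frac_unmapped` when nested).
#' @param seed integer seed; identical parameters and seed give an
#'   identical corpus.
#' @param nested logical; plant temporal failures inside the unmapped
#'   subset (default) or independently.
#' @param unmapped_slot `"condition"` (replace a condition term) or
#'   `"action"` (replace the action procedure term).
#' @return a `planted_corpus`: list with `cels` (list of [cels]),
#'   `truth` (data frame: `id`, `fully`, `partial_snomed`,
#'   `partial_cql`, `action_mapped`), `terminology`, and `params`.
#' @examples
#' pc <- generate_corpus(20, 0.25, 0.05, seed = 1)
#' sum(pc$truth$partial_snomed)
#' @export
generate_corpus <- function(n, frac_unmapped = 0, frac_temporal = 0, seed = 1,
                            nested = TRUE,
                            unmapped_slot = c("condition", "action")) {
  unmapped_slot <- match.arg(unmapped_slot)
  if (n < 1L) cels_error("corpus size must be >= 1", "cels_invalid_error")
  for (f in c(frac_unmapped, frac_temporal))
    if (f < 0 || f > 1)
      cels_error("fractions must lie in [0, 1]", "cels_invalid_error")
  n_unm <- floor(frac_unmapped * n + 1e-9)
  n_tmp <- floor(frac_temporal * n + 1e-9)
  if (nested && n_tmp > n_unm)
    cels_error("nested planting requires frac_temporal <= frac_unmapped",
               "cels_invalid_error")
  vocab <- generator_vocab()
  with_seed(seed, {
    unm_idx <- sort(sample.int(n, n_unm))
    tmp_idx <- sort(if (nested) {
      if (n_tmp > 0) unm_idx[sample.int(n_unm, n_tmp)] else integer(0)
    } else sample.int(n, n_tmp))
    corpus <- vector("list", n)
    for (i in seq_len(n)) {
      k <- sample.int(3L, 1L, prob = c(0.5, 0.35, 0.15))
      conds <- lapply(seq_len(k), function(j) random_condition(vocab))
      connectives <- sample(c("And", "Or"), max(0L, k - 1L),
                            replace = TRUE, prob = c(0.85, 0.15))
      act <- action_spec(sample(vocab$actions, 1L))
      if (i %in% unm_idx && unmapped_slot == "condition") {
        slot <- sample.int(k, 1L)
        conds[[slot]] <- condition(sample(vocab$oov, 1L),
                                   flagged = stats::runif(1) < 0.5)
      }
      if (i %in% unm_idx && unmapped_slot == "action")
        act$procedure <- normalize_term(sample(vocab$oov, 1L))
      if (i %in% tmp_idx) act$temporal <- random_future_temporal()
      corpus[[i]] <- cels(
        conds, act, connectives = connectives,
        polarity = sample(c("recommend", "not_recommend"), 1L),
        id = sprintf("syn-%05d", i),
        metadata = source_meta(sprintf("Synthetic evidence source %d", i),
                               authors = "Synthetic corpus generator",
                               year = "2019",
                               evidence_kind = sample(
                                 c("guideline", "decision_rule", "best_practice"), 1L)))
    }
    truth <- data.frame(
      id = vapply(corpus, `[[`, character(1), "id"),
      fully = !(seq_len(n) %in% unm_idx | seq_len(n) %in% tmp_idx),
      partial_snomed = seq_len(n) %in% unm_idx,
      partial_cql = seq_len(n) %in% tmp_idx,
      action_mapped = !(seq_len(n) %in% unm_idx & unmapped_slot == "action"),
      stringsAsFactors = FALSE)
    structure(
      list(cels = corpus, truth = truth,
           terminology = terminology(vocab$entries),
           params = list(n = n, frac_unmapped = frac_unmapped,
                         frac_temporal = frac_temporal, seed = seed,
                         nested = nested, unmapped_slot = unmapped_slot)),
      class = "planted_corpus")
  })
}

#' @export
print.planted_corpus <- function(x, ...) {
  cat(sprintf(
    "<planted corpus> n=%d, unmapped=%d, temporal=%d (seed %d, %s)\n",
    x$params$n, sum(x$truth$partial_snomed), sum(x$truth$partial_cql),
    x$params$seed, if (x$params$nested) "nested" else "independent"))
  invisible(x)
}
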