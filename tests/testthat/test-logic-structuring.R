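# Logic variants: classification, decision-tree flattening, score-rule
# expansion.

test_that("evidence units classify into the three logic variants", {
  ex <- paper_examples()
  expect_equal(classify_statement(ex$pe), "single_decision")
  expect_equal(classify_statement(ex$alvarado), "score_based")
  expect_equal(classify_statement(ex$pregnancy_tree), "branching")
  expect_equal(classify_statement(ex$alvarado_rule), "score_based")
  # a multi-statement set without a shared threshold term is branching
  two <- list(parse_cels("If [Pregnant] Then [VQ SPECT]"),
              parse_cels("If Not [Pregnant] Then [CTPA]"))
  expect_equal(classify_statement(two), "branching")
  expect_error(classify_statement(list()), "empty")
})

test_that("a one-split tree flattens to two CELS with negated false branch", {
  ex <- paper_examples()
  out <- flatten_decision_tree(ex$pregnancy_tree, id_prefix = "pe-preg")
  expect_length(out, 2L)
  expect_equal(serialize_cels(out[[1]]), "If [Pregnant] Then [VQ SPECT]")
  expect_equal(serialize_cels(out[[2]]), "If Not [Pregnant] Then [CTPA]")
})

test_that("a single leaf flattens to one CELS", {
  out <- flatten_decision_tree(decision_leaf("X-ray knee"))
  expect_length(out, 1L)
  expect_equal(out[[1]]$action$procedure, "X-ray knee")
})

test_that("a complete depth-3 tree flattens to 8 CELS of 3 conditions each", {
  leaf <- function(i) decision_leaf(paste("CT head"), "recommend")
  d1 <- function(t1, t2) decision_node(condition("Head trauma"), t1, t2)
  tree <- decision_node(
    condition("Age", comparator = ">", value = 65),
    decision_node(condition("High risk"), d1(leaf(1), leaf(2)), d1(leaf(3), leaf(4))),
    decision_node(condition("High risk"), d1(leaf(5), leaf(6)), d1(leaf(7), leaf(8))))
  out <- flatten_decision_tree(tree)
  expect_length(out, 8L)
  expect_true(all(vapply(out, function(x) length(x$conditions), integer(1)) == 3L))
  # depth-first, true branch first: the first CELS takes every true branch
  expect_false(any(vapply(out[[1]]$conditions, `[[`, logical(1), "negated")))
  expect_true(all(vapply(out[[8]]$conditions, `[[`, logical(1), "negated")))
})

test_that("leaf counts match independent path enumeration on random trees", {
  withr::local_seed(424)
  for (i in 1:25) {
    tree <- random_tree(sample(2:5, 1L))
    flat <- flatten_decision_tree(tree)
    paths <- enumerate_paths(tree)
    expect_length(flat, length(paths))
    expect_equal(count_leaves(tree), length(paths))
    # per-leaf condition paths agree with the oracle's path labels
    got <- lapply(flat, function(x) vapply(x$conditions, function(cond)
      paste0(if (cond$negated) "!" else "", cond$term), character(1)))
    expect_identical(got, paths)
  }
})

test_that("the score-based unit expands to the printed band statements", {
  ex <- paper_examples()
  out <- expand_score_rule(ex$alvarado_rule)
  expect_length(out, 3L)
  lines <- vapply(out, serialize_cels, character(1))
  expect_setequal(lines, c(
    "If [Alvarado score* <4] Then Not [CT Abdomen]",
    "If [Alvarado score* >=4] And [Alvarado score* <=6] Then [CT abdomen]",
    "If [Alvarado score* >6] Then Not [CT Abdomen]"))
})

test_that("a single unbounded band yields one comparator condition", {
  r <- score_rule("GCS", list(score_band("CT head", lower = 13)))
  out <- expand_score_rule(r)
  expect_length(out, 1L)
  expect_length(out[[1]]$conditions, 1L)
  expect_equal(out[[1]]$conditions[[1]]$comparator, ">=")
})

test_that("shared conditions are prepended to every band statement", {
  r <- score_rule("Alvarado score",
                  list(score_band("CT abdomen", upper = 4, upper_incl = FALSE),
                       score_band("CT abdomen", lower = 4)),
                  shared_conditions = list(condition("Abdominal pain")))
  out <- expand_score_rule(r)
  expect_true(all(vapply(out, function(x)
    x$conditions[[1]]$term == "Abdominal pain", logical(1))))
})

test_that("exactly one band fires per integer score (brute-force sweep)", {
  bands <- list(
    score_band("A", upper = 2, upper_incl = FALSE),
    score_band("B", lower = 2, upper = 4),
    score_band("C", lower = 4, lower_incl = FALSE, upper = 7, upper_incl = FALSE),
    score_band("D", lower = 7, upper = 9),
    score_band("E", lower = 9, lower_incl = FALSE))
  r <- score_rule("STONE score", bands)
  out <- expand_score_rule(r)
  expect_length(out, 5L)
  for (score in 0:12) {
    fired <- vapply(out, score_conditions_hold, logical(1),
                    score_term = "STONE score", score = score)
    expect_equal(sum(fired), 1L, info = sprintf("score=%d", score))
  }
})

test_that("overlapping or ill-ordered bands are rejected", {
  expect_error(score_rule("S", list(
    score_band("A", lower = 1, upper = 5),
    score_band("B", lower = 5, upper = 9))), "overlap")
  expect_error(score_band("A", lower = 5, upper = 4), "well-ordered")
  expect_error(score_band("A"), "finite bound")
})

test_that("trees and score rules load from their JSON documents", {
  tree <- tree_from_json(system.file("extdata", "pregnancy_tree.json",
                                     package = "celsify"))
  expect_equal(count_leaves(tree), 2L)
  expect_error(tree_from_json(list(condition = list(term = "X"))), "malformed")
  rule <- score_rule_from_json(system.file("extdata", "alvarado_rule.json",
                                           package = "celsify"))
  expect_length(rule$bands, 3L)
  expect_true(rule$flagged)
})
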