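# Representability auditing: temporal detection, per-statement flags,
# corpus tallies, and rounding.

test_that("future temporal components are detected and parsed", {
  f <- detect_future_temporal(
    parse_cels("If [High risk] Then [CT chest in 12 months]")$action)
  expect_s3_class(f, "temporal_finding")
  expect_equal(f$category, "temporal_action")
  expect_equal(f$temporal$window_min_months, 12)
  expect_equal(f$temporal$window_max_months, 12)

  f2 <- detect_future_temporal(action_spec("Low-dose CT annually for 3 years"))
  # the phrase is carried in the raw procedure string, not structured
  f2 <- detect_future_temporal(
    parse_cels("If [High risk] Then [Low-dose CT annually for 3 years]")$action)
  expect_equal(f2$temporal$recurrence$interval_months, 12)
  expect_equal(f2$temporal$recurrence$duration_months, 36)

  f3 <- detect_future_temporal(
    parse_cels("If [High risk] Then [CT chest in 3 months, 9 months, And 24 months]")$action)
  expect_equal(f3$temporal$points, c(3, 9, 24))

  f4 <- detect_future_temporal(
    parse_cels("If [High risk] Then [CT chest in 9-12 months And 24 months]")$action)
  expect_equal(f4$temporal$window_min_months, 9)
  expect_equal(f4$temporal$window_max_months, 24)

  expect_null(detect_future_temporal(action_spec("VQ SPECT")))
  # past lookbacks live on conditions and never fire the detector
  expect_null(detect_future_temporal(action_spec("CT chest")))

  raw <- detect_future_temporal(action_spec("CT chest in a few months"))
  expect_equal(raw$category, "raw_unparsed")
})

test_that("audit flags follow the failure taxonomy", {
  ex <- paper_examples()
  pe <- audit_cels(ex$pe, ex$terminology)
  expect_true(pe$fully_represented)
  expect_false(pe$partial_snomed || pe$partial_cql)
  expect_length(pe$reasons, 0L)

  alv <- audit_cels(parse_cels("If [Alvarado score >6] Then Not [CT Abdomen]"),
                    ex$terminology)
  expect_true(alv$partial_snomed)
  expect_false(alv$partial_cql)
  expect_equal(alv$reasons[[1]]$category, "clinical_term")
  expect_equal(alv$reasons[[1]]$text, "Alvarado score")

  fl <- audit_cels(ex$fleischner[[3]], ex$terminology)
  expect_true(fl$partial_cql)
  expect_false(fl$partial_snomed)
  expect_equal(fl$reasons[[1]]$category, "temporal_action")

  eng <- audit_cels(parse_cels("If [vehicle rollover] Then [CT head]"),
                    ex$terminology)
  expect_equal(eng$reasons[[1]]$category, "english_phrase")
})

test_that("snomed and cql flags can co-occur on one statement", {
  ex <- paper_examples()
  both <- audit_cels(
    parse_cels("If [Alvarado score >6] Then [CT chest in 12 months]"),
    ex$terminology)
  expect_true(both$partial_snomed)
  expect_true(both$partial_cql)
  expect_false(both$fully_represented)
})

test_that("corpus percentages follow direct arithmetic", {
  pc <- generate_corpus(40, 7 / 40, 0, seed = 11)
  rep <- audit_corpus(pc$cels, pc$terminology)
  expect_equal(rep$n_partial_snomed, 7L)
  expect_equal(rep$pct_partial_snomed, 17.5)
  expect_equal(rep$pct_full, 82.5)

  single <- audit_corpus(list(paper_examples()$pe),
                         paper_examples()$terminology)
  expect_equal(single$pct_full, 100.0)
  expect_error(audit_corpus(list(), paper_examples()$terminology), "empty")
})

test_that("percentages equal the exact half-up oracle on random counts", {
  withr::local_seed(7)
  for (i in 1:200) {
    total <- sample(1:2000, 1L)
    n <- sample(0:total, 1L)
    expect_equal(celsify:::round_half_up(100 * n / total, 1),
                 pct_oracle(n, total),
                 info = sprintf("n=%d total=%d", n, total))
  }
  # explicit half cases round up, not to even
  expect_equal(celsify:::round_half_up(0.15, 1), 0.2)
  expect_equal(celsify:::round_half_up(0.25, 1), 0.3)
  expect_equal(celsify:::round_half_up(17.85, 1), 17.9)
})

test_that("audit counts equal planted truth for seeded parameterizations", {
  withr::local_seed(2024)
  for (i in 1:20) {
    n <- sample(30:120, 1L)
    fu <- stats::runif(1, 0, 0.6)
    ft <- stats::runif(1, 0, if (i %% 2 == 0) fu else 0.3)
    nested <- i %% 2 == 0
    pc <- generate_corpus(n, fu, ft, seed = 1000 + i, nested = nested)
    rep <- audit_corpus(pc$cels, pc$terminology)
    expect_equal(rep$n_partial_snomed, sum(pc$truth$partial_snomed))
    expect_equal(rep$n_partial_cql, sum(pc$truth$partial_cql))
    expect_equal(rep$n_full, sum(pc$truth$fully))
    # per-statement agreement, not just totals
    got <- vapply(rep$results, `[[`, logical(1), "fully_represented")
    expect_identical(got, pc$truth$fully)
  }
})

test_that("fully represented statements always compile", {
  pc <- generate_corpus(60, 0.3, 0.15, seed = 5)
  rep <- audit_corpus(pc$cels, pc$terminology)
  for (i in seq_along(pc$cels)) {
    if (!rep$results[[i]]$fully_represented) next
    doc <- emit_cql(pc$cels[[i]], pc$terminology)
    elm <- emit_elm(pc$cels[[i]], doc)
    expect_true(validate_decision_rule_xml(render_xml(elm)))
  }
})

test_that("reports serialize to JSON and a three-row table", {
  pc <- generate_corpus(50, 0.2, 0.1, seed = 3)
  rep <- audit_corpus(pc$cels, pc$terminology)
  json_path <- withr::local_tempfile(fileext = ".json")
  tsv_path <- withr::local_tempfile(fileext = ".tsv")
  write_report(rep, json_path = json_path, tsv_path = tsv_path)
  back <- jsonlite::fromJSON(json_path)
  expect_equal(back$n_partial_snomed, 10L)
  expect_equal(back$pct_partial_snomed, 20.0)
  tab <- utils::read.delim(tsv_path)
  expect_equal(nrow(tab), 3L)
  expect_match(tab$type[1], "fully represented")
  expect_match(tab$type[2], "SNOMED")
  expect_match(tab$type[3], "due to CQL")
  expect_equal(tab$n, c(rep$n_full, rep$n_partial_snomed, rep$n_partial_cql))
})
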