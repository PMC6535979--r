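# DSL parsing, serialization, and structural validation.

test_that("single-decision statement parses into its parts", {
  x <- parse_cels("If [Suspected PE] Then [VQ SPECT]")
  expect_length(x$conditions, 1L)
  expect_equal(x$conditions[[1]]$term, "Suspected PE")
  expect_null(x$conditions[[1]]$comparator)
  expect_equal(x$action$procedure, "VQ SPECT")
  expect_equal(x$polarity, "recommend")
  expect_length(x$connectives, 0L)
})

test_that("comparators, asterisk flags, and Then Not are parsed", {
  x <- parse_cels("If [Alvarado score* <4] Then Not [CT Abdomen]")
  cond <- x$conditions[[1]]
  expect_equal(cond$term, "Alvarado score")
  expect_true(cond$flagged)
  expect_equal(cond$comparator, "<")
  expect_equal(cond$value, 4)
  expect_equal(x$polarity, "not_recommend")
  # Then Not never negates the procedure term itself
  expect_equal(x$action$procedure, "CT Abdomen")

  y <- parse_cels(paste0("If [pulmonary nodule on chest CT] And ",
                         "[nodule size <=4mm] And [high risk] ",
                         "Then [CT chest in 12 months]"))
  expect_length(y$conditions, 3L)
  expect_equal(y$connectives, c("And", "And"))
  expect_equal(y$conditions[[2]]$unit, "mm")
  expect_equal(y$action$procedure, "CT chest")
  expect_equal(y$action$temporal$direction, "future")
  expect_equal(y$action$temporal$window_min_months, 12)
})

test_that("negation, Or, and past lookbacks are part of the grammar", {
  x <- parse_cels(
    "If Not [Pregnant] Or [CT chest in the past 12 months] Then [CTPA]")
  expect_true(x$conditions[[1]]$negated)
  expect_equal(x$connectives, "Or")
  tmp <- x$conditions[[2]]$temporal
  expect_equal(tmp$direction, "past")
  expect_equal(tmp$window_max_months, 12)
  expect_equal(x$conditions[[2]]$term, "CT chest")
})

test_that("malformed statements raise parse errors naming the span", {
  expect_error(parse_cels("If [] Then [X]"), "empty condition")
  expect_error(parse_cels("If [A] Then [X"), "unbalanced brackets")
  expect_error(parse_cels("If [A] [X]"), "Then")
  expect_error(parse_cels("Then [X]"), "If")
  expect_error(parse_cels("If [A] Then []"), "empty action")
  expect_error(parse_cels("If [score == 4] Then [X]"), "comparator")
  expect_error(parse_cels("If [A] And Then [X]"), "expected")
})

test_that("serialization is canonical and parsing is deterministic", {
  line <- "If   [Suspected  PE]   Then   [VQ SPECT]"
  x <- parse_cels(line)
  expect_equal(serialize_cels(x), "If [Suspected PE] Then [VQ SPECT]")
  expect_identical(parse_cels(line), parse_cels(line))
  # printed forms of score thresholds round-trip verbatim
  printed <- "If [Alvarado score* >=4] And [Alvarado score* <=6] Then [CT abdomen]"
  expect_equal(serialize_cels(parse_cels(printed)), printed)
})

test_that("parse-serialize round trip is the identity on generated corpora", {
  pc <- generate_corpus(250, 0.3, 0.1, seed = 99, nested = TRUE)
  for (x in pc$cels) {
    expect_true(cels_identical(x, parse_cels(serialize_cels(x))),
                info = serialize_cels(x))
  }
})

test_that("validate_cels reports each invariant violation", {
  good <- parse_cels("If [Suspected PE] Then [VQ SPECT]")
  expect_length(validate_cels(good), 0L)

  bad_arity <- good
  bad_arity$conditions <- c(bad_arity$conditions, list(
    condition("Chest pain"), condition("Fever")))
  expect_match(validate_cels(bad_arity), "connective arity", all = FALSE)

  bad_cmp <- good
  bad_cmp$conditions[[1]]$comparator <- "<"
  expect_match(validate_cels(bad_cmp), "comparator present iff value",
               all = FALSE)

  bad_tmp <- good
  bad_tmp$action$temporal <- temporal_spec("future", segments = list(c(6, 12)))
  bad_tmp$action$temporal$segments[[1]] <- c(12, 6)  # min > max
  expect_match(validate_cels(bad_tmp), "min > max", all = FALSE)
})

test_that("DSL files round-trip with comments ignored", {
  path <- withr::local_tempfile(fileext = ".cels")
  writeLines(c("# a comment", "", "If [Suspected PE] Then [VQ SPECT]",
               "If [Pregnant] Then Not [CTPA]"), path)
  corpus <- read_cels_file(path)
  expect_length(corpus, 2L)
  expect_equal(corpus[[2]]$polarity, "not_recommend")
  out <- withr::local_tempfile(fileext = ".cels")
  write_cels_file(corpus, out)
  again <- read_cels_file(out)
  expect_true(all(mapply(cels_identical, corpus, again)))
})

test_that("file parse errors carry the line number", {
  path <- withr::local_tempfile(fileext = ".cels")
  writeLines(c("If [Suspected PE] Then [VQ SPECT]", "If [] Then [X]"), path)
  expect_error(read_cels_file(path), ":2:")
})

test_that("JSON list form mirrors fields exactly and round-trips", {
  x <- parse_cels("If [nodule size >4mm] And Not [high risk] Then Not [CT chest in 6-12 months]",
                  metadata = source_meta("Nodule follow-up", "Someone", "2017",
                                         "guideline"))
  l <- cels_to_list(x)
  expect_equal(l$conditions[[1]]$unit, "mm")
  expect_true(l$conditions[[2]]$negated)
  y <- cels_from_list(jsonlite::fromJSON(jsonlite::toJSON(l, auto_unbox = TRUE),
                                         simplifyVector = FALSE))
  expect_true(cels_identical(x, y))
  expect_equal(y$metadata$source_title, "Nodule follow-up")
})

test_that("temporal phrases render canonically", {
  expect_equal(render_temporal(temporal_spec("future", segments = list(12))),
               "in 12 months")
  expect_equal(render_temporal(temporal_spec("future", segments = list(c(6, 12)))),
               "in 6-12 months")
  expect_equal(render_temporal(temporal_spec("future",
                                             segments = list(3, 9, 24))),
               "in 3 months, 9 months, And 24 months")
  expect_equal(render_temporal(temporal_spec("future", recurrence = list(
    interval_months = 12, duration_months = 36))), "annually for 3 years")
  expect_equal(render_temporal(temporal_spec("past", segments = list(12))),
               "in the past 12 months")
})
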