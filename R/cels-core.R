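# Domain model and DSL for Clinical Evidence Logic Statements (CELS).
#
# A CELS is one "If [condition] (And|Or [condition])* Then [Not] [action]"
# statement. The bracketed surface terms are preserved verbatim (modulo
# whitespace normalization); a trailing asterisk on a term is the
# conventional marker for a term known to lack a terminology mapping and
# is stripped into an annotation flag. Mapping status itself is decided
# by the terminology module, never by the parser.

cels_error <- function(msg, class = "cels_parse_error") {
  stop(structure(
    class = c(class, "cels_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# ---- constructors -----------------------------------------------------------

#' Temporal specification for a condition or action
#'
#' Represents the time component of a clause: a past lookback window on a
#' condition ("CT chest in the past 12 months"), or a future schedule on
#' an action ("CT chest in 6-12 months", "CT chest in 3 months, 9 months,
#' And 24 months", "annually for 3 years"). Future schedules are stored as
#' a list of month segments (each a `c(lo, hi)` pair, degenerate when
#' `lo == hi`) or as a recurrence (interval and total duration in months).
#'
#' @param direction `"past"` or `"future"`.
#' @param segments list of numeric length-2 vectors `c(lo, hi)` of month
#'   offsets, or `NULL` for a pure recurrence.
#' @param recurrence `NULL`, or a list with `interval_months` and
#'   `duration_months`.
#' @return an object of class `cels_temporal` with derived fields
#'   `window_min_months`, `window_max_months` and, when every segment is a
#'   single time point and there is more than one, `points`.
#' @examples
#' temporal_spec("future", segments = list(c(6, 12)))
#' temporal_spec("future", recurrence = list(interval_months = 12, duration_months = 36))
#' @export
temporal_spec <- function(direction = c("past", "future"),
                          segments = NULL, recurrence = NULL) {
  direction <- match.arg(direction)
  if (is.null(segments) && is.null(recurrence))
    cels_error("temporal_spec needs segments or a recurrence",
               "cels_invalid_error")
  points <- NULL
  wmin <- wmax <- NA_real_
  if (!is.null(segments)) {
    segments <- lapply(segments, function(s) {
      s <- as.numeric(s)
      if (length(s) == 1L) s <- c(s, s)
      s
    })
    lo <- vapply(segments, `[`, numeric(1), 1L)
    hi <- vapply(segments, `[`, numeric(1), 2L)
    wmin <- min(lo); wmax <- max(hi)
    if (length(segments) > 1L && all(lo == hi)) points <- lo
  } else {
    wmin <- recurrence$interval_months
    wmax <- recurrence$duration_months
  }
  structure(
    list(direction = direction,
         window_min_months = wmin,
         window_max_months = wmax,
         recurrence = recurrence,
         points = points,
         segments = segments),
    class = "cels_temporal"
  )
}

#' Build one condition clause of a CELS
#'
#' @param term surface term (verbatim clinical text, e.g. `"nodule size"`).
#' @param comparator optional one of `<`, `<=`, `>`, `>=`, `=`; required
#'   exactly when `value` is given.
#' @param value optional numeric threshold.
#' @param unit optional unit token kept as an uninterpreted string
#'   (e.g. `"mm"`).
#' @param temporal optional past-looking [temporal_spec()].
#' @param negated logical; `TRUE` renders as `Not [term]`.
#' @param flagged logical; `TRUE` marks the term with the trailing
#'   asterisk convention for known terminology gaps.
#' @return an object of class `cels_condition`.
#' @examples
#' condition("Alvarado score", comparator = "<", value = 4, flagged = TRUE)
#' @export
condition <- function(term, comparator = NULL, value = NULL, unit = NULL,
                      temporal = NULL, negated = FALSE, flagged = FALSE) {
  structure(
    list(term = normalize_term(term), comparator = comparator,
         value = if (is.null(value)) NULL else as.numeric(value),
         unit = unit, temporal = temporal,
         negated = isTRUE(negated), flagged = isTRUE(flagged)),
    class = "cels_condition"
  )
}

#' Build the action clause of a CELS
#'
#' @param procedure surface term of the ordered procedure (e.g.
#'   `"VQ SPECT"`), without any temporal phrase.
#' @param temporal optional [temporal_spec()]; future-looking temporals
#'   are legal here structurally but flag the statement as inexpressible
#'   in CQL when audited.
#' @param flagged logical asterisk annotation, as for [condition()].
#' @return an object of class `cels_action`.
#' @export
action_spec <- function(procedure, temporal = NULL, flagged = FALSE) {
  structure(
    list(procedure = normalize_term(procedure), temporal = temporal,
         flagged = isTRUE(flagged)),
    class = "cels_action"
  )
}

#' Source metadata attached to a CELS
#'
#' @param source_title title of the evidence source (required, non-empty).
#' @param authors author string.
#' @param year publication year as a string.
#' @param evidence_kind one of `"guideline"`, `"decision_rule"`,
#'   `"best_practice"`.
#' @return an object of class `cels_meta`.
#' @export
source_meta <- function(source_title, authors = "", year = "",
                        evidence_kind = c("guideline", "decision_rule",
                                          "best_practice")) {
  evidence_kind <- match.arg(evidence_kind)
  if (!nzchar(normalize_term(source_title)))
    cels_error("source_title must be non-empty", "cels_invalid_error")
  structure(
    list(source_title = source_title, authors = authors, year = as.character(year),
         evidence_kind = evidence_kind),
    class = "cels_meta"
  )
}

#' Construct a Clinical Evidence Logic Statement
#'
#' @param conditions list of [condition()] objects (at least one).
#' @param action an [action_spec()].
#' @param connectives character vector of `"And"`/`"Or"` of length
#'   `length(conditions) - 1`; connectives mix left-associatively with no
#'   precedence.
#' @param polarity `"recommend"` (Then) or `"not_recommend"` (Then Not).
#'   "Then Not" expresses that the procedure is inappropriate; it never
#'   negates the procedure term itself.
#' @param id slug identifier; derived from the statement text if omitted.
#' @param metadata optional [source_meta()].
#' @return an object of class `cels`.
#' @examples
#' x <- cels(list(condition("Suspected PE")), action_spec("VQ SPECT"))
#' serialize_cels(x)
#' @export
cels <- function(conditions, action, connectives = NULL,
                 polarity = c("recommend", "not_recommend"),
                 id = NULL, metadata = NULL) {
  polarity <- match.arg(polarity)
  if (inherits(conditions, "cels_condition")) conditions <- list(conditions)
  if (is.null(connectives))
    connectives <- rep("And", max(0L, length(conditions) - 1L))
  x <- structure(
    list(id = id, conditions = conditions, connectives = as.character(connectives),
         action = action, polarity = polarity, metadata = metadata),
    class = "cels"
  )
  if (is.null(id)) x$id <- tolower(slugify(serialize_cels(x), sep = "-"))
  x
}

#' @export
print.cels <- function(x, ...) {
  cat("<cels> ", x$id, "\n  ", serialize_cels(x), "\n", sep = "")
  invisible(x)
}

#' @export
print.cels_temporal <- function(x, ...) {
  cat("<temporal> ", x$direction, " ", render_temporal(x), "\n", sep = "")
  invisible(x)
}

# ---- temporal phrase grammar ------------------------------------------------

.seg_rx <- "([0-9]+(?:\\.[0-9]+)?)(?:[ ]*-[ ]*([0-9]+(?:\\.[0-9]+)?))?[ ]*(?:months?)?"

# Parse "12 months" / "6-12 months" / "3 months, 9 months, And 24 months"
# into a list of c(lo, hi) segments; NULL when the text does not conform.
parse_month_segments <- function(text) {
  text <- normalize_term(text)
  parts <- strsplit(text, "(,[ ]*[Aa]nd[ ]+|,[ ]*|[ ]+[Aa]nd[ ]+)")[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return(NULL)
  if (!grepl("months?$", parts[length(parts)])) return(NULL)
  segs <- vector("list", length(parts))
  for (i in seq_along(parts)) {
    m <- regmatches(parts[i],
                    regexec(paste0("^", .seg_rx, "$"), parts[i], perl = TRUE))[[1]]
    if (length(m) == 0L) return(NULL)
    lo <- as.numeric(m[2])
    hi <- if (nzchar(m[3])) as.numeric(m[3]) else lo
    if (hi < lo || lo <= 0) return(NULL)
    segs[[i]] <- c(lo, hi)
  }
  segs
}

# Parse the temporal tail of an action phrase. Returns NULL when there is
# no temporal phrase, a cels_temporal on success, or the string "raw" when
# the text looks temporal but does not parse.
split_action_temporal <- function(text) {
  text <- normalize_term(text)
  m <- regmatches(text, regexec(
    "^(.*[^ ]) annually for ([0-9]+) years?$", text))[[1]]
  if (length(m) > 0L) {
    return(list(procedure = m[2],
                temporal = temporal_spec("future", recurrence = list(
                  interval_months = 12,
                  duration_months = as.numeric(m[3]) * 12))))
  }
  m <- regmatches(text, regexec("^(.*[^ ]) in ([^][]+)$", text))[[1]]
  if (length(m) > 0L && !grepl("(^|[ ])the past([ ]|$)", m[3])) {
    segs <- parse_month_segments(m[3])
    if (!is.null(segs))
      return(list(procedure = m[2],
                  temporal = temporal_spec("future", segments = segs)))
    if (grepl("months?", m[3]))
      return(list(procedure = text, temporal = "raw"))
  }
  list(procedure = text, temporal = NULL)
}

# Parse a past lookback tail on a condition term.
split_condition_temporal <- function(text) {
  text <- normalize_term(text)
  m <- regmatches(text, regexec(
    "^(.*[^ ]) (?:with)?in the past ([^][]+)$", text, perl = TRUE))[[1]]
  if (length(m) > 0L) {
    segs <- parse_month_segments(m[3])
    if (!is.null(segs) && length(segs) == 1L)
      return(list(term = m[2],
                  temporal = temporal_spec("past", segments = segs)))
  }
  list(term = text, temporal = NULL)
}

render_segment <- function(s, months = TRUE) {
  body <- if (s[1] == s[2]) format_num(s[1])
          else paste0(format_num(s[1]), "-", format_num(s[2]))
  if (months) paste0(body, " months") else body
}

#' Render a temporal specification as its canonical phrase
#'
#' Inverse of the temporal phrase parser: produces `"in 12 months"`,
#' `"in 6-12 months"`, `"in 3 months, 9 months, And 24 months"`,
#' `"annually for 3 years"`, or `"in the past 12 months"`.
#'
#' @param ts a [temporal_spec()].
#' @return a single string (without the leading procedure/term).
#' @export
render_temporal <- function(ts) {
  if (!is.null(ts$recurrence)) {
    r <- ts$recurrence
    if (r$interval_months == 12 && r$duration_months %% 12 == 0)
      return(sprintf("annually for %s years", format_num(r$duration_months / 12)))
    return(sprintf("every %s months for %s months",
                   format_num(r$interval_months), format_num(r$duration_months)))
  }
  segs <- vapply(ts$segments, render_segment, character(1))
  phrase <- if (length(segs) == 1L) segs
    else if (length(segs) == 2L) paste(segs, collapse = " And ")
    else paste0(paste(segs[-length(segs)], collapse = ", "), ", And ",
                segs[length(segs)])
  if (ts$direction == "past") paste0("in the past ", phrase)
  else paste0("in ", phrase)
}

# ---- parser -----------------------------------------------------------------

.comparator_rx <- "(<=|>=|<|>|=)"

parse_condition_content <- function(content, line) {
  content <- normalize_term(content)
  if (!nzchar(content))
    cels_error(sprintf("empty condition in %s", deparse(line)))
  if (grepl("(!=|=>|=<|<>|==)[ ]*[0-9]", content))
    cels_error(sprintf("unknown comparator token in [%s]", content))
  tmp <- split_condition_temporal(content)
  body <- tmp$term
  m <- regmatches(body, regexec(paste0(
    "^(.*[^ <>=])[ ]*", .comparator_rx,
    "[ ]*([0-9]*\\.?[0-9]+)[ ]*([A-Za-z%]+)?$"), body))[[1]]
  if (length(m) > 0L) {
    term <- m[2]; comp <- m[3]; val <- as.numeric(m[4])
    unit <- if (nzchar(m[5])) m[5] else NULL
  } else {
    term <- body; comp <- NULL; val <- NULL; unit <- NULL
  }
  flagged <- grepl("\\*$", term)
  term <- normalize_term(sub("\\*$", "", term))
  if (!nzchar(term))
    cels_error(sprintf("empty condition term in [%s]", content))
  condition(term, comparator = comp, value = val, unit = unit,
            temporal = tmp$temporal, flagged = flagged)
}

#' Parse one CELS statement from its DSL line
#'
#' The grammar is
#' `If <clause> ((And|Or) <clause>)* Then [Not] [<action>]`, where a
#' clause is an optional `Not` followed by a bracketed term, optionally
#' with a comparator and numeric threshold (`[nodule size <=4mm]`) or a
#' past lookback (`[CT chest in the past 12 months]`). `And` and `Or`
#' mix left-associatively with no precedence or parentheses. A trailing
#' asterisk on a term (the conventional unmapped-term marker) is stripped
#' and recorded in the `flagged` field. A future temporal phrase on the
#' action (`[CT chest in 6-12 months]`) is parsed into a structured
#' [temporal_spec()].
#'
#' @param text a single DSL statement.
#' @param id optional identifier; a slug of the canonical text otherwise.
#' @param metadata optional [source_meta()].
#' @return a [cels] object.
#' @examples
#' parse_cels("If [Suspected PE] Then [VQ SPECT]")
#' parse_cels("If [Alvarado score* <4] Then Not [CT Abdomen]")
#' @export
parse_cels <- function(text, id = NULL, metadata = NULL) {
  line <- normalize_term(text)
  if (!nzchar(line)) cels_error("empty statement")
  n_open <- lengths(regmatches(line, gregexpr("\\[", line)))
  n_close <- lengths(regmatches(line, gregexpr("\\]", line)))
  if (n_open != n_close)
    cels_error(sprintf("unbalanced brackets in %s", deparse(line)))

  rest <- line
  eat <- function(rx) {
    m <- regexpr(rx, rest, perl = TRUE)
    if (m == -1L) return(NULL)
    tok <- regmatches(rest, m)
    rest <<- substring(rest, attr(m, "match.length") + 1L)
    tok
  }
  if (is.null(eat("^[Ii]f[ ]+")))
    cels_error(sprintf("statement must begin with 'If': %s", deparse(line)))

  conditions <- list()
  connectives <- character(0)
  expect_clause <- TRUE
  repeat {
    negated <- !is.null(eat("^[Nn]ot[ ]+"))
    if (is.null(eat("^\\["))) {
      if (negated || expect_clause)
        cels_error(sprintf("expected '[' near %s", deparse(rest)))
      break
    }
    expect_clause <- FALSE
    m <- regexpr("^[^][]*\\]", rest)
    if (m == -1L) cels_error(sprintf("unbalanced brackets near %s", deparse(rest)))
    content <- sub("\\]$", "", regmatches(rest, m))
    rest <- substring(rest, attr(m, "match.length") + 1L)
    cond <- parse_condition_content(content, line)
    cond$negated <- negated
    conditions <- c(conditions, list(cond))
    conn <- eat("^[ ]+(And|Or)[ ]+")
    if (is.null(conn)) break
    connectives <- c(connectives, normalize_term(conn))
    expect_clause <- TRUE
  }
  if (length(conditions) == 0L)
    cels_error(sprintf("no conditions in %s", deparse(line)))

  if (is.null(eat("^[ ]*[Tt]hen[ ]+")))
    cels_error(sprintf("missing 'Then' in %s", deparse(line)))
  polarity <- if (!is.null(eat("^[Nn]ot[ ]+"))) "not_recommend" else "recommend"
  m <- regexpr("^\\[[^][]*\\][ ]*$", rest)
  if (m == -1L)
    cels_error(sprintf("expected bracketed action near %s", deparse(rest)))
  content <- normalize_term(gsub("^\\[|\\][ ]*$", "", regmatches(rest, m)))
  if (!nzchar(content)) cels_error(sprintf("empty action in %s", deparse(line)))
  flagged <- grepl("\\*$", content)
  content <- normalize_term(sub("\\*$", "", content))
  tmp <- split_action_temporal(content)
  temporal <- if (identical(tmp$temporal, "raw")) NULL else tmp$temporal
  act <- action_spec(tmp$procedure, temporal = temporal, flagged = flagged)

  cels(conditions, act, connectives = connectives, polarity = polarity,
       id = id, metadata = metadata)
}

# ---- serializer -------------------------------------------------------------

serialize_condition <- function(cond) {
  body <- cond$term
  if (cond$flagged) body <- paste0(body, "*")
  if (!is.null(cond$comparator))
    body <- paste0(body, " ", cond$comparator, format_num(cond$value),
                   cond$unit %||% "")
  if (!is.null(cond$temporal))
    body <- paste0(body, " ", render_temporal(cond$temporal))
  out <- paste0("[", body, "]")
  if (cond$negated) paste("Not", out) else out
}

#' Serialize a CELS back to its canonical DSL line
#'
#' Produces the canonical statement text; parsing the result yields a
#' structure equal to the input (round-trip identity, up to identifier
#' and metadata which the line does not carry).
#'
#' @param x a [cels] object.
#' @return a single string.
#' @export
serialize_cels <- function(x) {
  parts <- serialize_condition(x$conditions[[1L]])
  if (length(x$conditions) > 1L) {
    for (i in seq_along(x$connectives)) {
      parts <- paste(parts, x$connectives[i],
                     serialize_condition(x$conditions[[i + 1L]]))
    }
  }
  act <- x$action$procedure
  if (x$action$flagged) act <- paste0(act, "*")
  if (!is.null(x$action$temporal))
    act <- paste(act, render_temporal(x$action$temporal))
  paste0("If ", parts, " Then ",
         if (x$polarity == "not_recommend") "Not " else "",
         "[", act, "]")
}

#' Compare two CELS structurally
#'
#' Equality on conditions, connectives, action and polarity; identifier
#' and source metadata are ignored (the DSL line does not carry them).
#'
#' @param a,b [cels] objects.
#' @return logical.
#' @export
cels_identical <- function(a, b) {
  strip <- function(x) x[c("conditions", "connectives", "action", "polarity")]
  identical(strip(a), strip(b))
}

# ---- validation -------------------------------------------------------------

validate_temporal <- function(ts, where) {
  issues <- character(0)
  if (!ts$direction %in% c("past", "future"))
    issues <- c(issues, sprintf("%s: temporal direction must be past or future", where))
  if (!is.null(ts$segments)) {
    for (s in ts$segments) {
      if (s[2] < s[1])
        issues <- c(issues, sprintf("%s: temporal window min > max", where))
      if (any(s <= 0))
        issues <- c(issues, sprintf("%s: temporal offsets must be > 0", where))
    }
  }
  if (!is.null(ts$recurrence) &&
      (ts$recurrence$interval_months <= 0 || ts$recurrence$duration_months <= 0))
    issues <- c(issues, sprintf("%s: recurrence months must be > 0", where))
  issues
}

#' Validate a CELS against its structural invariants
#'
#' @param x a [cels] object (possibly hand-built or deserialized).
#' @return character vector of human-readable issues; empty when the
#'   statement satisfies every invariant.
#' @examples
#' validate_cels(parse_cels("If [Suspected PE] Then [VQ SPECT]"))
#' @export
validate_cels <- function(x) {
  issues <- character(0)
  if (length(x$conditions) < 1L)
    issues <- c(issues, "a CELS needs at least one condition")
  if (length(x$connectives) != max(0L, length(x$conditions) - 1L))
    issues <- c(issues, sprintf(
      "connective arity: %d conditions need %d connectives, found %d",
      length(x$conditions), max(0L, length(x$conditions) - 1L),
      length(x$connectives)))
  if (length(x$connectives) && !all(x$connectives %in% c("And", "Or")))
    issues <- c(issues, "connectives must be 'And' or 'Or'")
  if (!x$polarity %in% c("recommend", "not_recommend"))
    issues <- c(issues, "polarity must be recommend or not_recommend")
  for (i in seq_along(x$conditions)) {
    cond <- x$conditions[[i]]
    where <- sprintf("condition %d", i)
    if (!nzchar(normalize_term(cond$term)))
      issues <- c(issues, paste0(where, ": empty term"))
    if (is.null(cond$comparator) != is.null(cond$value))
      issues <- c(issues, paste0(where, ": comparator present iff value present"))
    if (!is.null(cond$comparator) && !cond$comparator %in% c("<", "<=", ">", ">=", "="))
      issues <- c(issues, paste0(where, ": unknown comparator"))
    if (!is.null(cond$temporal)) {
      issues <- c(issues, validate_temporal(cond$temporal, where))
      if (cond$temporal$direction != "past")
        issues <- c(issues, paste0(where, ": condition temporals must be past-looking"))
    }
  }
  if (is.null(x$action) || !nzchar(normalize_term(x$action$procedure)))
    issues <- c(issues, "action procedure must be non-empty")
  if (!is.null(x$action$temporal))
    issues <- c(issues, validate_temporal(x$action$temporal, "action"))
  if (!is.null(x$metadata) && !nzchar(normalize_term(x$metadata$source_title)))
    issues <- c(issues, "metadata source_title must be non-empty")
  issues
}

# ---- file and JSON interfaces ----------------------------------------------

#' Read a CELS corpus from a DSL text file
#'
#' One statement per line; blank lines and lines starting with `#` are
#' ignored. Parse errors are reported with the file line number.
#'
#' @param path file path (UTF-8).
#' @return list of [cels] objects; ids are `<basename>-L<line>`.
#' @export
read_cels_file <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  base <- tools::file_path_sans_ext(basename(path))
  out <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    x <- tryCatch(parse_cels(ln, id = sprintf("%s-L%d", base, i)),
                  cels_error = function(e) {
                    cels_error(sprintf("%s:%d: %s", path, i, conditionMessage(e)))
                  })
    out <- c(out, list(x))
  }
  out
}

#' Write a CELS corpus to a DSL text file
#' @param corpus list of [cels] objects.
#' @param path output path; written UTF-8 with LF endings.
#' @return `path`, invisibly.
#' @export
write_cels_file <- function(corpus, path) {
  writeLines(vapply(corpus, serialize_cels, character(1)), path, useBytes = TRUE)
  invisible(path)
}

temporal_to_list <- function(ts) {
  if (is.null(ts)) return(NULL)
  list(direction = ts$direction,
       window_min_months = ts$window_min_months,
       window_max_months = ts$window_max_months,
       recurrence = ts$recurrence,
       points = ts$points,
       segments = ts$segments)
}

# JSON deserialization maps absent optional fields to NULL or to an
# empty object; treat both as absent.
empty2null <- function(x) {
  if (is.null(x) || (is.list(x) && length(x) == 0L)) NULL else x
}

temporal_from_list <- function(l) {
  l <- empty2null(l)
  if (is.null(l)) return(NULL)
  segs <- empty2null(l$segments)
  if (!is.null(segs)) segs <- lapply(segs, function(s) as.numeric(unlist(s)))
  rec <- empty2null(l$recurrence)
  if (!is.null(rec))
    rec <- list(interval_months = as.numeric(rec$interval_months),
                duration_months = as.numeric(rec$duration_months))
  temporal_spec(l$direction, segments = segs, recurrence = rec)
}

#' Convert a CELS to a plain list mirroring its fields
#'
#' The list form is the JSON serialization: field names mirror the
#' domain types exactly, so `cels_from_list(cels_to_list(x))` is the
#' identity.
#'
#' @param x a [cels] object.
#' @return a nested plain list.
#' @export
cels_to_list <- function(x) {
  list(
    id = x$id,
    conditions = lapply(x$conditions, function(cond) list(
      term = cond$term, comparator = cond$comparator, value = cond$value,
      unit = cond$unit, temporal = temporal_to_list(cond$temporal),
      negated = cond$negated, flagged = cond$flagged)),
    connectives = as.list(x$connectives),
    action = list(procedure = x$action$procedure,
                  temporal = temporal_to_list(x$action$temporal),
                  flagged = x$action$flagged),
    polarity = x$polarity,
    metadata = if (is.null(x$metadata)) NULL else unclass(x$metadata)
  )
}

#' Rebuild a CELS from its plain-list (JSON) form
#' @param l a list as produced by [cels_to_list()].
#' @return a [cels] object.
#' @export
cels_from_list <- function(l) {
  conds <- lapply(l$conditions, function(cond) {
    val <- empty2null(cond$value)
    condition(cond$term, comparator = empty2null(cond$comparator),
              value = if (is.null(val)) NULL else as.numeric(val),
              unit = empty2null(cond$unit),
              temporal = temporal_from_list(cond$temporal),
              negated = isTRUE(cond$negated), flagged = isTRUE(cond$flagged))
  })
  act <- action_spec(l$action$procedure,
                     temporal = temporal_from_list(l$action$temporal),
                     flagged = isTRUE(l$action$flagged))
  meta <- empty2null(l$metadata)
  if (!is.null(meta))
    meta <- source_meta(meta$source_title, meta$authors %||% "",
                        meta$year %||% "", meta$evidence_kind %||% "guideline")
  cels(conds, act, connectives = unlist(l$connectives) %||% character(0),
       polarity = l$polarity, id = empty2null(l$id), metadata = meta)
}
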