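# Internal helpers shared across modules.

#' Normalize a surface term for comparison
#'
#' Trims leading/trailing whitespace and collapses internal runs of
#' whitespace to a single space. Storage of terms is case-preserving;
#' comparison keys are additionally lower-cased via [term_key()].
#'
#' @param x character vector of surface terms.
#' @return character vector of the same length.
#' @keywords internal
normalize_term <- function(x) {
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

#' Case-insensitive comparison key for a term
#' @param x character vector.
#' @return lower-cased normalized terms.
#' @keywords internal
term_key <- function(x) {
  tolower(normalize_term(x))
}

#' Round half-up to a fixed number of decimals
#'
#' Base R `round()` rounds half to even; audit percentages are defined
#' with half-up rounding (0.05 at one decimal rounds to 0.1).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  floor(x * scale + 0.5 + 1e-9) / scale
}

# Slugify a free-text name into an identifier-safe token:
# alphanumerics kept, word-initial capitalisation, everything else dropped.
slugify <- function(x, sep = "") {
  x <- normalize_term(x)
  parts <- strsplit(gsub("[^A-Za-z0-9]+", " ", x), " ", fixed = TRUE)[[1]]
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) return("X")
  parts <- paste0(toupper(substring(parts, 1L, 1L)), substring(parts, 2L))
  paste(parts, collapse = sep)
}

# Format a number the way the DSL prints it: no scientific notation,
# no trailing zeros ("4", "4.5", "0.25").
format_num <- function(x) {
  format(x, scientific = FALSE, trim = TRUE, drop0trailing = TRUE)
}

# Evaluate a body with a temporarily seeded RNG, restoring prior state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Minimal XML text escaping for element content and attribute values.
xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
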