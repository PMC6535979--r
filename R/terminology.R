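# SNOMED CT-subset terminology: surface-term lookup, unmapped-term
# classification, and extensional/intensional value sets.
#
# Lookup is exact on the normalized (whitespace-collapsed,
# case-insensitive) term key. No fuzzy or synonym matching: substituting
# a near-synonym changes the clinical meaning of a recommendation and is
# a human judgement, not a compiler step.

#' Construct a terminology subset
#'
#' @param entries a data frame with columns `term`, `concept_ids` (a
#'   semicolon-separated string or a list column of character vectors)
#'   and `match_type` (`"precoordinated"` for exactly one concept id,
#'   `"postcoordinated"` for two or more).
#' @param hierarchy optional data frame with columns `child`, `parent`
#'   giving is-a links between concept ids; must be acyclic.
#' @param english_lexicon character vector of common-English tokens used
#'   to classify unmapped terms; defaults to the packaged lexicon.
#' @return an object of class `terminology`.
#' @export
terminology <- function(entries = NULL, hierarchy = NULL,
                        english_lexicon = NULL) {
  tab <- new.env(parent = emptyenv())
  terms <- character(0)
  if (!is.null(entries) && nrow(entries) > 0L) {
    ids <- entries$concept_ids
    if (!is.list(ids)) ids <- strsplit(as.character(ids), ";", fixed = TRUE)
    keys <- term_key(entries$term)
    dup <- keys[duplicated(keys)]
    if (length(dup))
      cels_error(sprintf("duplicate terminology term(s): %s",
                         paste(unique(dup), collapse = ", ")),
                 "terminology_error")
    for (i in seq_len(nrow(entries))) {
      cids <- trimws(ids[[i]])
      cids <- cids[nzchar(cids)]
      mt <- as.character(entries$match_type[i])
      if (!mt %in% c("precoordinated", "postcoordinated"))
        cels_error(sprintf("row %d: bad match_type %s", i, deparse(mt)),
                   "terminology_error")
      if ((mt == "precoordinated") != (length(cids) == 1L))
        cels_error(sprintf(
          "row %d (%s): %s requires %s concept id(s), found %d",
          i, entries$term[i], mt,
          if (mt == "precoordinated") "exactly one" else "two or more",
          length(cids)), "terminology_error")
      assign(keys[i], concept_match(cids, mt), envir = tab)
    }
    terms <- entries$term
  }
  if (!is.null(hierarchy) && nrow(hierarchy) > 0L) {
    hierarchy <- data.frame(child = as.character(hierarchy$child),
                            parent = as.character(hierarchy$parent),
                            stringsAsFactors = FALSE)
    if (anyDuplicated(hierarchy$child))
      cels_error("hierarchy: a concept may have at most one parent",
                 "terminology_error")
    check_hierarchy_acyclic(hierarchy)
  }
  if (is.null(english_lexicon)) english_lexicon <- english_phrase_lexicon()
  structure(
    list(table = tab, terms = terms, hierarchy = hierarchy,
         english_lexicon = tolower(english_lexicon)),
    class = "terminology"
  )
}

check_hierarchy_acyclic <- function(h) {
  parent_of <- stats::setNames(h$parent, h$child)
  for (start in h$child) {
    seen <- character(0)
    node <- start
    while (node %in% names(parent_of)) {
      if (node %in% seen)
        cels_error(sprintf("hierarchy cycle involving concept %s", node),
                   "terminology_error")
      seen <- c(seen, node)
      node <- unname(parent_of[[node]])
    }
  }
  invisible(TRUE)
}

#' @export
print.terminology <- function(x, ...) {
  cat(sprintf("<terminology> %d term(s), %d hierarchy link(s)\n",
              length(x$terms),
              if (is.null(x$hierarchy)) 0L else nrow(x$hierarchy)))
  invisible(x)
}

#' Concept match for a surface term
#'
#' A precoordinated expression is captured by a single concept
#' identifier; a postcoordinated expression combines two or more.
#'
#' @param concept_ids character vector of concept identifiers.
#' @param match_type `"precoordinated"` or `"postcoordinated"`; inferred
#'   from the number of ids when omitted.
#' @return an object of class `concept_match`.
#' @export
concept_match <- function(concept_ids,
                          match_type = if (length(concept_ids) == 1L)
                            "precoordinated" else "postcoordinated") {
  structure(list(concept_ids = as.character(concept_ids),
                 match_type = match_type),
            class = "concept_match")
}

#' Load a terminology subset from TSV or JSON
#'
#' The TSV layout is three tab-separated columns `term`, `concept_ids`
#' (semicolon-separated) and `match_type`, with a header row; `#` lines
#' are comments. JSON mirrors the same fields as an array of objects. A
#' companion hierarchy table (columns `child`, `parent`) may be passed
#' alongside.
#'
#' @param path terminology file (`.tsv`/`.txt` or `.json`).
#' @param hierarchy_path optional hierarchy TSV (`child<TAB>parent`).
#' @return a [terminology] object.
#' @examples
#' t <- load_terminology(system.file("extdata", "terminology_synthetic_subset.tsv",
#'                                   package = "celsify"))
#' map_term("Suspected PE", t)
#' @export
load_terminology <- function(path, hierarchy_path = NULL) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    entries <- data.frame(term = raw$term,
                          concept_ids = I(as.list(raw$concept_ids)),
                          match_type = raw$match_type,
                          stringsAsFactors = FALSE)
  } else {
    entries <- utils::read.delim(path, header = TRUE, sep = "\t",
                                 comment.char = "#", quote = "",
                                 stringsAsFactors = FALSE,
                                 colClasses = "character")
    need <- c("term", "concept_ids", "match_type")
    if (!all(need %in% names(entries)))
      cels_error(sprintf("terminology file must have columns %s",
                         paste(need, collapse = ", ")), "terminology_error")
    if (nrow(entries) > 0L && any(!nzchar(entries$term)))
      cels_error("terminology file: empty term", "terminology_error")
  }
  hierarchy <- NULL
  if (!is.null(hierarchy_path)) {
    hierarchy <- utils::read.delim(hierarchy_path, header = TRUE, sep = "\t",
                                   comment.char = "#", quote = "",
                                   stringsAsFactors = FALSE,
                                   colClasses = "character")
    if (!all(c("child", "parent") %in% names(hierarchy)))
      cels_error("hierarchy file must have columns child, parent",
                 "terminology_error")
  }
  terminology(entries, hierarchy = hierarchy)
}

#' The packaged common-English token lexicon
#'
#' Tokens of ordinary English phrases that clinical terminologies do not
#' model ("new feature", "vehicle rollover", "suitable candidate").
#' Used to classify unmapped terms into English-phrase versus
#' clinical-term failures.
#'
#' @return character vector of lower-case tokens.
#' @export
english_phrase_lexicon <- function() {
  path <- system.file("extdata", "english_tokens.txt", package = "celsify")
  if (!nzchar(path)) return(character(0))
  tok <- readLines(path, warn = FALSE)
  tok <- trimws(tok)
  tolower(tok[nzchar(tok) & !startsWith(tok, "#")])
}

#' Map a surface term to its concept match
#'
#' Exact lookup on the normalized term key. An unmapped term is
#' classified by reason: `english_phrase` when any of its tokens appears
#' in the common-English lexicon, `clinical_term` otherwise (named
#' scores and rules such as "Alvarado score" fall here).
#'
#' @param term non-empty surface term.
#' @param t a [terminology] object.
#' @return a `concept_match`, or an object of class `unmapped_term` with
#'   a `reason` field.
#' @examples
#' t <- terminology(data.frame(term = "Suspected PE", concept_ids = "417113001",
#'                             match_type = "precoordinated"))
#' map_term("suspected pe", t)$concept_ids
#' map_term("Alvarado score", t)$reason
#' @export
map_term <- function(term, t) {
  key <- term_key(term)
  if (!nzchar(key))
    cels_error("map_term: empty term", "terminology_error")
  if (exists(key, envir = t$table, inherits = FALSE))
    return(get(key, envir = t$table))
  tokens <- strsplit(gsub("[^a-z0-9-]+", " ", key), " ", fixed = TRUE)[[1]]
  tokens <- tokens[nzchar(tokens)]
  reason <- if (any(tokens %in% t$english_lexicon)) "english_phrase"
            else "clinical_term"
  structure(list(term = normalize_term(term), reason = reason),
            class = "unmapped_term")
}

#' Test whether a term maps in a terminology
#' @inheritParams map_term
#' @return logical.
#' @export
is_mapped <- function(term, t) {
  inherits(map_term(term, t), "concept_match")
}

#' Define a value set
#'
#' @param name value-set name.
#' @param kind `"extensional"` (explicit member list) or `"intensional"`
#'   (a hierarchy rule: a root concept, optionally with all its
#'   descendants).
#' @param members character vector of concept ids (extensional only;
#'   must be non-empty).
#' @param root root concept id (intensional only).
#' @param descendants logical; include all hierarchy descendants of the
#'   root (intensional only).
#' @return an object of class `value_set`.
#' @export
value_set <- function(name, kind = c("extensional", "intensional"),
                      members = NULL, root = NULL, descendants = TRUE) {
  kind <- match.arg(kind)
  if (kind == "extensional" && length(members) == 0L)
    cels_error("extensional value set must have members", "terminology_error")
  if (kind == "intensional" && is.null(root))
    cels_error("intensional value set needs a root concept", "terminology_error")
  structure(list(name = name, kind = kind,
                 members = as.character(members %||% character(0)),
                 root = root, descendants = isTRUE(descendants)),
            class = "value_set")
}

#' Expand a value set to its concept ids
#'
#' Extensional sets return their members verbatim (duplicates removed,
#' order preserved). Intensional sets return the root plus, when the
#' descendants flag is set, every concept below it in the hierarchy,
#' in deterministic order: root first, then descendants sorted by id.
#'
#' @param vs a [value_set()].
#' @param t a [terminology] with a hierarchy (intensional sets only).
#' @return character vector of concept ids, duplicate-free.
#' @export
expand_value_set <- function(vs, t) {
  if (vs$kind == "extensional") return(unique(vs$members))
  h <- t$hierarchy
  known <- if (is.null(h)) character(0) else unique(c(h$child, h$parent))
  if (!vs$root %in% known)
    cels_error(sprintf("unknown root concept %s", vs$root), "terminology_error")
  if (!vs$descendants) return(vs$root)
  out <- character(0)
  frontier <- vs$root
  while (length(frontier)) {
    kids <- sort(h$child[h$parent %in% frontier])
    kids <- setdiff(kids, c(out, vs$root))
    out <- c(out, kids)
    frontier <- kids
  }
  c(vs$root, sort(out))
}
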