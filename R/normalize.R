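#' Construct a concept match
#'
#' One standardized-code candidate for a surface form, as returned by a
#' concept-normalization service: a code system, a code, a rank (1 = most
#' similar), and a similarity score in \[0, 1\].
#'
#' @param code_system one of `"CUI"`, `"ICD10"`, `"ATC"`, `"SNOMED"`.
#' @param code code string.
#' @param rank integer rank, 1-based.
#' @param score similarity in \[0, 1\].
#' @return an object of class `cx_match`.
#' @export
concept_match <- function(code_system, code, rank = 1L, score = 1) {
  structure(list(code_system = as.character(code_system),
                 code = as.character(code),
                 rank = as.integer(rank), score = as.numeric(score)),
            class = "cx_match")
}

match_key <- function(m) paste(m$code_system, m$code, sep = ":")

#' Construct a concept lexicon
#'
#' A local, offline stand-in for a metathesaurus lookup service: a mapping
#' from normalized surface strings to ranked code lists. Each entry's list
#' is sorted by rank, ranks contiguous from 1; [encode_term()] truncates to
#' the top 10 on lookup, emulating a top-10 match interface.
#'
#' @param entries named list: normalized surface -> list of
#'   [concept_match()]es (or lists with `code_system`, `code`, `score`).
#' @param code_system the code system this lexicon declares.
#' @return an object of class `cx_lexicon`.
#' @export
concept_lexicon <- function(entries, code_system = "CUI") {
  keys <- normalize_surface(names(entries))
  ents <- lapply(seq_along(entries), function(i) {
    ms <- entries[[i]]
    ms <- lapply(seq_along(ms), function(r) {
      m <- ms[[r]]
      concept_match(m$code_system %||% code_system, m$code,
                    rank = m$rank %||% r, score = m$score %||% 1)
    })
    ranks <- vapply(ms, `[[`, integer(1), "rank")
    if (length(ranks) > 0 && !identical(ranks, seq_along(ranks))) {
      cx_validation_error(sprintf(
        "lexicon entry '%s': ranks must be contiguous from 1", names(entries)[i]))
    }
    ms
  })
  names(ents) <- keys
  structure(list(entries = ents, code_system = code_system),
            class = "cx_lexicon")
}

#' Read/write a concept lexicon as JSON
#'
#' The file maps surface form to an ordered array of
#' `{"code_system": ..., "code": ..., "score": ...}` objects; rank is the
#' array position.
#'
#' @param path path to the JSON file.
#' @param lexicon a [concept_lexicon()].
#' @param code_system default code system for entries that omit it.
#' @return `read_concept_lexicon()` returns a `cx_lexicon`;
#'   `write_concept_lexicon()` returns `path` invisibly.
#' @export
read_concept_lexicon <- function(path, code_system = "CUI") {
  if (!file.exists(path)) cx_input_error(sprintf("file not found: %s", path))
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  cs <- raw$code_system %||% code_system
  entries <- raw$entries %||% raw
  lex <- concept_lexicon(entries, code_system = cs)
  if (!is.null(raw$categories)) {
    attr(lex, "categories") <- unlist(raw$categories)
  }
  lex
}

#' @rdname read_concept_lexicon
#' @export
write_concept_lexicon <- function(lexicon, path) {
  entries <- lapply(lexicon$entries, function(ms) {
    lapply(ms, function(m) list(code_system = m$code_system, code = m$code,
                                score = m$score))
  })
  obj <- list(code_system = lexicon$code_system, entries = entries)
  cats <- attr(lexicon, "categories")
  if (!is.null(cats)) obj$categories <- as.list(cats)
  writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)),
             path, useBytes = TRUE)
  invisible(path)
}

#' Construct a normalized term
#'
#' An extracted term together with its ranked list of standardized-code
#' matches (at most 10, most similar first).
#'
#' @param term an [extracted_term()].
#' @param matches list of [concept_match()]es sorted by rank.
#' @return an object of class `cx_nterm`.
#' @export
normalized_term <- function(term, matches = list()) {
  if (length(matches) > 10) {
    cx_validation_error("a normalized term carries at most 10 matches")
  }
  structure(list(term = term, matches = matches), class = "cx_nterm")
}

#' Top-ranked code of a normalized term
#'
#' @param nterm a [normalized_term()].
#' @return a list with `code_system` and `code`, or `NULL` when the term has
#'   no matches.
#' @export
primary_code <- function(nterm) {
  if (length(nterm$matches) == 0) return(NULL)
  m <- nterm$matches[[1]]
  list(code_system = m$code_system, code = m$code)
}

# dedup/evaluation key: top-ranked code when available, else normalized surface
entity_key <- function(nterm) {
  pc <- primary_code(nterm)
  if (is.null(pc)) {
    paste0("surf:", normalize_surface(nterm$term$surface))
  } else {
    paste0("code:", pc$code_system, ":", pc$code)
  }
}

#' Normalize a term to ranked standardized codes
#'
#' Looks the term's surface up in the lexicon under the canonical normalized
#' key (lowercase, punctuation stripped, whitespace collapsed); when the
#' exact key misses and ends in "s", a naive singular (trailing "s"
#' stripped) is tried, so that e.g. "hematomas" hits a "hematoma" entry.
#' A hit returns the entry's ranked list truncated to the top 10; a miss
#' returns a term with no matches (not an error — such terms remain
#' comparable by surface only).
#'
#' @param term an [extracted_term()].
#' @param lexicon a [concept_lexicon()].
#' @return a [normalized_term()].
#' @export
encode_term <- function(term, lexicon) {
  key <- normalize_surface(term$surface)
  entry <- lexicon$entries[[key]]
  if (is.null(entry) && endsWith(key, "s")) {
    entry <- lexicon$entries[[strip_plural(key)]]
  }
  matches <- if (is.null(entry)) list() else utils::head(entry, 10)
  matches <- lapply(seq_along(matches), function(r) {
    m <- matches[[r]]; m$rank <- r; m
  })
  normalized_term(term, matches)
}

#' Collapse duplicate entities within a document
#'
#' Terms sharing the same top-ranked code (or, when a term has no matches,
#' the same normalized surface) are collapsed to one representative: the
#' earliest mention by span start. Output order follows the first occurrence
#' of each key in the input, so the operation is deterministic and
#' idempotent.
#'
#' @param nterms list of [normalized_term()]s from one document.
#' @return list of `cx_nterm` with distinct keys.
#' @export
deduplicate_entities <- function(nterms) {
  if (length(nterms) == 0) return(list())
  keys <- vapply(nterms, entity_key, character(1))
  reps <- lapply(unique(keys), function(k) {
    group <- nterms[keys == k]
    starts <- vapply(group, function(nt) {
      if (is.na(nt$term$start)) .Machine$integer.max else nt$term$start
    }, integer(1))
    group[[which.min(starts)]]
  })
  reps
}
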