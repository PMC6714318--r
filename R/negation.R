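#' Construct a negation trigger lexicon
#'
#' Holds the phrase lists driving NegEx-style negation detection:
#' pre-triggers negate terms that follow them ("no", "denies"), post-triggers
#' negate terms that precede them ("was ruled out"), pseudo-triggers look
#' like triggers but are ignored ("no increase"), and terminators end a
#' negation scope ("but", "however"). The scope of a trigger is bounded by
#' `window` tokens within the sentence.
#'
#' @param pre_triggers,post_triggers,pseudo_triggers,terminators character
#'   vectors of lowercase phrases.
#' @param window maximum number of tokens a negation scope spans (default 5,
#'   the conventional NegEx setting).
#' @return an object of class `cx_neg_lexicon`.
#' @seealso [read_negation_lexicon()], [default_negation_lexicon()]
#' @export
negation_lexicon <- function(pre_triggers, post_triggers = character(),
                             pseudo_triggers = character(),
                             terminators = character(), window = 5L) {
  check <- function(x, nm) {
    x <- as.character(x)
    if (any(!nzchar(x))) cx_validation_error(sprintf("empty phrase in %s", nm))
    tolower(x)
  }
  if (!is.numeric(window) || window < 1) {
    cx_validation_error("window must be a positive integer")
  }
  structure(list(pre_triggers = check(pre_triggers, "pre_triggers"),
                 post_triggers = check(post_triggers, "post_triggers"),
                 pseudo_triggers = check(pseudo_triggers, "pseudo_triggers"),
                 terminators = check(terminators, "terminators"),
                 window = as.integer(window)),
            class = "cx_neg_lexicon")
}

#' Read a negation lexicon from a tab-separated file
#'
#' One entry per line: `phrase<TAB>role`, with roles `PRE`, `POST`, `PSEUDO`
#' or `TERM`. Lines starting with `#` are comments.
#'
#' @param path path to the lexicon file.
#' @param window scope window in tokens.
#' @return a [negation_lexicon()].
#' @export
read_negation_lexicon <- function(path, window = 5L) {
  if (!file.exists(path)) cx_input_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  phrases <- vapply(parts, `[`, character(1), 1)
  roles <- toupper(trimws(vapply(parts, `[`, character(1), 2)))
  negation_lexicon(pre_triggers = phrases[roles == "PRE"],
                   post_triggers = phrases[roles == "POST"],
                   pseudo_triggers = phrases[roles == "PSEUDO"],
                   terminators = phrases[roles == "TERM"],
                   window = window)
}

#' @rdname read_negation_lexicon
#' @export
default_negation_lexicon <- function(window = 5L) {
  read_negation_lexicon(system.file("extdata", "negex_triggers.tsv",
                                    package = "clinconex", mustWork = TRUE),
                        window = window)
}

# sentence ranges as 1-based inclusive (start, end) character offsets;
# boundaries are [.!?;] runs followed by whitespace or end of text
sentence_ranges <- function(text) {
  n <- nchar(text)
  if (n == 0) return(matrix(integer(0), ncol = 2))
  m <- gregexpr("[.!?;]+(\\s+|$)", text, perl = TRUE)[[1]]
  ends <- if (m[1] == -1L) integer(0) else as.integer(m) + attr(m, "match.length") - 1L
  ends <- unique(c(ends, n))
  starts <- c(1L, head(ends, -1) + 1L)
  cbind(starts, ends)
}

# token positions (start, end inclusive) and comparison keys within a string
tokenize <- function(s, offset = 0L) {
  m <- gregexpr("\\S+", s, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(list(start = integer(0), end = integer(0), key = character(0)))
  }
  start <- as.integer(m) + offset
  end <- start + attr(m, "match.length") - 1L
  raw <- substring(s, as.integer(m), as.integer(m) + attr(m, "match.length") - 1L)
  key <- gsub("^[^a-z0-9]+|[^a-z0-9]+$", "", tolower(raw), perl = TRUE)
  list(start = start, end = end, key = key)
}

# token-index ranges (i, j) where the phrase's tokens occur in sequence
phrase_occurrences <- function(keys, phrases) {
  out <- list()
  for (p in phrases) {
    ptoks <- strsplit(p, " ", fixed = TRUE)[[1]]
    k <- length(ptoks)
    if (k == 0 || length(keys) < k) next
    for (i in seq_len(length(keys) - k + 1)) {
      if (all(keys[i:(i + k - 1)] == ptoks)) {
        out[[length(out) + 1L]] <- c(i, i + k - 1L)
      }
    }
  }
  out
}

inside_any <- function(range, ranges) {
  any(vapply(ranges, function(r) range[1] >= r[1] && range[2] <= r[2], logical(1)))
}

#' Detect negated regions of a clinical text
#'
#' Applies NegEx-style trigger matching per sentence. For every non-pseudo
#' pre-trigger the scope runs forward from the trigger up to `window` tokens,
#' stopping at a terminator or the sentence end; post-trigger scopes run
#' symmetrically backward. Overlapping spans are merged. Spans are 0-based,
#' half-open character ranges into `text`.
#'
#' @param text document text.
#' @param lexicon a [negation_lexicon()]; defaults to the shipped trigger set.
#' @return list of negation spans, each a list with `start`, `end`, `trigger`.
#' @examples
#' lex <- negation_lexicon(pre_triggers = c("no", "denies"))
#' detect_negation_spans("patient denies a headache", lex)
#' @export
detect_negation_spans <- function(text, lexicon = default_negation_lexicon()) {
  if (is.null(text) || is.na(text) || !nzchar(text)) return(list())
  spans <- list()
  sents <- sentence_ranges(text)
  for (si in seq_len(nrow(sents))) {
    s0 <- sents[si, 1]; s1 <- sents[si, 2]
    toks <- tokenize(substr(text, s0, s1), offset = s0 - 1L)
    n <- length(toks$key)
    if (n == 0) next
    pseudo <- phrase_occurrences(toks$key, lexicon$pseudo_triggers)
    term_occ <- phrase_occurrences(toks$key, lexicon$terminators)
    term_idx <- unique(unlist(lapply(term_occ, function(r) r[1]:r[2])))
    w <- lexicon$window

    add_span <- function(from, to, trigger) {
      if (from > to) return()
      spans[[length(spans) + 1L]] <<- list(start = toks$start[from] - 1L,
                                           end = as.integer(toks$end[to]),
                                           trigger = trigger)
    }

    for (occ in phrase_occurrences(toks$key, lexicon$pre_triggers)) {
      if (inside_any(occ, pseudo)) next
      from <- occ[2] + 1L
      to <- min(occ[2] + w, n)
      stops <- term_idx[term_idx >= from & term_idx <= to]
      if (length(stops) > 0) to <- min(stops) - 1L
      add_span(from, to, paste(toks$key[occ[1]:occ[2]], collapse = " "))
    }
    for (occ in phrase_occurrences(toks$key, lexicon$post_triggers)) {
      if (inside_any(occ, pseudo)) next
      to <- occ[1] - 1L
      from <- max(occ[1] - w, 1L)
      stops <- term_idx[term_idx >= from & term_idx <= to]
      if (length(stops) > 0) from <- max(stops) + 1L
      add_span(from, to, paste(toks$key[occ[1]:occ[2]], collapse = " "))
    }
  }
  merge_spans(spans)
}

merge_spans <- function(spans) {
  if (length(spans) <= 1) return(spans)
  ord <- order(vapply(spans, `[[`, integer(1), "start"),
               vapply(spans, `[[`, integer(1), "end"))
  spans <- spans[ord]
  out <- list(spans[[1]])
  for (sp in spans[-1]) {
    last <- out[[length(out)]]
    if (sp$start < last$end) {
      last$end <- max(last$end, sp$end)
      if (!identical(last$trigger, sp$trigger)) {
        last$trigger <- paste(last$trigger, sp$trigger, sep = "+")
      }
      out[[length(out)]] <- last
    } else {
      out[[length(out) + 1L]] <- sp
    }
  }
  out
}

#' Flag terms that fall inside negated regions
#'
#' A term is flagged `negated = TRUE` when its character span overlaps any
#' negation span (any overlap counts). Terms without spans are located by
#' their first surface occurrence in `text`; if the surface does not occur,
#' the term is left unflagged. Input order is preserved.
#'
#' @param terms list of [extracted_term()]s from one document.
#' @param spans output of [detect_negation_spans()] on the same text.
#' @param text the document text, needed to locate span-less terms.
#' @return the terms with updated `negated` flags.
#' @export
flag_negated <- function(terms, spans, text = NULL) {
  if (length(spans) == 0) return(terms)
  starts <- vapply(spans, `[[`, integer(1), "start")
  ends <- vapply(spans, `[[`, integer(1), "end")
  lapply(terms, function(t) {
    s <- t$start; e <- t$end
    if (is.na(s) && !is.null(text)) {
      m <- regexpr(paste0("\\b", escape_regex(t$surface), "\\b"), text,
                   ignore.case = TRUE, perl = TRUE)
      if (m[1] != -1L) {
        s <- m[1] - 1L
        e <- m[1] + attr(m, "match.length") - 1L
      }
    }
    if (!is.na(s) && any(s < ends & starts < e)) t$negated <- TRUE
    t
  })
}

#' Apply the negation filter
#'
#' The kappa hyperparameter switches negation filtering on or off: with
#' `kappa = TRUE`, terms flagged as negated are removed; with
#' `kappa = FALSE` the input is returned unchanged. The filtered list is
#' always a subset of the unfiltered one, so recall with the filter on can
#' never exceed recall with it off.
#'
#' @param terms flagged terms (see [flag_negated()]); [normalized_term()]s
#'   are accepted too, using their inner term's flag.
#' @param kappa logical; filter negated terms?
#' @return list of terms.
#' @export
apply_negation_filter <- function(terms, kappa) {
  if (!isTRUE(kappa)) return(terms)
  Filter(function(t) {
    flag <- if (inherits(t, "cx_nterm")) t$term$negated else t$negated
    !isTRUE(flag)
  }, terms)
}
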