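#' Specification for a synthetic evaluation corpus
#'
#' Describes a simulated study: a concept lexicon, a corpus of template
#' clinical notes with embedded gold entities (some under negation
#' triggers), and per-extractor outputs with controlled sensitivity and
#' spurious-mention rates. Everything downstream of this spec is a pure
#' function of it, so identical seeds give identical corpora.
#'
#' @param seed integer seed; every generator derives its randomness from it.
#' @param n_docs number of documents.
#' @param lexicon_size number of surface forms in the lexicon.
#' @param entities_per_doc integer range `c(min, max)` of gold entities per
#'   document (a single value fixes the count).
#' @param negation_rate probability that a gold entity is embedded under a
#'   negation trigger and annotated with polarity absent.
#' @param extractor_profiles named list (extractor id -> list with
#'   `sensitivity` (probability of emitting each true entity),
#'   `spurious_rate` (expected spurious mentions per document), and
#'   `categories` (entity categories the extractor supports)).
#' @return an object of class `cx_simspec`.
#' @export
simulation_spec <- function(seed = 1L, n_docs = 20L, lexicon_size = 60L,
                            entities_per_doc = c(2L, 5L), negation_rate = 0.1,
                            extractor_profiles = default_extractor_profiles()) {
  if (length(entities_per_doc) == 1) entities_per_doc <- rep(entities_per_doc, 2)
  stopifnot(length(entities_per_doc) == 2)
  if (n_docs < 1 || lexicon_size < 1 || any(entities_per_doc < 1)) {
    cx_validation_error("n_docs, lexicon_size, entities_per_doc must be positive")
  }
  if (negation_rate < 0 || negation_rate > 1) {
    cx_validation_error("negation_rate must lie in [0, 1]")
  }
  for (id in names(extractor_profiles)) {
    p <- extractor_profiles[[id]]
    if (p$sensitivity < 0 || p$sensitivity > 1 || p$spurious_rate < 0) {
      cx_validation_error(sprintf("invalid profile for extractor '%s'", id))
    }
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 lexicon_size = as.integer(lexicon_size),
                 entities_per_doc = as.integer(entities_per_doc),
                 negation_rate = negation_rate,
                 extractor_profiles = extractor_profiles),
            class = "cx_simspec")
}

#' @rdname simulation_spec
#' @export
default_extractor_profiles <- function() {
  both <- c("medical_condition", "pharmaceutical_drug")
  list(alpha = list(sensitivity = 0.9, spurious_rate = 0.5, categories = both),
       bravo = list(sensitivity = 0.8, spurious_rate = 0.5, categories = both),
       charlie = list(sensitivity = 0.7, spurious_rate = 0.5, categories = both))
}

# fixed clinical stub surfaces always present in generated lexica
CLINICAL_STUBS <- list(
  asthma = "medical_condition", depression = "medical_condition",
  hematoma = "medical_condition", `orthostatic hypotension` = "medical_condition",
  hypertension = "medical_condition", `diabetes mellitus` = "medical_condition",
  pneumonia = "medical_condition", anemia = "medical_condition",
  `atrial fibrillation` = "medical_condition", fracture = "medical_condition",
  headache = "medical_condition", obesity = "medical_condition",
  aspirin = "pharmaceutical_drug", metformin = "pharmaceutical_drug",
  lisinopril = "pharmaceutical_drug", warfarin = "pharmaceutical_drug",
  simvastatin = "pharmaceutical_drug", omeprazole = "pharmaceutical_drug")

pseudo_term <- function(n_syllables) {
  syl <- c("car", "vel", "tor", "min", "lox", "ban", "dor", "fen", "gal",
           "hep", "lin", "mer", "nor", "pol", "quin", "ril", "sol", "tam",
           "ver", "zed")
  paste(sample(syl, n_syllables, replace = TRUE), collapse = "")
}

random_cui <- function(n) sprintf("C%07d", sample.int(9999999L, n))

#' Generate a synthetic concept lexicon
#'
#' Builds a deterministic lexicon of `lexicon_size` surface forms: a fixed
#' clinical stub list (asthma, depression, hematoma, orthostatic
#' hypotension, ...) padded with pronounceable pseudo-terms, each mapped to
#' 3-10 ranked CUI-style codes with descending similarity scores. Every
#' fifth pseudo-term gets a near-synonym companion surface sharing its top
#' two codes, so that cross-extractor merging of distinct-but-equivalent
#' surfaces is exercised. The entity category of each surface is stored in
#' the `"categories"` attribute.
#'
#' @param spec a [simulation_spec()].
#' @return a [concept_lexicon()] with a `"categories"` attribute.
#' @export
generate_lexicon <- function(spec) {
  set.seed(spec$seed)
  surfaces <- utils::head(names(CLINICAL_STUBS), spec$lexicon_size)
  categories <- unlist(CLINICAL_STUBS[surfaces])
  n_extra <- spec$lexicon_size - length(surfaces)
  synonyms <- character(0)
  i <- 0L
  while (length(surfaces) < spec$lexicon_size) {
    i <- i + 1L
    s <- pseudo_term(sample(2:3, 1))
    if (s %in% surfaces) next
    cat_i <- if (i %% 2 == 0) "pharmaceutical_drug" else "medical_condition"
    surfaces <- c(surfaces, s)
    categories <- c(categories, stats::setNames(cat_i, s))
    if (i %% 5 == 0 && length(surfaces) < spec$lexicon_size) {
      syn <- paste0(s, "osis")
      surfaces <- c(surfaces, syn)
      categories <- c(categories, stats::setNames(cat_i, syn))
      synonyms <- c(synonyms, stats::setNames(syn, s))
    }
  }
  entries <- lapply(surfaces, function(s) {
    k <- sample(3:10, 1)
    codes <- random_cui(k)
    lapply(seq_len(k), function(r) {
      list(code_system = "CUI", code = codes[r],
           score = round(1 - 0.04 * (r - 1), 3))
    })
  })
  names(entries) <- surfaces
  # near-synonyms share their base term's top-2 codes
  for (base in names(synonyms)) {
    syn <- synonyms[[base]]
    entries[[syn]][1:2] <- entries[[base]][1:2]
    entries[[syn]] <- lapply(seq_along(entries[[syn]]), function(r) {
      m <- entries[[syn]][[r]]; m$score <- round(1 - 0.04 * (r - 1), 3); m
    })
  }
  lex <- concept_lexicon(entries, code_system = "CUI")
  attr(lex, "categories") <- categories
  attr(lex, "synonyms") <- synonyms
  lex
}

affirm_templates <- list(
  medical_condition = c("The patient has %s.", "Examination revealed %s.",
                        "History is notable for %s."),
  pharmaceutical_drug = c("The patient was given %s.",
                          "Treatment with %s was started.",
                          "Current medication includes %s."))
negate_templates <- list(
  medical_condition = c("No %s was found.", "Patient denies %s.",
                        "There is no evidence of %s."),
  pharmaceutical_drug = c("No %s was administered.",
                          "Patient denies taking %s."))

#' Generate a synthetic corpus with gold annotations
#'
#' Each document is template prose with a per-document number of embedded
#' gold entities drawn from the lexicon. A `negation_rate` fraction of
#' entities are wrapped in negation-trigger templates ("No X was found.",
#' "Patient denies X.") and annotated with polarity absent; the rest are
#' affirmative and present. Gold rows carry the surface, the surface's full
#' code list from the lexicon, the category, and the polarity.
#'
#' @param spec a [simulation_spec()].
#' @param lexicon a lexicon from [generate_lexicon()].
#' @return list with `documents` (list of [document()]) and `gold` (list of
#'   [gold_annotation()]).
#' @export
generate_corpus <- function(spec, lexicon) {
  set.seed(spec$seed + 1L)
  categories <- attr(lexicon, "categories")
  if (is.null(categories)) {
    cx_validation_error("lexicon lacks a categories attribute; use generate_lexicon()")
  }
  surfaces <- names(categories)
  documents <- list()
  gold <- list()
  for (d in seq_len(spec$n_docs)) {
    did <- sprintf("doc%04d", d)
    lo <- spec$entities_per_doc[1]; hi <- spec$entities_per_doc[2]
    n_ent <- lo + sample.int(hi - lo + 1L, 1L) - 1L
    picked <- sample(surfaces, min(n_ent, length(surfaces)))
    sentences <- character(0)
    for (s in picked) {
      cat_s <- categories[[s]]
      negated <- stats::runif(1) < spec$negation_rate
      pool <- if (negated) negate_templates[[cat_s]] else affirm_templates[[cat_s]]
      sentences <- c(sentences, sprintf(sample(pool, 1), s))
      codes <- lapply(lexicon$entries[[normalize_surface(s)]], function(m) {
        list(code_system = m$code_system, code = m$code)
      })
      gold[[length(gold) + 1L]] <- gold_annotation(
        did, surface = s, codes = codes, category = cat_s,
        polarity = if (negated) "absent" else "present")
    }
    documents[[length(documents) + 1L]] <- document(
      did, paste(sentences, collapse = " "))
  }
  list(documents = documents, gold = gold)
}

#' Simulate per-extractor outputs with controlled error rates
#'
#' Each extractor emits each gold entity mention with probability
#' `sensitivity` (skipping categories outside its support, which emulates
#' backends that cannot extract drug entities), locating the mention's span
#' in the document text, and adds Poisson(`spurious_rate`) spurious lexicon
#' terms per document that do not occur in the text (span absent).
#' Deterministic under the spec's seed.
#'
#' @param documents,gold output of [generate_corpus()].
#' @param spec the same [simulation_spec()].
#' @param lexicon the lexicon, for spurious-term categories.
#' @return named list: extractor id -> named list (doc id -> list of
#'   [extracted_term()]s).
#' @export
simulate_extractor_outputs <- function(documents, gold, spec, lexicon) {
  set.seed(spec$seed + 2L)
  categories <- attr(lexicon, "categories")
  surfaces <- names(categories)
  gold_ids <- vapply(gold, `[[`, character(1), "doc_id")
  out <- list()
  for (ex_id in names(spec$extractor_profiles)) {
    profile <- spec$extractor_profiles[[ex_id]]
    per_doc <- list()
    for (doc in documents) {
      terms <- list()
      doc_gold <- gold[gold_ids == doc$doc_id]
      doc_surfaces <- vapply(doc_gold, `[[`, character(1), "surface")
      for (g in doc_gold) {
        if (!g$category %in% profile$categories) next
        if (stats::runif(1) >= profile$sensitivity) next
        m <- regexpr(paste0("\\b", escape_regex(g$surface), "\\b"), doc$text,
                     ignore.case = TRUE, perl = TRUE)
        if (m[1] == -1L) next
        terms[[length(terms) + 1L]] <- extracted_term(
          surface = substr(doc$text, m[1], m[1] + attr(m, "match.length") - 1L),
          start = m[1] - 1L, end = m[1] + attr(m, "match.length") - 1L,
          category = g$category, extractor_id = ex_id)
      }
      n_sp <- stats::rpois(1, profile$spurious_rate)
      if (n_sp > 0) {
        candidates <- setdiff(surfaces, doc_surfaces)
        candidates <- candidates[categories[candidates] %in% profile$categories]
        for (s in utils::head(sample(candidates), n_sp)) {
          terms[[length(terms) + 1L]] <- extracted_term(
            surface = s, category = categories[[s]], extractor_id = ex_id)
        }
      }
      per_doc[[doc$doc_id]] <- sort_terms(terms)
    }
    out[[ex_id]] <- per_doc
  }
  out
}

#' Write a simulated study to disk
#'
#' Writes `documents.jsonl`, `gold.jsonl`, `lexicon.json`, and one
#' `extractor_<id>.jsonl` per extractor profile into `dir`, in the formats
#' the pipeline readers expect.
#'
#' @param spec a [simulation_spec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the list of generated objects.
#' @export
write_simulation <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lexicon <- generate_lexicon(spec)
  corpus <- generate_corpus(spec, lexicon)
  outputs <- simulate_extractor_outputs(corpus$documents, corpus$gold, spec, lexicon)
  write_jsonl(lapply(corpus$documents, function(d)
    list(doc_id = d$doc_id, text = d$text)),
    file.path(dir, "documents.jsonl"))
  write_jsonl(lapply(corpus$gold, function(g)
    list(doc_id = g$doc_id, surface = g$surface, codes = g$codes,
         category = g$category, polarity = g$polarity)),
    file.path(dir, "gold.jsonl"))
  write_concept_lexicon(lexicon, file.path(dir, "lexicon.json"))
  for (ex_id in names(outputs)) {
    recs <- unlist(lapply(names(outputs[[ex_id]]), function(did) {
      lapply(outputs[[ex_id]][[did]], function(t)
        list(doc_id = did, surface = t$surface,
             start = if (is.na(t$start)) NULL else t$start,
             end = if (is.na(t$end)) NULL else t$end,
             category = t$category, extractor_id = t$extractor_id))
    }), recursive = FALSE)
    write_jsonl(recs, file.path(dir, sprintf("extractor_%s.jsonl", ex_id)))
  }
  invisible(list(lexicon = lexicon, documents = corpus$documents,
                 gold = corpus$gold, outputs = outputs))
}
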