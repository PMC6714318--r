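#' Construct a clinical document
#'
#' A document is the unit of extraction and evaluation: an identifier plus
#' raw clinical text (for example a discharge letter). Empty text is allowed
#' and simply yields zero extractions.
#'
#' @param doc_id non-empty string, unique within a corpus.
#' @param text raw clinical text (UTF-8).
#' @param metadata optional named list of key/value pairs.
#' @return an object of class `cx_document`.
#' @export
document <- function(doc_id, text = "", metadata = NULL) {
  if (!is.character(doc_id) || length(doc_id) != 1 || !nzchar(doc_id)) {
    cx_validation_error("doc_id must be a non-empty string")
  }
  if (is.null(text) || is.na(text)) text <- ""
  structure(list(doc_id = doc_id, text = as.character(text), metadata = metadata),
            class = "cx_document")
}

#' Construct a gold-standard annotation
#'
#' Gold annotations carry a surface form and/or a list of standardized codes,
#' a category, and a polarity. Classification-style gold (document-level
#' present/absent condition labels) uses polarity `"absent"` for conditions
#' annotated as not in the document; span-style gold lists only what occurs.
#' Any polarity value outside present/absent (e.g. "undecided", "unknown")
#' is normalized to absent.
#'
#' @param doc_id document identifier the annotation belongs to.
#' @param surface optional surface form.
#' @param codes optional list of codes, each a list with `code_system` and
#'   `code` elements.
#' @param category `"medical_condition"` or `"pharmaceutical_drug"`.
#' @param polarity `"present"` (default) or `"absent"`.
#' @return an object of class `cx_gold`.
#' @export
gold_annotation <- function(doc_id, surface = NULL, codes = NULL,
                            category = "medical_condition",
                            polarity = "present") {
  if (is.null(surface) && (is.null(codes) || length(codes) == 0)) {
    cx_validation_error(sprintf(
      "gold annotation for doc '%s' has neither surface nor codes", doc_id))
  }
  polarity <- chr1(polarity)
  if (is.na(polarity)) polarity <- "present"
  if (!polarity %in% c("present", "absent")) polarity <- "absent"
  if (!is.null(codes)) {
    codes <- lapply(codes, function(cd) {
      list(code_system = chr1(cd$code_system), code = chr1(cd$code))
    })
  }
  structure(list(doc_id = chr1(doc_id), surface = surface, codes = codes,
                 category = chr1(category), polarity = polarity),
            class = "cx_gold")
}

#' Read a corpus of clinical documents
#'
#' Reads either a JSONL file (one `{"doc_id": ..., "text": ...}` record per
#' line) or a directory of `.txt` files, where each file is one document and
#' the filename stem becomes the `doc_id`. Documents are returned in
#' lexicographic `doc_id` order so that downstream runs are deterministic.
#'
#' @param path file (jsonl) or directory (text_dir) to read.
#' @param format `"jsonl"` or `"text_dir"`.
#' @return list of [document()] objects sorted by `doc_id`.
#' @export
read_corpus <- function(path, format = c("jsonl", "text_dir")) {
  format <- match.arg(format)
  docs <- switch(format,
    jsonl = {
      records <- read_jsonl(path)
      lapply(records, function(r) {
        if (is.null(r$doc_id) || is.null(r$text)) {
          cx_validation_error("jsonl corpus records need doc_id and text fields")
        }
        document(chr1(r$doc_id), chr1(r$text), metadata = r$metadata)
      })
    },
    text_dir = {
      if (!dir.exists(path)) cx_input_error(sprintf("directory not found: %s", path))
      files <- list.files(path, pattern = "\\.txt$", full.names = TRUE)
      lapply(files, function(f) {
        txt <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
        document(tools::file_path_sans_ext(basename(f)), txt)
      })
    })
  ids <- vapply(docs, `[[`, character(1), "doc_id")
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    cx_validation_error(sprintf("duplicate doc_id in corpus: %s",
                                paste(unique(dup), collapse = ", ")))
  }
  docs[order(ids, method = "radix")]
}

#' Read gold-standard annotations
#'
#' Accepts JSONL or CSV with columns/fields `doc_id`, `surface` and/or
#' `codes`, `category`, `polarity`. In CSV, `codes` is a semicolon-separated
#' list of `system:code` pairs. Polarity values outside present/absent are
#' treated as absent; a missing polarity defaults to present.
#'
#' @param path path to a `.jsonl`/`.json` or `.csv` file.
#' @return list of [gold_annotation()] objects.
#' @export
read_gold <- function(path) {
  if (!file.exists(path)) cx_input_error(sprintf("file not found: %s", path))
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    records <- lapply(seq_len(nrow(df)), function(i) {
      r <- as.list(df[i, , drop = FALSE])
      if (!is.null(r$codes) && !is.na(r$codes) && nzchar(r$codes)) {
        parts <- strsplit(strsplit(r$codes, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
        r$codes <- lapply(parts, function(p) list(code_system = p[1], code = p[2]))
      } else {
        r$codes <- NULL
      }
      if (!is.null(r$surface) && (is.na(r$surface) || !nzchar(r$surface))) r$surface <- NULL
      r
    })
  } else {
    records <- read_jsonl(path)
  }
  lapply(records, function(r) {
    surface <- if (!is.null(r$surface)) chr1(r$surface) else NULL
    gold_annotation(r$doc_id, surface = surface, codes = r$codes,
                    category = chr1(r$category) %||% "medical_condition",
                    polarity = r$polarity %||% "present")
  })
}

entity_record <- function(e) {
  pc <- primary_code(e$representative)
  list(
    surface = e$representative$term$surface,
    primary_code = pc,
    extractor_ids = as.list(e$extractor_ids),
    cumulative_weight = e$cumulative_weight,
    members = lapply(e$members, nterm_record)
  )
}

nterm_record <- function(nt) {
  t <- nt$term
  list(term = list(surface = t$surface,
                   start = if (is.na(t$start)) NULL else t$start,
                   end = if (is.na(t$end)) NULL else t$end,
                   category = t$category,
                   extractor_id = t$extractor_id,
                   negated = t$negated),
       matches = lapply(nt$matches, function(m) {
         list(code_system = m$code_system, code = m$code,
              rank = m$rank, score = m$score)
       }))
}

record_nterm <- function(r) {
  t <- r$term
  term <- extracted_term(surface = chr1(t$surface),
                         start = if (is.null(t$start)) NA_integer_ else as.integer(t$start),
                         end = if (is.null(t$end)) NA_integer_ else as.integer(t$end),
                         category = chr1(t$category),
                         extractor_id = chr1(t$extractor_id),
                         negated = isTRUE(t$negated))
  matches <- lapply(r$matches, function(m) {
    concept_match(chr1(m$code_system), chr1(m$code),
                  rank = as.integer(m$rank), score = num1(m$score))
  })
  normalized_term(term, matches)
}

record_entity <- function(r) {
  members <- lapply(r$members, record_nterm)
  e <- new_merged_entity(members)
  e$cumulative_weight <- num1(r$cumulative_weight)
  e
}

#' Write and read extraction results as JSONL
#'
#' One JSON record per document, holding accepted and rejected entities
#' (surface, top code, contributing extractors, cumulative weight, and the
#' full member terms with their code matches) and the integration
#' configuration used. `read_results()` is the paired reader; a write/read
#' cycle reproduces every field, including weights at full double precision.
#'
#' @param results list of `cx_result` objects as produced by
#'   [integrate_terms()] or [run_extract()].
#' @param path output path (`.jsonl`).
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a list of `cx_result` objects.
#' @export
write_results <- function(results, path) {
  records <- lapply(results, function(res) {
    list(doc_id = res$doc_id,
         accepted = lapply(res$accepted, entity_record),
         rejected = lapply(res$rejected, entity_record),
         config = list(kappa = res$config$kappa, gamma = res$config$gamma,
                       theta = res$config$theta,
                       # as.list keeps extractor names in the JSON object
                       omega = as.list(res$config$omega)))
  })
  write_jsonl(records, path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  records <- read_jsonl(path)
  lapply(records, function(r) {
    cfg <- integration_config(kappa = isTRUE(r$config$kappa),
                              gamma = num1(r$config$gamma),
                              theta = num1(r$config$theta),
                              omega = unlist(r$config$omega))
    structure(list(doc_id = chr1(r$doc_id),
                   accepted = lapply(r$accepted, record_entity),
                   rejected = lapply(r$rejected, record_entity),
                   config = cfg),
              class = "cx_result")
  })
}
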