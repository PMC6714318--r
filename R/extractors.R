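CX_CATEGORIES <- c("medical_condition", "pharmaceutical_drug", "other")

#' Construct an extracted term
#'
#' A surface mention produced by one extractor. Spans are 0-based, half-open
#' `[start, end)` character offsets into the raw document text; a term may
#' have no span (e.g. a backend that does not report offsets), in which case
#' `start` and `end` are `NA`.
#'
#' @param surface non-empty extracted text span.
#' @param start,end character offsets, or `NA` when the backend reports none.
#' @param category `"medical_condition"`, `"pharmaceutical_drug"` or `"other"`.
#' @param extractor_id identifier of the producing extractor.
#' @param negated logical negation flag, set by [flag_negated()].
#' @return an object of class `cx_term`.
#' @export
extracted_term <- function(surface, start = NA_integer_, end = NA_integer_,
                           category = "other", extractor_id = "",
                           negated = FALSE) {
  if (!is.character(surface) || length(surface) != 1 || !nzchar(surface)) {
    cx_validation_error("term surface must be a non-empty string")
  }
  if (!category %in% CX_CATEGORIES) category <- "other"
  structure(list(surface = surface,
                 start = as.integer(start), end = as.integer(end),
                 category = category,
                 extractor_id = as.character(extractor_id),
                 negated = isTRUE(negated)),
            class = "cx_term")
}

#' Declare an extractor backend
#'
#' An extractor is any backend that returns entity mentions for a document.
#' Two kinds are supported: `"mock"` extractors, pure functions of the
#' document text and a fixture table (surface form to category), used for
#' testing and simulation; and `"rest"` adapters for remote NLP APIs,
#' described by an endpoint, credentials, a type-mapping table from backend
#' entity labels to the package's categories, and an injectable transport
#' function. Credentials are never read from command-line arguments.
#'
#' @param extractor_id unique identifier within an ensemble.
#' @param kind `"mock"` or `"rest"`.
#' @param supported_categories categories this backend can emit; fixture or
#'   response entities outside this set are dropped.
#' @param fixture for mock extractors, a named list/vector mapping surface
#'   form to category.
#' @param endpoint,credentials for rest extractors: URL and a list with a
#'   `token` element.
#' @param type_map for rest extractors, named list mapping backend entity
#'   type labels to categories; unmapped labels become `"other"`.
#' @param transport optional function(request) -> JSON payload used to
#'   execute a rest request; if absent, rest extraction signals a backend
#'   error (the ensemble runner then proceeds without this extractor).
#' @return an object of class `cx_extractor_spec`.
#' @export
extractor_spec <- function(extractor_id, kind = c("mock", "rest"),
                           supported_categories = c("medical_condition",
                                                    "pharmaceutical_drug"),
                           fixture = NULL, endpoint = NULL,
                           credentials = NULL, type_map = NULL,
                           transport = NULL) {
  kind <- match.arg(kind)
  if (!is.character(extractor_id) || !nzchar(extractor_id)) {
    cx_validation_error("extractor_id must be a non-empty string")
  }
  if (kind == "mock" && is.null(fixture)) {
    cx_config_error(sprintf("mock extractor '%s' needs a fixture table", extractor_id))
  }
  if (kind == "rest" && is.null(endpoint)) {
    cx_config_error(sprintf("rest extractor '%s' needs an endpoint", extractor_id))
  }
  structure(list(extractor_id = extractor_id, kind = kind,
                 supported_categories = supported_categories,
                 fixture = as.list(fixture), endpoint = endpoint,
                 credentials = credentials, type_map = type_map,
                 transport = transport),
            class = "cx_extractor_spec")
}

# fixture matching: case-insensitive, word boundaries, optional plural "s",
# longest surface first; overlapping shorter matches are suppressed
mock_extract <- function(text, spec) {
  fixture <- spec$fixture
  surfaces <- names(fixture)
  ord <- order(-nchar(surfaces), surfaces, method = "radix")
  claimed <- logical(nchar(text))
  terms <- list()
  for (s in surfaces[ord]) {
    category <- fixture[[s]]
    pattern <- paste0("\\b", escape_regex(s), "s?\\b")
    m <- gregexpr(pattern, text, ignore.case = TRUE, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    lens <- attr(m, "match.length")
    for (k in seq_along(m)) {
      idx <- m[k]:(m[k] + lens[k] - 1L)
      if (any(claimed[idx])) next
      claimed[idx] <- TRUE
      terms[[length(terms) + 1L]] <- extracted_term(
        surface = substr(text, m[k], m[k] + lens[k] - 1L),
        start = m[k] - 1L, end = m[k] + lens[k] - 1L,
        category = category, extractor_id = spec$extractor_id)
    }
  }
  terms
}

sort_terms <- function(terms) {
  if (length(terms) == 0) return(list())
  starts <- vapply(terms, function(t) {
    if (is.na(t$start)) .Machine$integer.max else t$start
  }, integer(1))
  surfaces <- vapply(terms, `[[`, character(1), "surface")
  terms[order(starts, surfaces, method = "radix")]
}

#' Run one extractor on one document
#'
#' Applies a mock or rest extractor and returns its mentions as
#' [extracted_term()] objects, restricted to the extractor's supported
#' categories and sorted by span start then surface. Rest transport failures
#' raise a condition of class `cx_backend_error` carrying the extractor id;
#' the ensemble runner catches these and continues with the remaining
#' extractors.
#'
#' @param doc a [document()].
#' @param spec an [extractor_spec()].
#' @return list of `cx_term` objects.
#' @export
extract_terms <- function(doc, spec) {
  if (!nzchar(doc$text)) return(list())
  terms <- switch(spec$kind,
    mock = mock_extract(doc$text, spec),
    rest = {
      request <- build_rest_request(doc, spec)
      if (is.null(spec$transport)) {
        cx_backend_error(sprintf("no transport configured for extractor '%s'",
                                 spec$extractor_id), spec$extractor_id)
      }
      payload <- tryCatch(spec$transport(request), error = function(e) {
        cx_backend_error(sprintf("extractor '%s' transport failed: %s",
                                 spec$extractor_id, conditionMessage(e)),
                         spec$extractor_id)
      })
      parse_rest_response(payload, spec)
    })
  keep <- vapply(terms, function(t) t$category %in% spec$supported_categories,
                 logical(1))
  sort_terms(terms[keep])
}

#' Build a REST request description for a document
#'
#' Returns a serializable description of the HTTP request an entity-
#' extraction API call would make: URL, authorization header, and a JSON
#' body holding the document text and `{"features": "entities"}`. No network
#' side effect occurs; the description is executed by the spec's transport
#' function (or recorded for contract tests).
#'
#' @inheritParams extract_terms
#' @return a list with `url`, `method`, `headers`, `body`.
#' @export
build_rest_request <- function(doc, spec) {
  if (spec$kind != "rest") cx_config_error("build_rest_request needs a rest extractor")
  token <- spec$credentials$token
  if (is.null(token) || !nzchar(token)) {
    cx_config_error(sprintf("extractor '%s' has no credentials token",
                            spec$extractor_id))
  }
  list(url = spec$endpoint,
       method = "POST",
       headers = list(Authorization = paste("Bearer", token),
                      `Content-Type` = "application/json"),
       body = list(text = doc$text, features = "entities"))
}

#' Parse a REST entity-extraction response
#'
#' Maps a backend-specific JSON entity array into [extracted_term()]s using
#' the extractor's type-mapping table; unknown entity type labels map to
#' category `"other"`. Accepts either a top-level array or an object with an
#' `entities` element; entities carry `text` (or `surface`) and `type`
#' fields and optional `start`/`end` offsets.
#'
#' @param payload JSON text (or an already-parsed list).
#' @param spec the [extractor_spec()] the payload came from.
#' @return list of `cx_term` objects.
#' @export
parse_rest_response <- function(payload, spec) {
  parsed <- if (is.character(payload)) {
    tryCatch(jsonlite::fromJSON(payload, simplifyVector = FALSE),
             error = function(e) {
               cx_parse_error(sprintf("extractor '%s' returned malformed JSON: %s",
                                      spec$extractor_id, conditionMessage(e)),
                              spec$extractor_id)
             })
  } else {
    payload
  }
  entities <- if (!is.null(parsed$entities)) parsed$entities else parsed
  terms <- lapply(entities, function(e) {
    surface <- chr1(e$text %||% e$surface)
    if (is.na(surface) || !nzchar(surface)) return(NULL)
    type <- chr1(e$type)
    category <- if (is.na(type)) NULL else spec$type_map[[type]]
    category <- chr1(category)
    if (is.na(category)) category <- "other"
    extracted_term(surface,
                   start = if (is.null(e$start)) NA_integer_ else as.integer(e$start),
                   end = if (is.null(e$end)) NA_integer_ else as.integer(e$end),
                   category = category, extractor_id = spec$extractor_id)
  })
  sort_terms(Filter(Negate(is.null), terms))
}
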