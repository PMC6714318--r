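`%||%` <- function(x, y) if (is.null(x)) y else x

cx_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "cx_error")))
}

#' @noRd
cx_input_error <- function(msg) cx_stop(msg, "cx_input_error")
cx_validation_error <- function(msg) cx_stop(msg, "cx_validation_error")
cx_config_error <- function(msg) cx_stop(msg, "cx_config_error")
cx_backend_error <- function(msg, extractor_id) {
  cx_stop(msg, "cx_backend_error", extractor_id = extractor_id)
}
cx_parse_error <- function(msg, extractor_id) {
  cx_stop(msg, c("cx_parse_error", "cx_backend_error"), extractor_id = extractor_id)
}

escape_regex <- function(x) gsub("([.\\\\|()\\[\\]{}^$*+?])", "\\\\\\1", x, perl = TRUE)

#' Normalize a surface form for lexicon lookup and comparison
#'
#' Lowercases, strips punctuation, and collapses runs of whitespace. This is
#' the canonical key under which surface strings are compared throughout the
#' package (lexicon lookup, deduplication, gold matching).
#'
#' @param x character vector of surface forms.
#' @return character vector of normalized keys.
#' @export
#' @examples
#' normalize_surface("  Orthostatic   Hypotension! ")
normalize_surface <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9 ]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# naive singular: strip one trailing "s" from the last word
strip_plural <- function(key) {
  sub("s$", "", key)
}

read_jsonl <- function(path) {
  if (!file.exists(path)) cx_input_error(sprintf("file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, jsonlite::fromJSON, simplifyVector = FALSE)
}

write_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    # 17 significant digits: doubles round-trip bit-exactly
    as.character(jsonlite::toJSON(r, auto_unbox = TRUE, digits = I(17), null = "null"))
  }, character(1))
  con <- tryCatch(file(path, open = "wb"), error = function(e) {
    cx_stop(sprintf("cannot open for writing: %s", path), "cx_io_error")
  })
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

# scalar coercion helpers for JSON records
chr1 <- function(x) if (is.null(x)) NA_character_ else as.character(x)[1]
num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)[1]
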