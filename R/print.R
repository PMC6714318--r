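#' @export
print.cx_document <- function(x, ...) {
  cat(sprintf("<document '%s'> %d chars\n", x$doc_id, nchar(x$text)))
  invisible(x)
}

#' @export
print.cx_config <- function(x, ...) {
  cat(sprintf("integration config: kappa=%s gamma=%.3g theta=%.3g\n",
              x$kappa, x$gamma, x$theta))
  if (length(x$omega) > 0) {
    cat("omega:", paste(sprintf("%s=%.3f", names(x$omega), x$omega),
                        collapse = " "), "\n")
  }
  invisible(x)
}

#' @export
print.cx_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("precision %.*f  recall %.*f  F1 %.*f\n",
              digits, x$precision, digits, x$recall, digits, x$f1))
  invisible(x)
}

#' @export
print.cx_counts <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' @export
print.cx_entity <- function(x, ...) {
  pc <- primary_code(x$representative)
  code <- if (is.null(pc)) "(no code)" else paste(pc$code_system, pc$code, sep = ":")
  cat(sprintf("<entity '%s' %s> extractors {%s} weight %s\n",
              x$representative$term$surface, code,
              paste(x$extractor_ids, collapse = ","),
              if (is.na(x$cumulative_weight)) "?" else
                sprintf("%.3f", x$cumulative_weight)))
  invisible(x)
}

#' @export
print.cx_result <- function(x, ...) {
  cat(sprintf("<extraction result '%s'>: %d accepted, %d rejected\n",
              x$doc_id, length(x$accepted), length(x$rejected)))
  for (e in x$accepted) print(e)
  invisible(x)
}

#' @export
print.cx_report <- function(x, ...) {
  cat(sprintf("evaluation over %d documents\n", nrow(x$per_document)))
  cat("counts: "); print(x$counts)
  cat("micro:  "); print(x$micro)
  cat("macro:  "); print(x$macro)
  if (!is.null(x$error_shares)) {
    cat(sprintf("errors: %.1f%% FP, %.1f%% FN\n",
                100 * x$error_shares$fp_share, 100 * x$error_shares$fn_share))
  }
  invisible(x)
}

#' @export
print.cx_grid <- function(x, ...) {
  cat(sprintf("tuning grid: %d cells\n", nrow(x$grid)))
  print(x$grid, row.names = FALSE)
  cat("best cell:\n")
  print(x$best, row.names = FALSE)
  invisible(x)
}
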