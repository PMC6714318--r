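#' Configure an extraction pipeline
#'
#' Wires the pipeline stages together: a corpus, an optional gold standard,
#' a concept lexicon, an extractor roster, the integration configuration,
#' and an optional output directory. Corpus, gold and lexicon may be given
#' either as in-memory objects or as file paths (JSONL / JSON). A
#' `deidentify` hook — a function applied to each document text before
#' extraction — is a pass-through slot for de-identification plugins and
#' defaults to the identity.
#'
#' @param corpus list of [document()]s, or a path to a JSONL corpus.
#' @param lexicon a [concept_lexicon()] or a path to a lexicon JSON.
#' @param extractors non-empty list of [extractor_spec()]s.
#' @param gold optional list of [gold_annotation()]s or path.
#' @param config an [integration_config()]; if its omega is empty, uniform
#'   weights 1/n over the roster are used.
#' @param neg_lexicon a [negation_lexicon()].
#' @param gold_style see [count_outcomes()].
#' @param output_dir optional directory for persisted results/reports.
#' @param deidentify function(text) -> text hook.
#' @return an object of class `cx_pipeline_config`.
#' @export
pipeline_config <- function(corpus, lexicon, extractors, gold = NULL,
                            config = integration_config(),
                            neg_lexicon = default_negation_lexicon(),
                            gold_style = c("exhaustive", "labels"),
                            output_dir = NULL, deidentify = identity) {
  gold_style <- match.arg(gold_style)
  if (is.character(corpus)) corpus <- read_corpus(corpus, "jsonl")
  if (is.character(lexicon)) lexicon <- read_concept_lexicon(lexicon)
  if (is.character(gold)) gold <- read_gold(gold)
  if (length(extractors) == 0) cx_config_error("extractor roster must be non-empty")
  ids <- vapply(extractors, `[[`, character(1), "extractor_id")
  if (anyDuplicated(ids)) {
    cx_config_error("extractor ids must be unique within the roster")
  }
  names(extractors) <- ids
  if (length(config$omega) == 0) {
    config$omega <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  }
  structure(list(corpus = corpus, lexicon = lexicon, extractors = extractors,
                 gold = gold, config = config, neg_lexicon = neg_lexicon,
                 gold_style = gold_style, output_dir = output_dir,
                 deidentify = deidentify),
            class = "cx_pipeline_config")
}

#' Flag and normalize raw per-extractor terms
#'
#' The shared preprocessing between extraction and tuning: per document,
#' negation spans are detected once on the text, every extractor's raw
#' terms are negation-flagged against them, and each term is encoded
#' against the lexicon. No filtering or deduplication happens here, so the
#' result can be re-integrated under any (kappa, gamma, theta) cell.
#'
#' @param documents list of [document()]s.
#' @param per_extractor_outputs named list: extractor id -> named list
#'   (doc id -> list of [extracted_term()]s), e.g. from
#'   [simulate_extractor_outputs()].
#' @param lexicon a [concept_lexicon()].
#' @param neg_lexicon a [negation_lexicon()].
#' @return named list: doc id -> (extractor id -> list of flagged
#'   [normalized_term()]s).
#' @export
prepare_extractor_terms <- function(documents, per_extractor_outputs, lexicon,
                                    neg_lexicon = default_negation_lexicon()) {
  out <- list()
  for (doc in documents) {
    spans <- detect_negation_spans(doc$text, neg_lexicon)
    per_ext <- lapply(per_extractor_outputs, function(by_doc) {
      terms <- by_doc[[doc$doc_id]] %||% list()
      flagged <- flag_negated(terms, spans, doc$text)
      lapply(flagged, encode_term, lexicon = lexicon)
    })
    out[[doc$doc_id]] <- per_ext
  }
  out
}

run_roster <- function(doc, extractors) {
  outputs <- list()
  failed <- character(0)
  for (spec in extractors) {
    res <- tryCatch(extract_terms(doc, spec),
                    cx_backend_error = function(e) e)
    if (inherits(res, "cx_backend_error")) {
      warning(sprintf("extractor '%s' failed on document '%s': %s",
                      spec$extractor_id, doc$doc_id, conditionMessage(res)),
              call. = FALSE)
      failed <- c(failed, spec$extractor_id)
    } else {
      outputs[[spec$extractor_id]] <- res
    }
  }
  list(outputs = outputs, failed = failed)
}

#' Run the extraction pipeline
#'
#' Executes the fixed stage order on every document: per-extractor
#' extraction, negation detection and flagging, negation filtering
#' (per kappa), concept normalization, per-extractor deduplication, and
#' ensemble integration. A failing backend is logged with a warning and
#' skipped; the run fails only if every extractor fails. The returned list
#' carries the raw per-extractor view in its `"per_extractor"` attribute
#' (the remote view, before integration) and per-stage term counts in
#' `"stage_counts"`. With an `output_dir` configured, results are persisted
#' as JSONL.
#'
#' @param pipeline a [pipeline_config()].
#' @return list of `cx_result` (one per document, in corpus order).
#' @export
run_extract <- function(pipeline) {
  cfg <- pipeline$config
  results <- list()
  raw_view <- list()
  log_rows <- list()
  any_ok <- FALSE
  for (doc in pipeline$corpus) {
    doc <- document(doc$doc_id, pipeline$deidentify(doc$text), doc$metadata)
    roster <- run_roster(doc, pipeline$extractors)
    if (length(roster$outputs) > 0) any_ok <- TRUE
    raw_view[[doc$doc_id]] <- roster$outputs
    spans <- detect_negation_spans(doc$text, pipeline$neg_lexicon)
    n_raw <- 0L; n_neg <- 0L; n_kept <- 0L; n_norm <- 0L
    per_ext <- lapply(roster$outputs, function(terms) {
      flagged <- flag_negated(terms, spans, doc$text)
      n_raw <<- n_raw + length(flagged)
      n_neg <<- n_neg + sum(vapply(flagged, `[[`, logical(1), "negated"))
      kept <- apply_negation_filter(flagged, cfg$kappa)
      n_kept <<- n_kept + length(kept)
      normalized <- lapply(kept, encode_term, lexicon = pipeline$lexicon)
      n_norm <<- n_norm + sum(vapply(normalized, function(nt)
        length(nt$matches) > 0, logical(1)))
      deduplicate_entities(normalized)
    })
    res <- integrate_terms(per_ext, cfg, doc_id = doc$doc_id)
    results[[length(results) + 1L]] <- res
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      doc_id = doc$doc_id, extracted = n_raw, negated = n_neg,
      after_filter = n_kept, encoded = n_norm,
      merged = length(res$accepted) + length(res$rejected),
      accepted = length(res$accepted))
  }
  if (!any_ok && length(pipeline$corpus) > 0 && length(pipeline$extractors) > 0) {
    cx_stop("all extractors failed; no results produced",
            c("cx_all_backends_failed", "cx_backend_error"))
  }
  attr(results, "per_extractor") <- raw_view
  attr(results, "stage_counts") <- do.call(rbind, log_rows)
  if (!is.null(pipeline$output_dir)) {
    if (!dir.exists(pipeline$output_dir)) dir.create(pipeline$output_dir, recursive = TRUE)
    write_results(results, file.path(pipeline$output_dir, "results.jsonl"))
  }
  results
}

#' Evaluate extraction results against the gold standard
#'
#' Computes per-document TP/FP/FN counts, micro- and macro-averaged
#' precision/recall/F1, and the FP/FN error decomposition. With an
#' `output_dir` configured the report is written as `report.json`.
#'
#' @param pipeline a [pipeline_config()] with gold annotations.
#' @param results optional pre-computed results (e.g. from [run_extract()]
#'   or [read_results()]); computed fresh when absent.
#' @return an object of class `cx_report`: a list with `per_document`
#'   (data.frame), `counts`, `micro`, `macro`, `error_shares`.
#' @export
run_evaluate <- function(pipeline, results = NULL) {
  if (is.null(pipeline[["gold"]])) {
    cx_config_error("evaluation requires gold annotations in the pipeline config")
  }
  if (is.null(results)) results <- run_extract(pipeline)
  gold_ids <- vapply(pipeline[["gold"]], `[[`, character(1), "doc_id")
  per_doc <- lapply(results, function(res) {
    count_outcomes(res$accepted, pipeline[["gold"]][gold_ids == res$doc_id],
                   gold_style = pipeline$gold_style, doc_id = res$doc_id)
  })
  totals <- aggregate_counts(per_doc)
  macro_cells <- lapply(per_doc, compute_metrics)
  macro <- structure(list(
    precision = mean(vapply(macro_cells, `[[`, numeric(1), "precision")),
    recall = mean(vapply(macro_cells, `[[`, numeric(1), "recall")),
    f1 = mean(vapply(macro_cells, `[[`, numeric(1), "f1"))),
    class = "cx_metrics")
  report <- structure(list(
    per_document = data.frame(
      doc_id = vapply(results, `[[`, character(1), "doc_id"),
      tp = vapply(per_doc, `[[`, integer(1), "tp"),
      fp = vapply(per_doc, `[[`, integer(1), "fp"),
      fn = vapply(per_doc, `[[`, integer(1), "fn")),
    counts = totals,
    micro = compute_metrics(totals),
    macro = macro,
    error_shares = error_decomposition(totals)),
    class = "cx_report")
  if (!is.null(pipeline$output_dir)) {
    if (!dir.exists(pipeline$output_dir)) dir.create(pipeline$output_dir, recursive = TRUE)
    obj <- list(per_document = report$per_document,
                counts = unclass(report$counts),
                micro = unclass(report$micro), macro = unclass(report$macro),
                error_shares = report$error_shares)
    writeLines(as.character(jsonlite::toJSON(obj, auto_unbox = TRUE,
                                             digits = NA, dataframe = "rows")),
               file.path(pipeline$output_dir, "report.json"), useBytes = TRUE)
  }
  report
}

#' Tune the integration hyperparameters on a pipeline
#'
#' Runs the roster once, keeps the flagged/normalized per-extractor view,
#' and defers to [grid_tune()] over the requested (kappa, gamma, theta)
#' grid. With an `output_dir` configured the grid is persisted as CSV.
#'
#' @param pipeline a [pipeline_config()] with gold annotations.
#' @param kappa_values,gamma_values,theta_values grid axes.
#' @return a `cx_grid` (see [grid_tune()]).
#' @export
run_tune <- function(pipeline, kappa_values = c(FALSE, TRUE),
                     gamma_values = 0.1, theta_values = 0.35) {
  if (is.null(pipeline[["gold"]])) {
    cx_config_error("tuning requires gold annotations in the pipeline config")
  }
  per_extractor_outputs <- list()
  for (doc in pipeline$corpus) {
    roster <- run_roster(doc, pipeline$extractors)
    for (ex_id in names(roster$outputs)) {
      per_extractor_outputs[[ex_id]][[doc$doc_id]] <- roster$outputs[[ex_id]]
    }
  }
  per_doc_terms <- prepare_extractor_terms(pipeline$corpus,
                                           per_extractor_outputs,
                                           pipeline$lexicon,
                                           pipeline$neg_lexicon)
  tuned <- grid_tune(per_doc_terms, pipeline[["gold"]], pipeline$config$omega,
                     kappa_values = kappa_values, gamma_values = gamma_values,
                     theta_values = theta_values,
                     gold_style = pipeline$gold_style)
  if (!is.null(pipeline$output_dir)) {
    if (!dir.exists(pipeline$output_dir)) dir.create(pipeline$output_dir, recursive = TRUE)
    utils::write.csv(tuned$grid, file.path(pipeline$output_dir, "tuning_grid.csv"),
                     row.names = FALSE)
  }
  tuned
}
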