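#' Outcome counts for entity-level evaluation
#'
#' @param tp,fp,fn non-negative integer counts of true positives, false
#'   positives, and false negatives.
#' @return an object of class `cx_counts`.
#' @export
outcome_counts <- function(tp = 0L, fp = 0L, fn = 0L) {
  if (any(c(tp, fp, fn) < 0)) cx_validation_error("counts must be non-negative")
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn)),
            class = "cx_counts")
}

gold_code_keys <- function(g) {
  if (is.null(g$codes)) return(character(0))
  vapply(g$codes, function(cd) paste(cd$code_system, cd$code, sep = ":"),
         character(1))
}

#' Count TP/FP/FN for one document
#'
#' Matches predicted (accepted) entities against gold annotations with a
#' greedy one-to-one rule: code matches first (the entity's top-ranked code
#' appears among a gold annotation's codes), then surface matches
#' (normalized surface equality, with a naive plural fallback). Each gold
#' annotation matches at most one entity and vice versa.
#'
#' A matched gold annotation with polarity present counts as a true
#' positive; a matched absent annotation counts as a false positive (the
#' entity was extracted but annotated as not in the document); an unmatched
#' present annotation is a false negative. What happens to entities matching
#' no annotation depends on the gold style: with exhaustive gold (every true
#' entity is annotated, as in medication-name or span-style gold) they are
#' false positives; with label-style gold (a fixed label set with
#' present/absent polarity, as in document-level condition labels) they are
#' ignored, since the label set does not cover them.
#'
#' @param predicted list of accepted merged entities for one document.
#' @param gold list of [gold_annotation()]s for the same document.
#' @param gold_style `"exhaustive"` or `"labels"`.
#' @param doc_id optional id; if given, every gold annotation must carry it.
#' @return an [outcome_counts()].
#' @export
count_outcomes <- function(predicted, gold,
                           gold_style = c("exhaustive", "labels"),
                           doc_id = NULL) {
  gold_style <- match.arg(gold_style)
  if (!is.null(doc_id) && length(gold) > 0) {
    ids <- vapply(gold, `[[`, character(1), "doc_id")
    if (any(ids != doc_id)) {
      cx_validation_error(sprintf(
        "gold annotations for document '%s' carry other doc_ids", doc_id))
    }
  }
  np <- length(predicted)
  ng <- length(gold)
  p_matched <- rep(FALSE, np)
  g_matched <- rep(FALSE, ng)

  p_code <- vapply(predicted, function(e) {
    pc <- primary_code(e$representative)
    if (is.null(pc)) NA_character_ else paste(pc$code_system, pc$code, sep = ":")
  }, character(1))
  p_surf <- vapply(predicted, function(e)
    normalize_surface(e$representative$term$surface), character(1))
  g_codes <- lapply(gold, gold_code_keys)
  g_surf <- vapply(gold, function(g) {
    if (is.null(g$surface)) NA_character_ else normalize_surface(g$surface)
  }, character(1))
  g_polarity <- vapply(gold, `[[`, character(1), "polarity")

  pair_polarity <- character(0)
  claim <- function(i, j) {
    p_matched[i] <<- TRUE
    g_matched[j] <<- TRUE
    pair_polarity <<- c(pair_polarity, g_polarity[j])
  }
  # pass 1: code matches
  for (i in seq_len(np)) {
    if (is.na(p_code[i])) next
    for (j in seq_len(ng)) {
      if (!g_matched[j] && p_code[i] %in% g_codes[[j]]) {
        claim(i, j)
        break
      }
    }
  }
  # pass 2: surface matches (normalized; naive plural fallback)
  surf_eq <- function(a, b) {
    if (is.na(a) || is.na(b)) return(FALSE)
    a == b || strip_plural(a) == strip_plural(b)
  }
  for (i in seq_len(np)) {
    if (p_matched[i]) next
    for (j in seq_len(ng)) {
      if (!g_matched[j] && surf_eq(p_surf[i], g_surf[j])) {
        claim(i, j)
        break
      }
    }
  }
  tp <- sum(pair_polarity == "present")
  fp <- sum(pair_polarity == "absent")
  if (gold_style == "exhaustive") fp <- fp + sum(!p_matched)
  fn <- sum(!g_matched & g_polarity == "present")
  outcome_counts(tp, fp, fn)
}

#' Precision, recall and F1 from outcome counts
#'
#' precision = TP / (TP + FP), recall = TP / (TP + FN), and F1 is their
#' harmonic mean 2 * precision * recall / (precision + recall). Any 0/0 is
#' defined as 0, so empty documents and empty predictions are well-defined.
#'
#' @param counts an [outcome_counts()], or anything with `tp`, `fp`, `fn`.
#' @return an object of class `cx_metrics` with `precision`, `recall`, `f1`.
#' @export
compute_metrics <- function(counts) {
  safe_div <- function(num, den) if (den == 0) 0 else num / den
  precision <- safe_div(counts$tp, counts$tp + counts$fp)
  recall <- safe_div(counts$tp, counts$tp + counts$fn)
  f1 <- safe_div(2 * precision * recall, precision + recall)
  structure(list(precision = precision, recall = recall, f1 = f1),
            class = "cx_metrics")
}

#' Micro-aggregate per-document outcome counts
#'
#' Element-wise sums of tp, fp, fn across documents; computing metrics on
#' the sum is micro-averaging, the package default.
#'
#' @param counts_list list of [outcome_counts()].
#' @return an [outcome_counts()].
#' @export
aggregate_counts <- function(counts_list) {
  outcome_counts(sum(vapply(counts_list, `[[`, integer(1), "tp")),
                 sum(vapply(counts_list, `[[`, integer(1), "fp")),
                 sum(vapply(counts_list, `[[`, integer(1), "fn")))
}

#' Estimate extractor reliability weights from held-out F1 scores
#'
#' Each extractor's F1 score, measured by running it alone on a (small)
#' annotated subset, is sum-normalized into a weight:
#' `omega_i = f1_i / sum(f1)`. The weights sum to 1 and preserve the F1
#' ordering of the extractors.
#'
#' @param per_extractor_f1 named numeric vector of F1 scores, at least one
#'   of them positive.
#' @return named numeric vector omega summing to 1.
#' @export
estimate_extractor_weights <- function(per_extractor_f1) {
  f1 <- unlist(per_extractor_f1)
  if (length(f1) == 0 || is.null(names(f1)) || any(!nzchar(names(f1)))) {
    cx_validation_error("per_extractor_f1 must be a named vector")
  }
  if (any(f1 < 0)) cx_validation_error("F1 scores must be non-negative")
  total <- sum(f1)
  if (total == 0) {
    cx_validation_error("all F1 scores are zero; weights are undefined")
  }
  f1 / total
}

#' Decompose errors into false-positive and false-negative shares
#'
#' @param counts an [outcome_counts()].
#' @return list with `fp_share` and `fn_share` summing to 1, or `NULL` when
#'   there are no errors (fp + fn = 0, the decomposition is undefined).
#' @export
error_decomposition <- function(counts) {
  total <- counts$fp + counts$fn
  if (total == 0) return(NULL)
  list(fp_share = counts$fp / total, fn_share = counts$fn / total)
}

#' Grid search over the integration hyperparameters
#'
#' Runs integration and evaluation for every combination of the supplied
#' kappa, gamma and theta values on pre-computed per-extractor terms
#' (normalized and negation-flagged but not yet filtered), and reports
#' micro-averaged metrics per cell plus the best cell by F1. Ties are broken
#' toward smaller theta, then smaller gamma, then kappa = FALSE.
#'
#' @param per_doc_terms named list: doc id -> named list (extractor id ->
#'   list of flagged [normalized_term()]s), as produced by
#'   [prepare_extractor_terms()].
#' @param gold list of [gold_annotation()]s for the corpus.
#' @param omega named extractor weights.
#' @param kappa_values,gamma_values,theta_values grid axes.
#' @param gold_style see [count_outcomes()].
#' @return an object of class `cx_grid`: a list with `grid` (data.frame of
#'   cells and metrics) and `best` (one-row data.frame).
#' @export
grid_tune <- function(per_doc_terms, gold, omega,
                      kappa_values = c(FALSE, TRUE),
                      gamma_values = 0.1, theta_values = 0.35,
                      gold_style = c("exhaustive", "labels")) {
  gold_style <- match.arg(gold_style)
  if (length(kappa_values) == 0 || length(gamma_values) == 0 ||
      length(theta_values) == 0) {
    cx_config_error("tuning grid must be non-empty on every axis")
  }
  cells <- expand.grid(kappa = kappa_values, gamma = gamma_values,
                       theta = theta_values, KEEP.OUT.ATTRS = FALSE)
  gold_ids <- vapply(gold, `[[`, character(1), "doc_id")
  rows <- lapply(seq_len(nrow(cells)), function(ci) {
    cfg <- integration_config(kappa = cells$kappa[ci], gamma = cells$gamma[ci],
                              theta = cells$theta[ci], omega = omega)
    counts <- lapply(names(per_doc_terms), function(did) {
      per_ext <- lapply(per_doc_terms[[did]], function(terms) {
        deduplicate_entities(apply_negation_filter(terms, cfg$kappa))
      })
      res <- integrate_terms(per_ext, cfg, doc_id = did)
      count_outcomes(res$accepted, gold[gold_ids == did],
                     gold_style = gold_style, doc_id = did)
    })
    m <- compute_metrics(aggregate_counts(counts))
    data.frame(kappa = cfg$kappa, gamma = cfg$gamma, theta = cfg$theta,
               precision = m$precision, recall = m$recall, f1 = m$f1)
  })
  grid <- do.call(rbind, rows)
  ord <- order(-grid$f1, grid$theta, grid$gamma, grid$kappa, method = "radix")
  structure(list(grid = grid, best = grid[ord[1], , drop = FALSE]),
            class = "cx_grid")
}
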