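#' Integration hyperparameters
#'
#' The three hyperparameters steering ensemble integration, plus the
#' per-extractor reliability weights:
#' \describe{
#'   \item{kappa}{logical; negation filter on/off.}
#'   \item{gamma}{term-similarity threshold in \[0, 1\]; a pair of terms is
#'     merged when its similarity weight is strictly greater than gamma.
#'     Higher gamma means fewer merges and more distinct entities.}
#'   \item{theta}{extractor threshold in \[0, 1\]; an entity is accepted when
#'     the cumulative weight of its contributing extractors is strictly
#'     greater than theta. Higher theta demands support from more (or more
#'     reliable) extractors.}
#'   \item{omega}{named numeric vector mapping extractor id to a weight in
#'     \[0, 1\]; weights produced by [estimate_extractor_weights()] sum to 1.}
#' }
#' The defaults gamma = 0.1, theta = 0.35, kappa = FALSE are the recommended
#' starting point for tuning.
#'
#' @param kappa logical.
#' @param gamma,theta numeric in \[0, 1\].
#' @param omega named numeric vector of extractor weights.
#' @return an object of class `cx_config`.
#' @export
integration_config <- function(kappa = FALSE, gamma = 0.1, theta = 0.35,
                               omega = numeric()) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    cx_config_error("gamma must lie in [0, 1]")
  }
  if (!is.numeric(theta) || theta < 0 || theta > 1) {
    cx_config_error("theta must lie in [0, 1]")
  }
  if (length(omega) > 0) {
    if (is.null(names(omega)) || any(!nzchar(names(omega)))) {
      cx_config_error("omega must be a named vector of extractor weights")
    }
    if (any(omega < 0 | omega > 1)) {
      cx_config_error("omega weights must lie in [0, 1]")
    }
  }
  structure(list(kappa = isTRUE(kappa), gamma = as.numeric(gamma),
                 theta = as.numeric(theta), omega = omega),
            class = "cx_config")
}

#' Similarity weight between two normalized terms
#'
#' Two terms are compared through their ranked code-match lists: `alpha` is
#' the fraction of shared codes over the full top-10 lists (denominator
#' fixed at 10), `beta` the fraction shared among the top-3 matches of both
#' (denominator fixed at 3), and the combined weight is
#' `alpha / 4 + 3 * beta / 4`, emphasizing agreement among the most similar
#' candidates. The weight lies in \[0, 1\], is symmetric, and is 0 whenever
#' either match list is empty.
#'
#' @param a,b [normalized_term()]s.
#' @return an object of class `cx_pairsim` with fields `alpha`, `beta`,
#'   `weight`.
#' @export
pair_similarity <- function(a, b) {
  keys_a <- vapply(a$matches, match_key, character(1))
  keys_b <- vapply(b$matches, match_key, character(1))
  if (length(keys_a) == 0 || length(keys_b) == 0) {
    alpha <- 0; beta <- 0
  } else {
    alpha <- length(intersect(keys_a, keys_b)) / 10
    beta <- length(intersect(utils::head(keys_a, 3), utils::head(keys_b, 3))) / 3
  }
  structure(list(alpha = alpha, beta = beta,
                 weight = alpha / 4 + 3 * beta / 4),
            class = "cx_pairsim")
}

#' Decide whether a pair of terms is "equal"
#'
#' A pair is considered the same entity when its similarity weight is
#' strictly greater than the threshold gamma; a weight exactly at the
#' threshold does not merge.
#'
#' @param sim a [pair_similarity()] result.
#' @param gamma threshold in \[0, 1\].
#' @return logical.
#' @export
are_equal_terms <- function(sim, gamma) {
  if (!is.numeric(gamma) || gamma < 0 || gamma > 1) {
    cx_config_error("gamma must lie in [0, 1]")
  }
  sim$weight > gamma
}

new_merged_entity <- function(members) {
  stopifnot(length(members) > 0)
  # deterministic member order: extractor id, span start, surface
  ord <- order(vapply(members, function(m) m$term$extractor_id, character(1)),
               vapply(members, function(m) {
                 if (is.na(m$term$start)) .Machine$integer.max else m$term$start
               }, integer(1)),
               vapply(members, function(m) m$term$surface, character(1)),
               method = "radix")
  members <- members[ord]
  # representative: most matches, then earliest span, then surface
  n_matches <- vapply(members, function(m) length(m$matches), integer(1))
  starts <- vapply(members, function(m) {
    if (is.na(m$term$start)) .Machine$integer.max else m$term$start
  }, integer(1))
  surfaces <- vapply(members, function(m) m$term$surface, character(1))
  rep_idx <- order(-n_matches, starts, surfaces, method = "radix")[1]
  structure(list(members = members,
                 representative = members[[rep_idx]],
                 extractor_ids = sort(unique(vapply(members, function(m)
                   m$term$extractor_id, character(1)))),
                 cumulative_weight = NA_real_),
            class = "cx_entity")
}

#' Merge equivalent terms across extractors
#'
#' Builds the graph whose nodes are the pooled normalized terms of one
#' document and whose edges are pairs with similarity weight strictly above
#' gamma, and returns its connected components as merged entities
#' (transitive closure: if A matches B and B matches C, all three merge even
#' when A and C do not match directly). The partition — and the returned
#' order, sorted by representative surface — is invariant to the input
#' order.
#'
#' @param nterms pooled [normalized_term()]s from one document, already
#'   deduplicated per extractor.
#' @param gamma similarity threshold.
#' @return list of merged entities (class `cx_entity`).
#' @export
merge_terms <- function(nterms, gamma) {
  n <- length(nterms)
  if (n == 0) return(list())
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        if (are_equal_terms(pair_similarity(nterms[[i]], nterms[[j]]), gamma)) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  entities <- lapply(unique(roots), function(r) new_merged_entity(nterms[roots == r]))
  # order-invariant entity ordering
  rep_surface <- vapply(entities, function(e)
    normalize_surface(e$representative$term$surface), character(1))
  rep_key <- vapply(entities, function(e) entity_key(e$representative), character(1))
  entities[order(rep_surface, rep_key, method = "radix")]
}

#' Cumulative extractor weight of a merged entity
#'
#' Sums the reliability weights omega over the distinct extractors that
#' contributed to the entity; an extractor counts once no matter how many
#' member mentions it produced. With weights normalized to sum to 1, the
#' cumulative weight lies in \[0, 1\] and equals 1 only for an entity found
#' by every extractor.
#'
#' @param entity a merged entity from [merge_terms()].
#' @param omega named numeric vector of extractor weights.
#' @return numeric weight.
#' @export
cumulative_weight <- function(entity, omega) {
  ids <- entity$extractor_ids
  missing <- setdiff(ids, names(omega))
  if (length(missing) > 0) {
    cx_config_error(sprintf("no omega weight for extractor(s): %s",
                            paste(missing, collapse = ", ")))
  }
  sum(omega[ids])
}

#' Integrate per-extractor terms into accepted entities
#'
#' The ensemble integration step: pools the (negation-filtered, normalized,
#' per-extractor deduplicated) terms of all extractors for one document,
#' merges equivalent terms with [merge_terms()] at threshold gamma, computes
#' each entity's cumulative extractor weight, and accepts an entity exactly
#' when that weight is strictly greater than theta. Entities below or at the
#' threshold are kept in the rejected list (they are treated as false
#' extractions). Both lists are sorted by descending cumulative weight, then
#' surface; the result is invariant to the order of extractors and of terms
#' within an extractor.
#'
#' @param per_extractor_terms named list: extractor id -> list of
#'   [normalized_term()]s for one document.
#' @param config an [integration_config()]; `config$omega` must cover every
#'   contributing extractor.
#' @param doc_id document identifier recorded in the result.
#' @return an object of class `cx_result` with `accepted`, `rejected`,
#'   `config`, `doc_id`.
#' @export
integrate_terms <- function(per_extractor_terms, config, doc_id = NA_character_) {
  pool <- do.call(c, unname(per_extractor_terms)) %||% list()
  entities <- merge_terms(pool, config$gamma)
  entities <- lapply(entities, function(e) {
    e$cumulative_weight <- cumulative_weight(e, config$omega)
    e
  })
  accepted <- Filter(function(e) e$cumulative_weight > config$theta, entities)
  rejected <- Filter(function(e) e$cumulative_weight <= config$theta, entities)
  sort_entities <- function(es) {
    if (length(es) == 0) return(list())
    w <- vapply(es, `[[`, numeric(1), "cumulative_weight")
    s <- vapply(es, function(e) normalize_surface(e$representative$term$surface),
                character(1))
    es[order(-w, s, method = "radix")]
  }
  structure(list(doc_id = doc_id,
                 accepted = sort_entities(accepted),
                 rejected = sort_entities(rejected),
                 config = config),
            class = "cx_result")
}
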