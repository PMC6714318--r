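# accepted-entity stand-ins for evaluation tests
mk_entity <- function(surface, codes = character(0), extractor_id = "e1") {
  merge_terms(list(mk_nterm(codes, surface = surface,
                            extractor_id = extractor_id)), gamma = 1)[[1]]
}

test_that("count_outcomes applies the TP/FP/FN definitions", {
  gold <- list(mk_gold(surface = "asthma"), mk_gold(surface = "depression"))
  pred <- list(mk_entity("asthma"))
  counts <- count_outcomes(pred, gold, doc_id = "d1")
  expect_equal(unclass(counts), list(tp = 1L, fp = 0L, fn = 1L))

  # nothing predicted
  expect_equal(unclass(count_outcomes(list(), list(mk_gold(surface = "x")))),
               list(tp = 0L, fp = 0L, fn = 1L))

  # an extraction matching an absent label is a false positive
  counts <- count_outcomes(list(mk_entity("obesity")),
                           list(mk_gold(surface = "obesity", polarity = "absent")),
                           gold_style = "labels")
  expect_equal(unclass(counts), list(tp = 0L, fp = 1L, fn = 0L))

  # label-style gold ignores unmatched predictions; exhaustive counts them FP
  pred2 <- list(mk_entity("asthma"), mk_entity("nausea"))
  gold2 <- list(mk_gold(surface = "asthma"))
  expect_equal(count_outcomes(pred2, gold2, gold_style = "labels")$fp, 0L)
  expect_equal(count_outcomes(pred2, gold2, gold_style = "exhaustive")$fp, 1L)
})

test_that("matching is greedy one-to-one with code priority", {
  # one prediction cannot satisfy two gold items
  gold <- list(mk_gold(surface = "asthma"), mk_gold(surface = "asthma"))
  counts <- count_outcomes(list(mk_entity("asthma")), gold)
  expect_equal(unclass(counts), list(tp = 1L, fp = 0L, fn = 1L))
  # code match beats surface: prediction coded C1 with surface "wheeze"
  # matches the coded gold, not the surface-only one
  gold <- list(mk_gold(surface = "wheeze", polarity = "absent"),
               mk_gold(codes = "C1", surface = "asthma"))
  counts <- count_outcomes(list(mk_entity("wheeze", codes = "C1")), gold,
                           gold_style = "labels")
  expect_equal(unclass(counts), list(tp = 1L, fp = 0L, fn = 0L))
  # plural surfaces still match their singular gold
  counts <- count_outcomes(list(mk_entity("hematomas")),
                           list(mk_gold(surface = "hematoma")))
  expect_equal(counts$tp, 1L)
  # doc_id mismatch is a validation error
  expect_error(count_outcomes(list(), list(mk_gold(doc_id = "other")),
                              doc_id = "d1"),
               class = "cx_validation_error")
})

test_that("compute_metrics reproduces the printed recall/precision -> F1 rows", {
  rows <- list(  # recall, precision, published F1
    list(0.733, 0.939, 0.823), list(0.805, 0.925, 0.861),
    list(0.620, 0.835, 0.712), list(0.636, 0.838, 0.724),
    list(0.594, 0.271, 0.373), list(0.795, 0.816, 0.805))
  for (r in rows) {
    # counts scaled to reproduce the stated rates exactly at tp = 1
    tp <- 1
    fp <- tp / r[[2]] - tp
    fn <- tp / r[[1]] - tp
    m <- compute_metrics(list(tp = tp, fp = fp, fn = fn))
    expect_equal(m$precision, r[[2]], tolerance = 1e-12)
    expect_equal(m$recall, r[[1]], tolerance = 1e-12)
    expect_lt(abs(m$f1 - r[[3]]), 1e-3)
  }
})

test_that("metrics handle degenerate counts with the 0/0 -> 0 convention", {
  z <- compute_metrics(outcome_counts(0L, 0L, 0L))
  expect_equal(unclass(z), list(precision = 0, recall = 0, f1 = 0))
  m <- compute_metrics(outcome_counts(3L, 1L, 0L))
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 0.75)
  # equal precision and recall collapse the harmonic mean
  p <- compute_metrics(outcome_counts(3L, 1L, 1L))
  expect_equal(p$precision, p$recall)
  expect_equal(p$f1, p$precision)
  # bounds and harmonic-mean inequality on random counts
  set.seed(9)
  for (i in 1:50) {
    cts <- outcome_counts(sample(0:20, 1), sample(0:20, 1), sample(0:20, 1))
    m <- compute_metrics(cts)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
    expect_lte(m$f1, max(m$precision, m$recall) + 1e-12)
  }
})

test_that("micro aggregation sums counts element-wise", {
  a <- outcome_counts(1L, 0L, 1L)
  b <- outcome_counts(2L, 1L, 0L)
  expect_equal(unclass(aggregate_counts(list(a, b))),
               list(tp = 3L, fp = 1L, fn = 1L))
  expect_equal(aggregate_counts(list(a)), a)
  expect_equal(unclass(aggregate_counts(list())), list(tp = 0L, fp = 0L, fn = 0L))
})

test_that("extractor weights are sum-normalized F1 scores", {
  omega <- estimate_extractor_weights(c(A = 0.8, B = 0.6, C = 0.6))
  expect_equal(omega, c(A = 0.4, B = 0.3, C = 0.3))
  expect_equal(sum(omega), 1)
  expect_equal(estimate_extractor_weights(c(only = 0.5)), c(only = 1))
  expect_error(estimate_extractor_weights(c(A = 0, B = 0)),
               class = "cx_validation_error")
})

test_that("error decomposition reports FP/FN shares", {
  expect_equal(error_decomposition(outcome_counts(fp = 3L, fn = 1L)),
               list(fp_share = 0.75, fn_share = 0.25))
  expect_equal(error_decomposition(outcome_counts(fp = 0L, fn = 5L)),
               list(fp_share = 0, fn_share = 1))
  expect_equal(error_decomposition(outcome_counts(fp = 4L, fn = 4L)),
               list(fp_share = 0.5, fn_share = 0.5))
  expect_null(error_decomposition(outcome_counts(5L, 0L, 0L)))
})

test_that("grid_tune evaluates the full grid and reports a consistent best cell", {
  spec <- simulation_spec(seed = 21L, n_docs = 10L, lexicon_size = 30L,
                          negation_rate = 0.2)
  lexicon <- generate_lexicon(spec)
  corpus <- generate_corpus(spec, lexicon)
  outputs <- simulate_extractor_outputs(corpus$documents, corpus$gold, spec, lexicon)
  per_doc <- prepare_extractor_terms(corpus$documents, outputs, lexicon)
  omega <- stats::setNames(rep(1 / 3, 3), names(spec$extractor_profiles))

  tuned <- grid_tune(per_doc, corpus$gold, omega,
                     kappa_values = c(FALSE, TRUE),
                     gamma_values = c(0.1, 0.5), theta_values = c(0.2, 0.9))
  expect_equal(nrow(tuned$grid), 8)  # full Cartesian product
  expect_equal(tuned$best$f1, max(tuned$grid$f1))
  # one-cell grid equals a direct pipeline run
  one <- grid_tune(per_doc, corpus$gold, omega, kappa_values = FALSE,
                   gamma_values = 0.1, theta_values = 0.35)
  expect_equal(nrow(one$grid), 1)
  expect_equal(one$best, one$grid)
  # kappa on can only lower recall
  by_kappa <- split(tuned$grid, tuned$grid$kappa)
  merged <- merge(by_kappa$`TRUE`, by_kappa$`FALSE`, by = c("gamma", "theta"))
  expect_true(all(merged$recall.x <= merged$recall.y + 1e-12))
  expect_error(grid_tune(per_doc, corpus$gold, omega, kappa_values = logical(0)),
               class = "cx_config_error")
})
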