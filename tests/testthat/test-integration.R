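test_that("pair_similarity evaluates the alpha/beta weight on worked cases", {
  ten <- sprintf("C%02d", 1:10)
  a <- mk_nterm(ten)
  expect_equal(pair_similarity(a, a)$weight, 1.0)
  expect_equal(pair_similarity(a, mk_nterm(sprintf("D%02d", 1:10)))$weight, 0.0)
  # 2 shared of 10 overall, 1 shared within both top-3
  b <- mk_nterm(c("C01", "X1", "X2", "C04", "X3", "X4", "X5", "X6", "X7", "X8"))
  s <- pair_similarity(a, b)
  expect_equal(s$alpha, 0.2)
  expect_equal(s$beta, 1 / 3)
  expect_equal(s$weight, 0.2 / 4 + 3 * (1 / 3) / 4)  # 0.30
  # empty match list on either side forces weight 0
  expect_equal(pair_similarity(a, mk_nterm(character(0)))$weight, 0)
  expect_equal(pair_similarity(mk_nterm(character(0)), a)$weight, 0)
  # code equality is (system, code) pairwise: same code string, other system
  other <- mk_nterm(ten, system = "ICD10")
  expect_equal(pair_similarity(a, other)$weight, 0)
})

test_that("pair_similarity matches the brute-force oracle and is symmetric", {
  set.seed(101)
  for (trial in 1:300) {
    a <- random_nterm()
    b <- random_nterm()
    got <- pair_similarity(a, b)
    want <- oracle_similarity(a, b)
    expect_equal(got$alpha, want$alpha)
    expect_equal(got$beta, want$beta)
    expect_equal(got$weight, want$weight)
    rev <- pair_similarity(b, a)
    expect_equal(rev$weight, got$weight)
    expect_gte(got$weight, 0)
    expect_lte(got$weight, 1)
  }
})

test_that("weight is monotone in both overlaps", {
  base <- sprintf("C%02d", 1:10)
  for (k in 0:9) {
    lo <- mk_nterm(c(base[seq_len(k)], sprintf("Z%02d", seq_len(10 - k))))
    hi <- mk_nterm(c(base[seq_len(k + 1)], sprintf("Z%02d", seq_len(9 - k))))
    expect_lte(pair_similarity(mk_nterm(base), lo)$weight,
               pair_similarity(mk_nterm(base), hi)$weight)
  }
})

test_that("equal-term decision is strictly greater-than gamma", {
  s <- structure(list(alpha = 0.2, beta = 1 / 3, weight = 0.30),
                 class = "cx_pairsim")
  expect_true(are_equal_terms(s, 0.1))
  expect_false(are_equal_terms(s, 0.30))  # exactly at threshold
  expect_false(are_equal_terms(structure(list(weight = 0), class = "cx_pairsim"), 0))
  expect_error(are_equal_terms(s, 1.5), class = "cx_config_error")
})

test_that("merge_terms chains similarity transitively", {
  A <- mk_nterm(sprintf("A%02d", 1:10), surface = "a", extractor_id = "e1")
  B <- mk_nterm(c("A01", "A02", "C01", "A03", "C02", "C03", sprintf("B%02d", 1:4)),
                surface = "b", extractor_id = "e2")
  C <- mk_nterm(c(sprintf("C%02d", 1:3), sprintf("D%02d", 1:7)),
                surface = "c", extractor_id = "e3")
  # A~B share top-3, B~C share top-3 via C01..C03, A and C are disjoint
  expect_gt(pair_similarity(A, B)$weight, 0.1)
  expect_gt(pair_similarity(B, C)$weight, 0.1)
  expect_equal(pair_similarity(A, C)$weight, 0)
  merged <- merge_terms(list(A, B, C), gamma = 0.1)
  expect_length(merged, 1)
  expect_setequal(merged[[1]]$extractor_ids, c("e1", "e2", "e3"))
  # singleton input
  expect_length(merge_terms(list(A), 0.1), 1)
  # gamma = 1: nothing merges (weight can never strictly exceed 1)
  expect_length(merge_terms(list(A, B, C), gamma = 1), 3)
  expect_length(merge_terms(list(), 0.1), 0)
})

test_that("merge_terms equals the brute-force component oracle on random instances", {
  set.seed(202)
  for (trial in 1:500) {
    n <- sample(0:12, 1)
    terms <- lapply(seq_len(n), function(i)
      random_nterm(universe = sprintf("C%02d", 1:12), max_len = 6,
                   extractor_id = paste0("e", sample(1:4, 1))))
    gamma <- sample(c(0, 0.05, 0.1, 0.3, 0.6), 1)
    merged <- merge_terms(terms, gamma)
    comp <- oracle_components(terms, gamma)
    expect_equal(length(merged), length(unique(comp)))
    # identical partitions, not just counts
    oracle_sets <- vapply(split(seq_len(n), comp), function(idx)
      paste(sort(vapply(terms[idx], function(t) t$term$surface, character(1))),
            collapse = "|"), character(1))
    expect_setequal(partition_sets(merged), unname(oracle_sets))
  }
})

test_that("merging is invariant to input order", {
  set.seed(303)
  terms <- lapply(1:8, function(i)
    random_nterm(universe = sprintf("C%02d", 1:10), max_len = 5,
                 extractor_id = paste0("e", i %% 3 + 1)))
  ref <- merge_terms(terms, 0.1)
  for (rep in 1:5) {
    perm <- merge_terms(sample(terms), 0.1)
    expect_equal(partition_sets(perm), partition_sets(ref))
  }
})

test_that("cumulative weight sums distinct extractors only", {
  omega3 <- c(A = 0.4, B = 0.3, C = 0.3)
  ab <- merge_terms(list(mk_nterm(sprintf("C%02d", 1:10), extractor_id = "A"),
                         mk_nterm(sprintf("C%02d", 1:10), extractor_id = "B"),
                         mk_nterm(sprintf("C%02d", 1:10), extractor_id = "B")),
                    gamma = 0.1)
  expect_length(ab, 1)
  expect_equal(cumulative_weight(ab[[1]], omega3), 0.7)  # B counted once
  omega6 <- stats::setNames(rep(1 / 6, 6), paste0("e", 1:6))
  solo <- merge_terms(list(mk_nterm("C01", extractor_id = "e4")), 0.1)
  expect_equal(cumulative_weight(solo[[1]], omega6), 1 / 6)
  expect_error(cumulative_weight(solo[[1]], omega3), class = "cx_config_error")
})

test_that("integration accepts strictly above theta and sorts by weight", {
  omega <- stats::setNames(rep(1 / 6, 6), paste0("e", 1:6))
  cfg <- integration_config(gamma = 0.1, theta = 0.35, omega = omega)
  hematoma <- sprintf("H%02d", 1:10)
  ohypo <- sprintf("O%02d", 1:10)
  per_ext <- lapply(stats::setNames(nm = paste0("e", 1:6)), function(id) {
    i <- as.integer(sub("e", "", id))
    out <- list()
    if (i <= 2) out <- c(out, list(mk_nterm(hematoma, surface = "hematoma",
                                            extractor_id = id)))
    if (i <= 5) out <- c(out, list(mk_nterm(ohypo, surface = "orthostatic hypotension",
                                            extractor_id = id)))
    out
  })
  res <- integrate_terms(per_ext, cfg, doc_id = "d1")
  expect_length(res$accepted, 1)
  expect_length(res$rejected, 1)
  expect_equal(res$accepted[[1]]$representative$term$surface,
               "orthostatic hypotension")
  expect_equal(res$accepted[[1]]$cumulative_weight, 5 / 6)
  expect_equal(res$rejected[[1]]$cumulative_weight, 2 / 6)

  # empty input
  empty <- integrate_terms(list(), cfg, doc_id = "d0")
  expect_length(empty$accepted, 0)
  expect_length(empty$rejected, 0)
  # single extractor with full weight
  one <- integrate_terms(list(eX = list(mk_nterm("C1", extractor_id = "eX"))),
                         integration_config(omega = c(eX = 1)), "d2")
  expect_length(one$accepted, 1)
  expect_equal(one$accepted[[1]]$cumulative_weight, 1.0)
})

test_that("integration is invariant to extractor and term order", {
  set.seed(404)
  ids <- paste0("e", 1:3)
  omega <- stats::setNames(rep(1 / 3, 3), ids)
  per_ext <- lapply(stats::setNames(nm = ids), function(id)
    lapply(1:4, function(i) random_nterm(universe = sprintf("C%02d", 1:15),
                                         max_len = 6, extractor_id = id)))
  cfg <- integration_config(omega = omega)
  ref <- integrate_terms(per_ext, cfg, "d")
  digest <- function(res) lapply(res$accepted, function(e)
    list(s = e$representative$term$surface, w = e$cumulative_weight,
         ids = e$extractor_ids))
  for (rep in 1:4) {
    shuffled <- lapply(per_ext[sample(ids)], sample)
    expect_equal(digest(integrate_terms(shuffled, cfg, "d")), digest(ref))
  }
})

test_that("raising theta never grows the accepted set", {
  set.seed(505)
  ids <- paste0("e", 1:4)
  omega <- stats::setNames(rep(0.25, 4), ids)
  per_ext <- lapply(stats::setNames(nm = ids), function(id)
    lapply(1:5, function(i) random_nterm(universe = sprintf("C%02d", 1:12),
                                         max_len = 8, extractor_id = id)))
  surfaces <- function(res) vapply(res$accepted, function(e)
    e$representative$term$surface, character(1))
  prev <- NULL
  for (theta in c(0.1, 0.3, 0.5, 0.8)) {
    cur <- surfaces(integrate_terms(per_ext,
                                    integration_config(theta = theta, omega = omega),
                                    "d"))
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("raising gamma never decreases the number of entities", {
  set.seed(606)
  terms <- lapply(1:10, function(i)
    random_nterm(universe = sprintf("C%02d", 1:10), max_len = 8,
                 extractor_id = paste0("e", i %% 3 + 1)))
  counts <- vapply(c(0, 0.1, 0.25, 0.5, 0.9), function(g)
    length(merge_terms(terms, g)), integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("integration config validates its ranges", {
  expect_error(integration_config(gamma = -0.1), class = "cx_config_error")
  expect_error(integration_config(theta = 1.2), class = "cx_config_error")
  expect_error(integration_config(omega = c(0.5, 0.5)), class = "cx_config_error")
  cfg <- integration_config()
  expect_equal(cfg$gamma, 0.1)
  expect_equal(cfg$theta, 0.35)
  expect_false(cfg$kappa)
})
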