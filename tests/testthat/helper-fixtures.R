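# shared builders for small in-code fixtures

mk_nterm <- function(codes, surface = "x", extractor_id = "e1",
                     start = NA_integer_, system = "CUI") {
  end <- if (is.na(start)) NA_integer_ else start + nchar(surface)
  term <- extracted_term(surface, start = start, end = end,
                         category = "medical_condition",
                         extractor_id = extractor_id)
  matches <- lapply(seq_along(codes), function(i) {
    concept_match(system, codes[i], rank = i, score = 1 - 0.05 * (i - 1))
  })
  normalized_term(term, matches)
}

mk_gold <- function(doc_id = "d1", surface = NULL, codes = NULL,
                    polarity = "present", category = "medical_condition") {
  if (!is.null(codes)) {
    codes <- lapply(codes, function(cd) list(code_system = "CUI", code = cd))
  }
  gold_annotation(doc_id, surface = surface, codes = codes,
                  category = category, polarity = polarity)
}

# random match lists over a small code universe, for property tests
random_nterm <- function(universe = sprintf("C%03d", 1:30), max_len = 10,
                         extractor_id = "e1") {
  k <- sample(0:max_len, 1)
  codes <- if (k == 0) character(0) else sample(universe, k)
  mk_nterm(codes, surface = paste0("t", sample.int(1e6, 1)),
           extractor_id = extractor_id)
}

# independent brute-force similarity: plain set arithmetic on code keys
oracle_similarity <- function(a, b) {
  keys <- function(nt) vapply(nt$matches, function(m)
    paste(m$code_system, m$code, sep = ":"), character(1))
  ka <- keys(a); kb <- keys(b)
  if (length(ka) == 0 || length(kb) == 0) return(list(alpha = 0, beta = 0, weight = 0))
  alpha <- sum(ka %in% kb) / 10
  beta <- sum(ka[seq_len(min(3, length(ka)))] %in%
                kb[seq_len(min(3, length(kb)))]) / 3
  list(alpha = alpha, beta = beta, weight = alpha / 4 + 3 * beta / 4)
}

# brute-force connected components by repeated closure over an adjacency matrix
oracle_components <- function(nterms, gamma) {
  n <- length(nterms)
  if (n == 0) return(integer(0))
  adj <- diag(TRUE, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      w <- oracle_similarity(nterms[[i]], nterms[[j]])$weight
      adj[i, j] <- adj[j, i] <- w > gamma
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj > 0)) break
    adj <- nxt
  }
  comp <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (comp[i] == 0L) {
      cid <- cid + 1L
      comp[adj[i, ] > 0] <- cid
    }
  }
  comp
}

# partition of term surfaces induced by merge_terms, as a canonical string set
partition_sets <- function(entities) {
  sets <- lapply(entities, function(e)
    sort(vapply(e$members, function(m) m$term$surface, character(1))))
  sort(vapply(sets, paste, character(1), collapse = "|"))
}
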