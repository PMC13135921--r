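# Shared fixtures: small deterministic catalogs, predictors, and brute-force
# statistical oracles kept independent of the implementation paths they check.

small_catalog <- function(seed = 7L) {
  make_toy_catalog(n_alleles = 8L, length = 30L, rate = 0.2, seed = seed)
}

small_predictor <- function(seed = 11L, ...) {
  surrogate_predictor(seed = seed, ...)
}

seeded_pair <- function(catalog, seed) {
  set.seed(seed)
  random_pair(catalog)
}

# Mann-Whitney AUC by explicit cross-pair counting (ties count 1/2).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  s <- 0
  for (p in pos) s <- s + sum(p > neg) + 0.5 * sum(p == neg)
  s / (length(pos) * length(neg))
}

# Default-conditions study, simulated once and reused across test files.
get_default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(default_sim_config(master_seed = 1L))
    }
    cache
  }
})

expect_score_identities <- function(sc) {
  expect_identical(sc$class1, sum(sc$per_locus[c("A", "B", "C")]))
  expect_identical(sc$class2, sum(sc$per_locus[c("DRB1", "DQB1")]))
  expect_true(max(sc$per_locus) <= sc$total)
  expect_true(sc$total <= sc$class1 + sc$class2)
}
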