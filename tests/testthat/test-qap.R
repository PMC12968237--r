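test_that("split_half divides rows evenly and reproducibly", {
  m <- rand_lm(5, 3, seed = 2)
  halves <- split_half(m, seed = 9)
  expect_equal(sort(c(n_texts(halves[[1]]), n_texts(halves[[2]]))), c(2L, 3L))
  again <- split_half(m, seed = 9)
  expect_identical(halves[[1]]$incidence, again[[1]]$incidence)
  expect_error(split_half(lm_from_sets(list(1), 2)), "at least two")

  big <- rand_lm(1000, 2, seed = 3)
  h <- split_half(big, seed = 1)
  expect_equal(n_texts(h[[1]]), 500L)
  expect_equal(n_texts(h[[2]]), 500L)
  # halves partition the corpus
  expect_equal(sum(h[[1]]$incidence) + sum(h[[2]]$incidence),
               sum(big$incidence))
})

test_that("identical matrices give r = 1 at the minimal attainable p", {
  a <- withr::with_seed(5, rand_adj(10, 0.5))
  res <- qap_correlation(a, a, n_permutations = 199, seed = 3)
  expect_equal(res$r_observed, 1)
  expect_equal(res$p_value, 1 / 200)
})

test_that("QAP r is symmetric and invariant to joint relabeling", {
  withr::with_seed(8, {
    a <- rand_adj(9, 0.5)
    b <- rand_adj(9, 0.5)
  })
  r_ab <- qap_correlation(a, b, n_permutations = 99, seed = 1)$r_observed
  r_ba <- qap_correlation(b, a, n_permutations = 99, seed = 1)$r_observed
  expect_equal(r_ab, r_ba, tolerance = 1e-12)

  p <- withr::with_seed(2, sample.int(9))
  r_perm <- qap_correlation(a[p, p], b[p, p], n_permutations = 99,
                            seed = 1)$r_observed
  expect_equal(r_perm, r_ab, tolerance = 1e-12)
})

test_that("degenerate matrices report missing r with a warning", {
  a <- matrix(0, 5, 5)
  b <- withr::with_seed(1, rand_adj(5, 0.6))
  expect_warning(res <- qap_correlation(a, b, 99, seed = 1), "zero variance")
  expect_true(is.na(res$r_observed))
  expect_error(qap_correlation(matrix(0, 2, 3), matrix(0, 3, 3), 10, 1),
               "square")
  asym <- matrix(c(0, 1, 0, 0), 2, 2)
  expect_error(qap_correlation(asym, asym, 10, 1), "symmetric")
})

test_that("a relabeled copy correlates weakly under its own QAP null", {
  withr::with_seed(31, {
    a <- rand_adj(10, 0.5)
    p <- sample.int(10)
    b <- a[p, p]
  })
  res <- qap_correlation(a, b, n_permutations = 499, seed = 7)
  # the permuted copy is just another draw from the null: not significant
  expect_gt(res$p_value, 0.05)
})

test_that("split-half QAP recovers shared structure in a planted corpus", {
  m <- generate_corpus(planted_structure_config(30000, seed = 55))
  res <- split_half_qap(m, cfg = association_config(apply_significance_filter = FALSE),
                        n_permutations = 199, seed = 5)
  expect_equal(sum(res$half_sizes), 30000L)
  expect_gt(res$r_observed, 0.9)
  expect_lt(res$p_value, 0.01)
})

test_that("stratified QAP requires groups and returns high r for shared structure", {
  m <- generate_corpus(planted_structure_config(30000, seed = 77))
  expect_error(stratified_qap(m), "group_id")
  m$group_id <- withr::with_seed(3, sample(1:60, 30000, replace = TRUE,
                                           prob = rgamma(60, 1)))
  for (rule in c("median", "pareto", "quartile")) {
    res <- stratified_qap(m, rule = rule,
                          cfg = association_config(apply_significance_filter = FALSE),
                          n_permutations = 99, seed = 5)
    expect_gt(res$r_observed, 0.85)
    expect_equal(sum(res$stratum_sizes), 30000L)
  }
})

test_that("strata with disjoint planted structure correlate near zero", {
  tax <- default_taxonomy()
  mk <- function(idx, seed) {
    generate_corpus(synthetic_config(
      8000,
      prevalences = ifelse(seq_along(tax) %in% idx, 0.02, 0.084),
      bundles = list(list(members = tax[idx[1:2]], weight = 0.05),
                     list(members = tax[idx[c(1, 3)]], weight = 0.05)),
      seed = seed))
  }
  a <- corpus_adj <- distortnet:::corpus_adjacency(
    mk(c(1, 2, 3), 1), association_config(apply_significance_filter = FALSE))
  b <- distortnet:::corpus_adjacency(
    mk(c(10, 11, 12), 2), association_config(apply_significance_filter = FALSE))
  res <- qap_correlation(a, b, n_permutations = 199, seed = 3)
  expect_lt(abs(res$r_observed), 0.3)
})
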