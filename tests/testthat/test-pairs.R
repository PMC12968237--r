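test_that("pair table enumerates C(D,2) pairs with hand-checked counts", {
  # A present in texts 1-3, B in texts 1,2,4 -> O = 2
  m <- lm_from_sets(list(c(1, 2), c(1, 2), 1, 2, integer(0), integer(0)), 3)
  ps <- pair_stats(m)
  expect_equal(nrow(ps), choose(3, 2))
  ab <- ps[ps$label_i == "A" & ps$label_j == "B", ]
  expect_equal(ab$observed, 2L)
  expect_equal(ab$n_i, 3L)
  expect_equal(ab$n_j, 3L)
  # E = 3*3/6, lift = 2/1.5 (hand arithmetic)
  expect_equal(ab$expected, 1.5)
  expect_equal(ab$lift, 4 / 3, tolerance = 1e-12)
  # label C has zero marginal: all its pairs have O = 0 and lift undefined
  cc <- ps[ps$label_j == "C" | ps$label_i == "C", ]
  expect_true(all(cc$observed == 0L))
  expect_true(all(is.na(cc$lift)))
})

test_that("18 labels give 153 pairs", {
  m <- withr::with_seed(3, label_matrix(matrix(rbinom(5 * 18, 1, 0.2), 5),
                                        taxonomy = default_taxonomy()))
  expect_equal(nrow(pair_stats(m)), 153L)
})

test_that("chi-square matches the closed form on a balanced 2x2 table", {
  # contingency [[30,20],[20,30]] at n = 100: chi2 = 4 exactly
  sets <- c(rep(list(c(1, 2)), 30), rep(list(1L), 20),
            rep(list(2L), 20), rep(list(integer(0)), 30))
  ps <- pair_stats(lm_from_sets(sets, 2))
  expect_equal(ps$chi2, 4, tolerance = 1e-12)
  expect_equal(ps$p_value, stats::pchisq(4, 1, lower.tail = FALSE),
               tolerance = 1e-12)
})

test_that("independent margins give chi2 = 0, p = 1, lift = 1", {
  # O = E exactly: A and B independent by construction
  sets <- c(rep(list(c(1, 2)), 1), rep(list(1L), 1), rep(list(2L), 1),
            rep(list(integer(0)), 1))
  ps <- pair_stats(lm_from_sets(sets, 2))
  expect_equal(ps$lift, 1)
  expect_equal(ps$chi2, 0)
  expect_equal(ps$p_value, 1)
})

test_that("pair statistics agree with brute-force oracles on random matrices", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(5:60, 1)
      d <- sample(2:8, 1)
      m <- rand_lm(n, d, p = runif(1, 0.05, 0.6))
      ps <- pair_stats(m)
      orc <- oracle_pairs(m$incidence)
      expect_equal(ps$observed, orc$observed)
      expect_equal(ps$expected, orc$expected, tolerance = 1e-12)
      expect_equal(ps$lift, orc$lift, tolerance = 1e-12)
      for (r in sample(nrow(ps), min(4, nrow(ps)))) {
        oc <- oracle_chi2(m$incidence, orc$i[r], orc$j[r])
        expect_equal(ps$chi2[r], oc$chi2, tolerance = 1e-9)
        expect_equal(ps$p_value[r], oc$p, tolerance = 1e-9)
      }
    }
  })
})

test_that("per-pair observed count never exceeds either marginal", {
  m <- rand_lm(100, 7, p = 0.3, seed = 13)
  ps <- pair_stats(m)
  expect_true(all(ps$observed <= pmin(ps$n_i, ps$n_j)))
  expect_lte(sum(ps$observed), choose(7, 2) * 100)
})

test_that("lift is invariant under duplicating the corpus", {
  m <- rand_lm(60, 6, p = 0.3, seed = 17)
  mm <- rbind(m, m)
  expect_equal(pair_stats(mm)$lift, pair_stats(m)$lift, tolerance = 1e-12)
})

test_that("edge filtering applies strict lift, count, and Bonferroni rules", {
  stats <- data.frame(
    label_i = c("A", "B", "C", "D"), label_j = c("B", "C", "D", "E"),
    n_i = 10L, n_j = 10L, observed = c(5L, 5L, 0L, 5L),
    expected = 2, lift = c(1.0, 2.5, NA, 2.5),
    chi2 = 10, p_value = c(1e-6, 1e-6, 1e-6, 0.01))
  cfg <- association_config(alpha = 0.05, n_tests = 153)
  out <- filter_edges(stats, cfg)
  # lift exactly 1 excluded (strict); NA lift excluded; p = 0.01 above
  # 0.05/153 excluded; only row 2 survives
  expect_equal(nrow(out), 1L)
  expect_equal(out$label_i, "B")
  expect_true(all(out$significant))
  expect_equal(attr(out, "corrected_alpha"), 0.05 / 153)

  off <- filter_edges(stats, association_config(apply_significance_filter = FALSE))
  expect_equal(sort(off$label_i), c("B", "D"))

  min2 <- filter_edges(stats, association_config(min_count = 6,
                                                 apply_significance_filter = FALSE))
  expect_equal(nrow(min2), 0L)
})

test_that("Yates-corrected chi-square matches chisq.test with correction", {
  m <- rand_lm(40, 4, p = 0.3, seed = 23)
  ps <- pair_stats(m, continuity_correction = TRUE)
  orc <- oracle_pairs(m$incidence)
  for (r in seq_len(nrow(ps))) {
    tab <- table(factor(m$incidence[, orc$i[r]], levels = c(1, 0)),
                 factor(m$incidence[, orc$j[r]], levels = c(1, 0)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    ct <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
    expect_equal(ps$chi2[r], unname(ct$statistic), tolerance = 1e-9)
  }
})
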