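tax18 <- default_taxonomy()

test_that("degenerate count distribution forces one label per text", {
  cfg <- synthetic_config(500, count_distribution = c("1" = 1), bundles = list(),
                          seed = 4)
  m <- generate_corpus(cfg)
  expect_true(all(label_counts(m) == 1L))
})

test_that("a weight-1 pair bundle forces maximal lift", {
  cfg <- synthetic_config(
    300, count_distribution = c("2" = 1),
    bundles = list(list(members = tax18[c(2, 5)], weight = 1)), seed = 9)
  m <- generate_corpus(cfg)
  expect_true(all(m$incidence[, 2] == 1L & m$incidence[, 5] == 1L))
  ps <- pair_stats(m)
  row <- ps[ps$label_i == tax18[2] & ps$label_j == tax18[5], ]
  expect_equal(row$observed, 300L)
  expect_equal(row$lift, 1)  # both marginals saturated: O = E = N
})

test_that("generation is bit-reproducible for a fixed seed", {
  cfg <- synthetic_config(2000, seed = 77)
  m1 <- generate_corpus(cfg)
  m2 <- generate_corpus(cfg)
  expect_identical(m1$incidence, m2$incidence)
  expect_identical(m1$length_chars, m2$length_chars)
  m3 <- generate_corpus(synthetic_config(2000, seed = 78))
  expect_false(identical(m1$incidence, m3$incidence))
})

test_that("generated lengths respect the analyzed-corpus range", {
  m <- generate_corpus(synthetic_config(5000, seed = 2))
  expect_true(all(m$length_chars >= 200 & m$length_chars <= 8307))
})

test_that("group sizes are heterogeneous under the Dirichlet assignment", {
  m <- generate_corpus(synthetic_config(20000, seed = 5, group_count = 50))
  sizes <- table(m$group_id)
  expect_gt(max(sizes) / max(min(sizes), 1), 2)
  expect_equal(sum(sizes), 20000)
})

test_that("flat prevalences with Binomial counts give exchangeable labels", {
  # independent-Bernoulli equivalent: per-text count ~ Binomial(18, p) with
  # uniform label weights makes every pairwise lift converge to 1
  p <- 1.78 / 18
  probs <- stats::dbinom(0:10, 18, p)
  cd <- stats::setNames(probs / sum(probs), 0:10)
  cfg <- synthetic_config(50000, prevalences = rep(1 / 18, 18),
                          bundles = list(), count_distribution = cd, seed = 31)
  ps <- pair_stats(generate_corpus(cfg))
  expect_lt(abs(mean(ps$lift) - 1), 0.02)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(0), "positive integer")
  expect_error(synthetic_config(10, count_distribution = c("19" = 1)),
               "exceed the taxonomy")
  expect_error(synthetic_config(10, count_distribution = c("1" = 0.5)),
               "sum to 1")
  expect_error(
    synthetic_config(10, bundles = list(list(members = c("X", "Y"), weight = 0.1))),
    "not in taxonomy")
  expect_error(
    synthetic_config(10, bundles = list(list(members = tax18[1:2], weight = 0.8),
                                        list(members = tax18[3:4], weight = 0.4))),
    "at most 1")
})

test_that("noise injection is an identity at zero and exact at the spec rates", {
  m <- rand_lm(50, 8, p = 0.25, seed = 6)
  expect_identical(inject_noise(m, noise_spec(0, seed = 1))$incidence,
                   m$incidence)

  # force exactly L = 100 positives
  inc <- matrix(0L, 50, 8, dimnames = list(NULL, letter_taxonomy(8)))
  inc[sample(length(inc), 100)] <- 1L
  m100 <- label_matrix(inc)
  noisy <- inject_noise(m100, noise_spec(0.5, seed = 3))
  flipped_off <- sum(m100$incidence == 1L & noisy$incidence == 0L)
  flipped_on <- sum(m100$incidence == 0L & noisy$incidence == 1L)
  expect_equal(flipped_off, 25)
  expect_equal(flipped_on, 25)
  expect_equal(sum(noisy$incidence), 100)
  expect_true(all(noisy$incidence %in% c(0L, 1L)))
})

test_that("noise is deterministic in the seed and seed-sensitive", {
  m <- rand_lm(100, 10, p = 0.2, seed = 8)
  a <- inject_noise(m, noise_spec(0.1, seed = 5))
  b <- inject_noise(m, noise_spec(0.1, seed = 5))
  c <- inject_noise(m, noise_spec(0.1, seed = 6))
  expect_identical(a$incidence, b$incidence)
  expect_false(identical(a$incidence, c$incidence))
  expect_error(noise_spec(0.6), "0, 0.5")
})

test_that("noise preserves the positive-cell count within rounding", {
  withr::with_seed(14, {
    for (eps in c(0.05, 0.15, 0.3, 0.5)) {
      m <- rand_lm(80, 9, p = runif(1, 0.1, 0.4))
      noisy <- inject_noise(m, noise_spec(eps, seed = sample.int(1e6, 1)))
      expect_lte(abs(sum(noisy$incidence) - sum(m$incidence)), 1)
      expect_true(all(noisy$incidence %in% c(0L, 1L)))
    }
  })
})

test_that("fn_fraction skews the deletion/addition split", {
  m <- rand_lm(100, 10, p = 0.3, seed = 12)
  L <- sum(m$incidence)
  del_only <- inject_noise(m, noise_spec(0.2, seed = 1, fn_fraction = 1))
  expect_equal(sum(m$incidence == 1L & del_only$incidence == 0L),
               round(0.2 * L))
  expect_equal(sum(m$incidence == 0L & del_only$incidence == 1L), 0)
})
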