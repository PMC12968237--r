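#' Association filtering configuration
#'
#' Thresholds applied when turning pairwise statistics into network edges:
#' lift strictly above `lift_threshold`, observed count at least
#' `min_count`, and (when the significance filter is on) chi-square
#' p-value below the Bonferroni-corrected level `alpha / n_tests`.
#'
#' The significance filter defaults to ON, matching the headline network
#' construction; resampling analyses (bootstrap, noise sweeps) pass their
#' own configuration with the filter OFF, reflecting the two-criterion
#' reconstruction rule (count >= 1, lift > 1).
#'
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_tests Number of tests for the Bonferroni correction; default
#'   `NULL` means the number of pairs in the table being filtered
#'   (C(D,2), i.e. 153 for the 18-label taxonomy).
#' @param lift_threshold Edges require lift strictly greater than this
#'   (default 1.0).
#' @param min_count Minimum observed co-occurrence count (default 1).
#' @param apply_significance_filter Apply the Bonferroni p-value criterion
#'   (default `TRUE`).
#' @param continuity_correction Use the Yates continuity correction in the
#'   chi-square statistic (default `FALSE`).
#' @return An object of class `association_config`.
#' @export
association_config <- function(alpha = 0.05, n_tests = NULL,
                               lift_threshold = 1.0, min_count = 1L,
                               apply_significance_filter = TRUE,
                               continuity_correction = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0,1)")
  if (!is.null(n_tests) && n_tests < 1) stop("n_tests must be >= 1")
  structure(
    list(alpha = alpha, n_tests = n_tests, lift_threshold = lift_threshold,
         min_count = as.integer(min_count),
         apply_significance_filter = isTRUE(apply_significance_filter),
         continuity_correction = isTRUE(continuity_correction)),
    class = "association_config"
  )
}

# Pair co-occurrence counts and chi-square statistics from a raw incidence
# matrix; the vectorized core shared by every resampling loop.
pair_table <- function(inc, continuity_correction = FALSE) {
  d <- ncol(inc)
  n <- nrow(inc)
  if (n < 1L) stop("pair statistics require a non-empty matrix")
  if (d < 2L) stop("pair statistics require at least two labels")
  cross <- crossprod(inc)
  marg <- diag(cross)
  combs <- utils::combn(d, 2L)
  i <- combs[1, ]; j <- combs[2, ]
  o <- cross[cbind(i, j)]
  n_i <- marg[i]; n_j <- marg[j]
  e <- n_i * n_j / n
  lift <- ifelse(e > 0, o / e, NA_real_)
  # 2x2 table closed form: a = both, b = only i, c = only j, d = neither
  a <- o; b <- n_i - o; cc <- n_j - o; dd <- n - n_i - n_j + o
  denom <- n_i * n_j * (n - n_i) * (n - n_j)
  num <- a * dd - b * cc
  if (continuity_correction) num <- pmax(abs(num) - n / 2, 0)
  chi2 <- ifelse(denom > 0, n * num^2 / denom, 0)
  p <- ifelse(denom > 0, stats::pchisq(chi2, df = 1, lower.tail = FALSE), 1)
  data.frame(
    label_i = colnames(inc)[i], label_j = colnames(inc)[j],
    n_i = as.integer(n_i), n_j = as.integer(n_j),
    observed = as.integer(o), expected = e, lift = lift,
    chi2 = chi2, p_value = p,
    stringsAsFactors = FALSE
  )
}

#' Pairwise co-occurrence statistics for all label pairs
#'
#' For each of the C(D,2) unordered label pairs computes the observed
#' co-occurrence count O (texts containing both labels), the expected
#' count under independence E = N_i * N_j / N_total, the lift ratio O / E,
#' and a Pearson chi-square test (1 df, no continuity correction by
#' default) on the 2x2 contingency table (both / only i / only j /
#' neither). Pairs with E = 0 (a label absent from the corpus) report lift
#' as `NA`, never infinite. Zero row/column margins yield chi2 = 0,
#' p = 1.
#'
#' @param m A non-empty `label_matrix` with at least two labels.
#' @param continuity_correction Apply the Yates correction (default
#'   `FALSE`).
#' @return Data frame of class `pair_stats` with one row per pair and
#'   columns `label_i`, `label_j`, `n_i`, `n_j`, `observed`, `expected`,
#'   `lift`, `chi2`, `p_value`. Attribute `n_total` carries the corpus
#'   size.
#' @export
pair_stats <- function(m, continuity_correction = FALSE) {
  out <- pair_table(m$incidence, continuity_correction)
  attr(out, "n_total") <- n_texts(m)
  class(out) <- c("pair_stats", class(out))
  out
}

#' Filter pair statistics to significant network edges
#'
#' Retains pairs with lift strictly greater than `cfg$lift_threshold`,
#' observed count at least `cfg$min_count`, and — when the significance
#' filter is on — chi-square p-value below the Bonferroni-corrected level
#' `alpha / n_tests`. Pairs with undefined lift never pass.
#'
#' @param stats A `pair_stats` data frame (complete table).
#' @param cfg An [association_config()].
#' @return The subset of significant pairs (with a `significant` column,
#'   all `TRUE`), carrying attributes `config`, `corrected_alpha` and
#'   `n_total`.
#' @export
filter_edges <- function(stats, cfg = association_config()) {
  n_tests <- if (is.null(cfg$n_tests)) nrow(stats) else cfg$n_tests
  corrected <- cfg$alpha / n_tests
  ok <- !is.na(stats$lift) &
    stats$lift > cfg$lift_threshold &
    stats$observed >= cfg$min_count
  if (cfg$apply_significance_filter) ok <- ok & stats$p_value < corrected
  out <- stats[ok, , drop = FALSE]
  out$significant <- rep(TRUE, nrow(out))
  attr(out, "config") <- cfg
  attr(out, "corrected_alpha") <- corrected
  attr(out, "n_total") <- attr(stats, "n_total")
  out
}
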