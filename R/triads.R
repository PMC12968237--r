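#' Triadic co-occurrence statistics and the Integrated Significance Metric
#'
#' For every unordered triple of labels (C(D,3) combinations; 816 for the
#' 18-label taxonomy) computes:
#'
#' * `count` — number of texts containing all three labels;
#' * `f_rel` — relative frequency, `count / N_total` (an alternative
#'   denominator, the total number of triadic instances
#'   `sum over texts of C(k_text, 3)`, is available via
#'   `f_rel_denominator = "triadic_instances"`);
#' * `p_avg` — mean of the three conditional probabilities
#'   P(i | j and k), P(j | i and k), P(k | i and j), each the triple count
#'   divided by the corresponding pair count; a conditional with zero
#'   denominator contributes 0;
#' * `oer` — observed-to-expected ratio under independence,
#'   `count / (N_total * pi_i * pi_j * pi_k)` with `pi` the marginal label
#'   proportions;
#' * `ism = f_rel * p_avg * oer` — the multiplicative Integrated
#'   Significance Metric, high only when frequency, conditional
#'   probability and enrichment are simultaneously elevated. Triples with
#'   `count = 0` report all components (and ISM) as 0.
#'
#' @param m A `label_matrix` with at least three labels.
#' @param f_rel_denominator `"n_texts"` (default) or `"triadic_instances"`.
#' @return Data frame of class `triad_stats`, one row per triple, columns
#'   `label_i`, `label_j`, `label_k`, `count`, `f_rel`, `p_avg`, `oer`,
#'   `ism`. Attribute `n_total` carries the corpus size.
#' @export
triad_stats <- function(m, f_rel_denominator = c("n_texts", "triadic_instances")) {
  f_rel_denominator <- match.arg(f_rel_denominator)
  inc <- m$incidence
  d <- ncol(inc)
  n <- nrow(inc)
  if (d < 3L) stop("triad statistics require at least three labels")
  marg <- colSums(inc)
  cross <- crossprod(inc)

  combs <- utils::combn(d, 3L)
  n_tri <- ncol(combs)
  i <- combs[1, ]; j <- combs[2, ]; k <- combs[3, ]
  # counts via per-label restriction: among texts containing label i, the
  # pair co-occurrence matrix of the remaining labels gives all (i,j,k)
  cps <- vector("list", d - 2L)
  for (a in 1:(d - 2L)) {
    rows <- inc[, a] == 1L
    cps[[a]] <- crossprod(inc[rows, (a + 1L):d, drop = FALSE])
  }
  cnt <- vapply(seq_len(n_tri), function(t) {
    as.integer(cps[[i[t]]][j[t] - i[t], k[t] - i[t]])
  }, integer(1))

  denom_f <- if (f_rel_denominator == "n_texts") n else {
    kx <- rowSums(inc)
    sum(choose(kx, 3))
  }
  f_rel <- if (denom_f > 0) cnt / denom_f else rep(0, n_tri)

  pair_count <- function(a, b) cross[cbind(pmin(a, b), pmax(a, b))]
  cond <- function(num, den) ifelse(den > 0, num / den, 0)
  p_avg <- (cond(cnt, pair_count(j, k)) +
            cond(cnt, pair_count(i, k)) +
            cond(cnt, pair_count(i, j))) / 3

  expected <- n * (marg[i] / n) * (marg[j] / n) * (marg[k] / n)
  oer <- ifelse(expected > 0, cnt / expected, 0)

  ism <- f_rel * p_avg * oer
  zero <- cnt == 0L
  f_rel[zero] <- 0; p_avg[zero] <- 0; oer[zero] <- 0; ism[zero] <- 0

  out <- data.frame(
    label_i = colnames(inc)[i], label_j = colnames(inc)[j],
    label_k = colnames(inc)[k],
    count = cnt, f_rel = f_rel, p_avg = p_avg, oer = oer, ism = ism,
    stringsAsFactors = FALSE
  )
  attr(out, "n_total") <- n
  class(out) <- c("triad_stats", class(out))
  out
}

#' Threshold triads at an ISM percentile
#'
#' Computes the empirical percentile cutoff (linear interpolation, type-7
#' quantile) over the full vector of C(D,3) ISM values and retains all
#' triads with `ism >= cutoff`, ranked in descending ISM order; ties at
#' the cutoff are kept. An explicit `cutoff` overrides the percentile
#' rule.
#'
#' @param stats A complete `triad_stats` data frame.
#' @param percentile Percentile in (0, 100) (default 99).
#' @param cutoff Optional explicit ISM cutoff; when given, `percentile`
#'   is ignored.
#' @return List of class `triad_threshold` with `percentile`,
#'   `cutoff_value`, and `significant_triads` (ranked data frame with a
#'   `rank` column).
#' @export
threshold_triads <- function(stats, percentile = 99, cutoff = NULL) {
  if (is.null(cutoff)) {
    if (percentile <= 0 || percentile >= 100) {
      stop("percentile must lie strictly between 0 and 100")
    }
    cutoff <- as.numeric(stats::quantile(stats$ism, percentile / 100, type = 7))
  } else {
    percentile <- NA_real_
  }
  sig <- stats[stats$ism >= cutoff, , drop = FALSE]
  sig <- sig[order(-sig$ism, sig$label_i, sig$label_j, sig$label_k), , drop = FALSE]
  if (nrow(sig) > 0L) sig <- cbind(rank = seq_len(nrow(sig)), sig)
  rownames(sig) <- NULL
  structure(
    list(percentile = percentile, cutoff_value = cutoff,
         significant_triads = sig),
    class = "triad_threshold"
  )
}

#' @export
print.triad_threshold <- function(x, ...) {
  cat(sprintf("ISM threshold %.6g (%s): %d significant triads\n",
              x$cutoff_value,
              if (is.na(x$percentile)) "explicit cutoff"
              else sprintf("%gth percentile", x$percentile),
              nrow(x$significant_triads)))
  invisible(x)
}
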