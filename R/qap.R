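#' Split a corpus into two random halves
#'
#' A uniformly random permutation of rows divided into halves of size
#' floor(N/2) and ceiling(N/2); deterministic given the seed.
#'
#' @param m A `label_matrix` with at least two texts.
#' @param seed Integer seed.
#' @return List of two `label_matrix` halves.
#' @export
split_half <- function(m, seed = 42L) {
  n <- n_texts(m)
  if (n < 2L) stop("split_half requires at least two texts")
  perm <- withr::with_seed(seed, sample.int(n))
  first <- perm[seq_len(n %/% 2L)]
  second <- perm[(n %/% 2L + 1L):n]
  list(subset_rows(m, first), subset_rows(m, second))
}

#' QAP permutation correlation between two adjacency matrices
#'
#' The observed statistic is the Pearson correlation over the
#' off-diagonal upper-triangle cells. The null distribution is built by
#' applying the same random node relabeling to the rows AND columns of
#' the second matrix and recomputing the correlation, which respects the
#' dyadic dependence of network data. The p-value is two-sided on |r|
#' with the add-one convention, `p = (1 + #{|r_perm| >= |r_obs|}) /
#' (n_permutations + 1)`, so `p >= 1/(n_permutations + 1)`.
#'
#' @param a,b Square symmetric numeric matrices over the same node set in
#'   the same order.
#' @param n_permutations Number of permutations (default 5000).
#' @param seed Integer seed.
#' @return List of class `qap_result`: `r_observed`, `p_value`,
#'   `n_permutations`, `seed`, `null_distribution`. Zero variance in
#'   either matrix's off-diagonal yields `r_observed = NA` with a
#'   warning.
#' @export
qap_correlation <- function(a, b, n_permutations = 5000L, seed = 1L) {
  if (!is.matrix(a) || !is.matrix(b) || nrow(a) != ncol(a) ||
      !all(dim(a) == dim(b))) {
    stop("a and b must be square matrices of equal dimension")
  }
  if (max(abs(a - t(a))) > 1e-12 || max(abs(b - t(b))) > 1e-12) {
    stop("a and b must be symmetric")
  }
  ut <- upper.tri(a)
  if (stats::sd(a[ut]) == 0 || stats::sd(b[ut]) == 0) {
    warning("zero variance in off-diagonal cells; QAP r undefined")
    return(structure(list(r_observed = NA_real_, p_value = NA_real_,
                          n_permutations = as.integer(n_permutations),
                          seed = as.integer(seed),
                          null_distribution = numeric(0)),
                     class = "qap_result"))
  }
  r_obs <- stats::cor(a[ut], b[ut])
  nperm <- as.integer(n_permutations)
  null_r <- withr::with_seed(seed, {
    vapply(seq_len(nperm), function(i) {
      p <- sample.int(nrow(b))
      stats::cor(a[ut], b[p, p][ut])
    }, numeric(1))
  })
  p <- (1 + sum(abs(null_r) >= abs(r_obs))) / (nperm + 1)
  structure(
    list(r_observed = r_obs, p_value = p, n_permutations = nperm,
         seed = as.integer(seed), null_distribution = null_r),
    class = "qap_result"
  )
}

#' @export
print.qap_result <- function(x, ...) {
  cat(sprintf("QAP r = %.4f, p = %.4g (%d permutations)\n",
              x$r_observed, x$p_value, x$n_permutations))
  invisible(x)
}

# corpus -> filtered network -> adjacency over the full taxonomy node set
corpus_adjacency <- function(m, cfg, convention = "lift_weighted") {
  edges <- filter_edges(pair_stats(m, cfg$continuity_correction), cfg)
  net <- build_network(edges, isolate_policy = "keep", nodes = m$taxonomy,
                       validate = FALSE)
  network_adjacency(net, nodes = m$taxonomy, convention = convention)
}

#' Split-half reliability of the co-occurrence network
#'
#' Divides the corpus into two random halves, builds one filtered network
#' per half on the full taxonomy node set (so the adjacency matrices stay
#' conformable even if a label drops out of one half), and reports the
#' QAP correlation between the two lift-weighted adjacencies.
#'
#' @param m A `label_matrix`.
#' @param cfg [association_config()] used for both halves.
#' @param n_permutations QAP permutations (default 5000).
#' @param seed Integer seed (used for both the split and the QAP
#'   permutations).
#' @param convention Adjacency convention, `"lift_weighted"` or
#'   `"binary"`.
#' @return A `qap_result` with additional fields `half_sizes` and
#'   `matrix_convention`.
#' @export
split_half_qap <- function(m, cfg = association_config(),
                           n_permutations = 5000L, seed = 42L,
                           convention = c("lift_weighted", "binary")) {
  convention <- match.arg(convention)
  halves <- split_half(m, seed = seed)
  a <- corpus_adjacency(halves[[1]], cfg, convention)
  b <- corpus_adjacency(halves[[2]], cfg, convention)
  out <- qap_correlation(a, b, n_permutations = n_permutations, seed = seed)
  out$half_sizes <- c(n_texts(halves[[1]]), n_texts(halves[[2]]))
  out$matrix_convention <- convention
  out
}

#' Stratified cross-group reliability
#'
#' Partitions the corpus groups (e.g. video threads) into high- and
#' low-activity strata by group size, builds one filtered network per
#' stratum on the union node set, and reports their QAP correlation.
#' Partition rules: `"median"` (groups at or above the median size are
#' high), `"pareto"` (top 20% of groups by size), `"quartile"` (top 25%).
#'
#' @param m A `label_matrix` with `group_id` on every record.
#' @param rule Partition rule.
#' @param cfg [association_config()] for both strata.
#' @param n_permutations QAP permutations (default 5000).
#' @param seed Integer seed.
#' @param convention Adjacency convention.
#' @return A `qap_result` with additional fields `rule` and
#'   `stratum_sizes`.
#' @export
stratified_qap <- function(m, rule = c("median", "pareto", "quartile"),
                           cfg = association_config(),
                           n_permutations = 5000L, seed = 1L,
                           convention = c("lift_weighted", "binary")) {
  rule <- match.arg(rule)
  convention <- match.arg(convention)
  if (is.null(m$group_id)) stop("stratified_qap requires group_id on every record")
  sizes <- table(m$group_id)
  cut <- switch(rule,
                median = stats::median(sizes),
                pareto = stats::quantile(sizes, 0.80, type = 7),
                quartile = stats::quantile(sizes, 0.75, type = 7))
  high_groups <- names(sizes)[sizes >= cut]
  is_high <- as.character(m$group_id) %in% high_groups
  if (!any(is_high) || all(is_high)) stop("both strata must be non-empty")
  high <- subset_rows(m, is_high)
  low <- subset_rows(m, !is_high)
  if (sum(label_marginals(high)) == 0L || sum(label_marginals(low)) == 0L) {
    stop("a stratum contains no labels")
  }
  a <- corpus_adjacency(high, cfg, convention)
  b <- corpus_adjacency(low, cfg, convention)
  out <- qap_correlation(a, b, n_permutations = n_permutations, seed = seed)
  out$rule <- rule
  out$stratum_sizes <- c(high = n_texts(high), low = n_texts(low))
  out$matrix_convention <- convention
  out
}
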