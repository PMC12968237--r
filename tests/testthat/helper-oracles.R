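# Brute-force oracles, independent of the package's vectorized paths.

letter_taxonomy <- function(d) {
  stopifnot(d <= 26)
  LETTERS[seq_len(d)]
}

# random binary label matrix with letter taxonomy
rand_lm <- function(n, d, p = 0.3, seed = NULL) {
  draw <- function() {
    label_matrix(matrix(rbinom(n * d, 1, p), nrow = n,
                        dimnames = list(NULL, letter_taxonomy(d))))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# label matrix from a list of per-text label index sets
lm_from_sets <- function(sets, d) {
  inc <- matrix(0L, nrow = length(sets), ncol = d,
                dimnames = list(NULL, letter_taxonomy(d)))
  for (i in seq_along(sets)) inc[i, sets[[i]]] <- 1L
  label_matrix(inc)
}

# pairwise observed/expected/lift by direct per-text loops
oracle_pairs <- function(inc) {
  d <- ncol(inc); n <- nrow(inc)
  out <- NULL
  for (i in 1:(d - 1)) for (j in (i + 1):d) {
    o <- sum(inc[, i] == 1 & inc[, j] == 1)
    ni <- sum(inc[, i]); nj <- sum(inc[, j])
    e <- ni * nj / n
    out <- rbind(out, data.frame(
      i = i, j = j, observed = o, expected = e,
      lift = if (e > 0) o / e else NA_real_))
  }
  out
}

# chi-square via stats::chisq.test on the explicit 2x2 table
oracle_chi2 <- function(inc, i, j) {
  tab <- table(factor(inc[, i], levels = c(1, 0)),
               factor(inc[, j], levels = c(1, 0)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(chi2 = 0, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2 = unname(ct$statistic), p = unname(ct$p.value))
}

# triadic statistics by per-text enumeration
oracle_triads <- function(inc) {
  d <- ncol(inc); n <- nrow(inc)
  combs <- utils::combn(d, 3)
  key <- apply(combs, 2, paste, collapse = "-")
  cnt <- stats::setNames(numeric(ncol(combs)), key)
  for (t in seq_len(n)) {
    labs <- which(inc[t, ] == 1)
    if (length(labs) >= 3) {
      for (kk in utils::combn(labs, 3, simplify = FALSE)) {
        id <- paste(kk, collapse = "-")
        cnt[id] <- cnt[id] + 1
      }
    }
  }
  pair_o <- function(a, b) sum(inc[, a] == 1 & inc[, b] == 1)
  marg <- colSums(inc)
  res <- NULL
  for (c_idx in seq_len(ncol(combs))) {
    ii <- combs[1, c_idx]; jj <- combs[2, c_idx]; kk <- combs[3, c_idx]
    ct <- cnt[c_idx]
    conds <- c(
      if (pair_o(jj, kk) > 0) ct / pair_o(jj, kk) else 0,
      if (pair_o(ii, kk) > 0) ct / pair_o(ii, kk) else 0,
      if (pair_o(ii, jj) > 0) ct / pair_o(ii, jj) else 0)
    p_avg <- mean(conds)
    expct <- n * (marg[ii] / n) * (marg[jj] / n) * (marg[kk] / n)
    oer <- if (expct > 0) ct / expct else 0
    f_rel <- ct / n
    ism <- f_rel * p_avg * oer
    if (ct == 0) { f_rel <- 0; p_avg <- 0; oer <- 0; ism <- 0 }
    res <- rbind(res, data.frame(i = ii, j = jj, k = kk, count = ct,
                                 f_rel = f_rel, p_avg = p_avg,
                                 oer = oer, ism = ism))
  }
  res
}

# graph oracles on a symmetric weight matrix (0 = no edge)

oracle_density <- function(adj) {
  n <- nrow(adj)
  sum(adj[upper.tri(adj)] > 0) / choose(n, 2)
}

oracle_local_clustering <- function(adj) {
  n <- nrow(adj)
  a <- adj > 0
  vapply(seq_len(n), function(v) {
    nb <- which(a[v, ])
    if (length(nb) < 2) return(0)
    links <- sum(a[nb, nb, drop = FALSE][upper.tri(a[nb, nb, drop = FALSE])])
    links / choose(length(nb), 2)
  }, numeric(1))
}

# betweenness by exhaustive simple-path enumeration (tiny graphs only):
# distance of an edge is 1/weight, shortest paths found among all simple
# paths, normalized by (n-1)(n-2)/2
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    paths <- list()
    recurse <- function(path, len) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- list(path = path, len = len)
        return()
      }
      for (u in which(adj[v, ] > 0)) {
        if (!(u %in% path)) recurse(c(path, u), len + 1 / adj[v, u])
      }
    }
    recurse(s, 0)
    paths
  }
  btw <- numeric(n)
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    paths <- all_paths(s, t)
    if (length(paths) == 0) next
    lens <- vapply(paths, `[[`, numeric(1), "len")
    shortest <- paths[lens <= min(lens) + 1e-12]
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      on_v <- sum(vapply(shortest, function(p) v %in% p$path, logical(1)))
      btw[v] <- btw[v] + on_v / length(shortest)
    }
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw
}

# network object from a weight matrix, via the package's builder
net_from_adj <- function(adj) {
  n <- nrow(adj)
  labs <- letter_taxonomy(n)
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  pairs <- data.frame(label_i = labs[idx[, 1]], label_j = labs[idx[, 2]],
                      lift = adj[cbind(idx[, 1], idx[, 2])],
                      observed = 1L, p_value = 0)
  build_network(pairs, isolate_policy = "keep", nodes = labs)
}

# random symmetric weight matrix
rand_adj <- function(n, p_edge = 0.5, weighted = TRUE) {
  adj <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p_edge) {
      w <- if (weighted) runif(1, 0.5, 3) else 1
      adj[i, j] <- w; adj[j, i] <- w
    }
  }
  adj
}
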