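#' Jaccard similarity of two node sets
#'
#' `|a intersect b| / |a union b|`; two empty sets are identical by
#' convention and return 1.
#'
#' @param a,b Character vectors (sets; duplicates ignored).
#' @return Numeric in `[0, 1]`.
#' @export
jaccard_similarity <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(1)
  length(intersect(a, b)) / u
}

#' Misclassification noise-robustness sweep
#'
#' The reference network and its top-5 hubs are computed once from the
#' unperturbed corpus. For every noise level and replicate, noise is
#' injected ([inject_noise()]), the network is rebuilt under the
#' two-criterion filter (count >= 1, lift > 1), and density, average
#' clustering and the hub Jaccard similarity against the reference hubs
#' are recorded. All networks in the sweep are built on the fixed
#' taxonomy node set, so density changes across noise levels reflect
#' edge gain and loss rather than node-set churn. Replicate seeds are
#' derived as `seed + (level_index - 1) * 1000 + replicate_index`, so
#' any single cell of the design is reproducible in isolation.
#'
#' By default the reference network uses the same filter as the noisy
#' reconstructions, so the zero-noise level reproduces the reference
#' exactly (hub Jaccard 1, zero density deviation); pass a different
#' `reference_cfg` (e.g. with the significance filter on) for an
#' asymmetric design.
#'
#' @param m A non-empty `label_matrix`.
#' @param levels Noise levels (default 0 to 0.5 in steps of 0.05).
#' @param replicates Replicates per level (default 50).
#' @param cfg [association_config()] for the noisy reconstructions
#'   (default: significance filter OFF).
#' @param seed Master integer seed.
#' @param reference_cfg Filter for the reference network (default `cfg`).
#' @param fn_fraction Fraction of erroneous cells realized as deletions
#'   (passed to [noise_spec()]).
#' @return List of class `noise_sweep_result`: `levels`,
#'   `replicates_per_level`, `summary` (data frame with per-level mean/sd
#'   of density, clustering and hub Jaccard, and the regime), `replicates`
#'   (per-replicate data frame), `reference_hubs`, `seed`.
#' @export
noise_sweep <- function(m, levels = seq(0, 0.5, by = 0.05),
                        replicates = 50L,
                        cfg = association_config(apply_significance_filter = FALSE),
                        seed = 1L, reference_cfg = cfg, fn_fraction = 0.5) {
  if (n_texts(m) == 0L) stop("noise_sweep requires a non-empty matrix")
  if (any(levels < 0 | levels > 0.5)) stop("noise levels must lie in [0, 0.5]")
  ref_edges <- filter_edges(pair_stats(m, reference_cfg$continuity_correction),
                            reference_cfg)
  ref_net <- build_network(ref_edges, isolate_policy = "keep",
                           nodes = m$taxonomy, validate = FALSE)
  ref_hubs <- top_hubs(ref_net, 5L)

  inc <- m$incidence
  n <- nrow(inc)
  rows <- vector("list", length(levels) * replicates)
  r <- 0L
  for (li in seq_along(levels)) {
    eps <- levels[li]
    for (ri in seq_len(replicates)) {
      rep_seed <- as.integer(seed + (li - 1L) * 1000L + ri)
      noisy <- inject_noise(m, noise_spec(eps, seed = rep_seed,
                                          fn_fraction = fn_fraction))
      tab <- pair_table(noisy$incidence, cfg$continuity_correction)
      attr(tab, "n_total") <- n
      edges <- filter_edges(tab, cfg)
      net <- build_network(edges, isolate_policy = "keep",
                           nodes = m$taxonomy, validate = FALSE)
      topo <- network_topology(net)
      r <- r + 1L
      rows[[r]] <- data.frame(
        level = eps, replicate = ri, seed = rep_seed,
        density = topo$density, avg_clustering = topo$avg_clustering,
        hub_jaccard = jaccard_similarity(top_hubs(net, 5L), ref_hubs),
        n_nodes = igraph::vcount(net$graph),
        n_edges = igraph::ecount(net$graph)
      )
    }
  }
  reps <- do.call(rbind, rows)
  agg <- function(f, col) {
    vapply(levels, function(l) f(reps[[col]][reps$level == l]), numeric(1))
  }
  mean_na <- function(x) mean(x, na.rm = TRUE)
  sd_na <- function(x) stats::sd(x, na.rm = TRUE)
  summary_df <- data.frame(
    level = levels,
    mean_density = agg(mean_na, "density"),
    sd_density = agg(sd_na, "density"),
    mean_clustering = agg(mean_na, "avg_clustering"),
    sd_clustering = agg(sd_na, "avg_clustering"),
    mean_hub_jaccard = agg(mean_na, "hub_jaccard"),
    sd_hub_jaccard = agg(sd_na, "hub_jaccard")
  )
  out <- structure(
    list(levels = levels, replicates_per_level = as.integer(replicates),
         summary = summary_df, replicates = reps,
         reference_hubs = ref_hubs, seed = as.integer(seed)),
    class = "noise_sweep_result"
  )
  classify_regimes(out)
}

#' Classify per-level stability regimes
#'
#' From the mean hub Jaccard at each noise level: `stable` when
#' >= 0.95, `degrading` when >= 0.60, `collapse` below 0.60. The 0.60
#' boundary is the hub-stability threshold; the 0.95 boundary
#' operationalizes the "perfectly preserved" regime.
#'
#' @param result A `noise_sweep_result`.
#' @return The result with a `regime` column filled in `summary`.
#' @export
classify_regimes <- function(result) {
  j <- result$summary$mean_hub_jaccard
  result$summary$regime <- ifelse(j >= 0.95, "stable",
                                  ifelse(j >= 0.60, "degrading", "collapse"))
  result
}

#' @export
print.noise_sweep_result <- function(x, ...) {
  cat(sprintf("Noise sweep: %d levels x %d replicates (seed %d)\n",
              length(x$levels), x$replicates_per_level, x$seed))
  print(cbind(x$summary[c("level", "mean_density", "mean_clustering",
                          "mean_hub_jaccard", "regime")]), row.names = FALSE)
  invisible(x)
}
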