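#' Bootstrap node-stability analysis
#'
#' Resamples the corpus rows with replacement `k` times; each iteration
#' recomputes the pairwise statistics, filters edges with `cfg`
#' (two-criterion rule by default: count >= 1, lift > 1, no significance
#' filter), and rebuilds the network with the isolate-drop policy. A node
#' "appears" in an iteration iff it retains at least one surviving edge.
#' Density and average clustering are recorded per iteration and
#' summarized as 2.5/97.5 percentile confidence intervals. Nodes are
#' classified by the dual-threshold rule: core if appearance >= 0.95,
#' exploratory if >= 0.60, excluded otherwise.
#'
#' @param m A non-empty `label_matrix`.
#' @param k Number of bootstrap iterations (>= 1; default 10000).
#' @param cfg [association_config()] used for edge filtering in each
#'   resample; default has the significance filter OFF.
#' @param seed Integer seed; the run is deterministic given it.
#' @return List of class `stability_report`: `k_iterations`, `appearance`
#'   (named proportions), `node_class` (named factor levels core /
#'   exploratory / excluded), `density_ci`, `clustering_ci`,
#'   `density_point`, `clustering_point` (full-data network values under
#'   the same filter, `NA` when that network has < 2 nodes), `seed`, plus
#'   the per-iteration `densities` and `clusterings` vectors.
#' @export
bootstrap_stability <- function(m, k = 10000L,
                                cfg = association_config(apply_significance_filter = FALSE),
                                seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (n_texts(m) == 0L) stop("bootstrap requires a non-empty matrix")
  inc <- m$incidence
  n <- nrow(inc)
  labels <- m$taxonomy
  appear <- stats::setNames(numeric(length(labels)), labels)
  densities <- rep(NA_real_, k)
  clusterings <- rep(NA_real_, k)

  withr::with_seed(seed, {
    for (it in seq_len(k)) {
      idx <- sample.int(n, n, replace = TRUE)
      tab <- pair_table(inc[idx, , drop = FALSE], cfg$continuity_correction)
      attr(tab, "n_total") <- n
      edges <- filter_edges(tab, cfg)
      present <- unique(c(edges$label_i, edges$label_j))
      appear[present] <- appear[present] + 1
      if (length(present) >= 2L) {
        net <- build_network(edges, isolate_policy = "drop", validate = FALSE)
        topo <- network_topology(net)
        densities[it] <- topo$density
        clusterings[it] <- topo$avg_clustering
      }
    }
  })

  appear <- appear / k
  full_edges <- filter_edges(pair_stats(m, cfg$continuity_correction), cfg)
  full_net <- build_network(full_edges, isolate_policy = "drop", validate = FALSE)
  point <- if (igraph::vcount(full_net$graph) >= 2L) {
    network_topology(full_net)
  } else {
    list(density = NA_real_, avg_clustering = NA_real_)
  }
  ci <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(c(lower = NA_real_, upper = NA_real_))
    stats::setNames(as.numeric(stats::quantile(x, c(0.025, 0.975), type = 7)),
                    c("lower", "upper"))
  }
  report <- structure(
    list(k_iterations = as.integer(k), appearance = appear,
         node_class = NULL,
         density_ci = ci(densities), clustering_ci = ci(clusterings),
         density_point = point$density, clustering_point = point$avg_clustering,
         densities = densities, clusterings = clusterings,
         seed = as.integer(seed)),
    class = "stability_report"
  )
  report <- classify_nodes(report)
  for (metric in c("density", "clustering")) {
    pt <- report[[paste0(metric, "_point")]]
    bounds <- report[[paste0(metric, "_ci")]]
    if (!is.na(pt) && !anyNA(bounds) && (pt < bounds[1] || pt > bounds[2])) {
      warning(sprintf("full-data %s (%.4f) lies outside its bootstrap CI [%.4f, %.4f]",
                      metric, pt, bounds[1], bounds[2]))
    }
  }
  report
}

#' Classify nodes by the dual-threshold stability rule
#'
#' Core if bootstrap appearance >= 0.95, exploratory if >= 0.60 and
#' < 0.95, excluded below 0.60 (boundaries inclusive on the lower side).
#'
#' @param report A `stability_report` with appearances computed.
#' @return The report with `node_class` filled.
#' @export
classify_nodes <- function(report) {
  a <- report$appearance
  cls <- ifelse(a >= 0.95, "core", ifelse(a >= 0.60, "exploratory", "excluded"))
  report$node_class <- stats::setNames(cls, names(a))
  report
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap stability over %d iterations (seed %d)\n",
              x$k_iterations, x$seed))
  tab <- data.frame(appearance = round(x$appearance, 4),
                    class = x$node_class)
  print(tab[order(-tab$appearance), ])
  cat(sprintf("density %.3f CI [%.3f, %.3f]; clustering %.3f CI [%.3f, %.3f]\n",
              x$density_point, x$density_ci[1], x$density_ci[2],
              x$clustering_point, x$clustering_ci[1], x$clustering_ci[2]))
  invisible(x)
}
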