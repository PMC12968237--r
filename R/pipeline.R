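#' Full-pipeline configuration
#'
#' Bundles every stage's parameters and seeds. Exactly one of `input` (a
#' path readable by [read_label_matrix()]) or `synthetic` (a
#' [synthetic_config()]) supplies the corpus. All randomness flows from
#' the explicit per-stage seeds; no stage reads a global generator.
#'
#' @param input Optional corpus file path.
#' @param input_format `"csv"` or `"jsonl"`.
#' @param synthetic Optional [synthetic_config()].
#' @param taxonomy Label names.
#' @param min_chars Length-filter threshold applied when records carry
#'   `length_chars` (default 200; `NULL` disables).
#' @param association [association_config()] for the headline network.
#' @param triad_percentile ISM percentile threshold (default 99).
#' @param triad_cutoff Optional explicit ISM cutoff overriding the
#'   percentile.
#' @param bootstrap_k Bootstrap iterations (default 10000).
#' @param bootstrap_seed Seed for the bootstrap.
#' @param resample_association [association_config()] for bootstrap and
#'   noise reconstructions (default: significance filter OFF).
#' @param qap_permutations QAP permutations (default 5000).
#' @param qap_seed Seed for split-half and QAP.
#' @param noise_levels Noise sweep levels (default 0 to 0.5 step 0.05).
#' @param noise_replicates Replicates per noise level (default 50).
#' @param noise_seed Master seed for the sweep.
#' @param stratified_rule Optional stratification rule (`"median"`,
#'   `"pareto"`, `"quartile"`) applied when the corpus carries group ids;
#'   `NULL` skips the stratified analysis.
#' @param out_dir Optional directory for per-stage artifacts.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, input_format = "csv",
                            synthetic = NULL,
                            taxonomy = default_taxonomy(),
                            min_chars = 200L,
                            association = association_config(),
                            triad_percentile = 99,
                            triad_cutoff = NULL,
                            bootstrap_k = 10000L,
                            bootstrap_seed = 1L,
                            resample_association = association_config(apply_significance_filter = FALSE),
                            qap_permutations = 5000L,
                            qap_seed = 42L,
                            noise_levels = seq(0, 0.5, by = 0.05),
                            noise_replicates = 50L,
                            noise_seed = 1L,
                            stratified_rule = NULL,
                            out_dir = NULL) {
  if (is.null(input) == is.null(synthetic)) {
    stop("exactly one of input or synthetic must be supplied")
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `synthetic` and `association` / `resample_association` are nested
#' maps passed to their constructors.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  taxonomy <- if (!is.null(y$taxonomy)) y$taxonomy else default_taxonomy()
  mk_assoc <- function(spec, default) {
    if (is.null(spec)) return(default)
    do.call(association_config, spec)
  }
  synth <- NULL
  if (!is.null(y$synthetic)) {
    s <- y$synthetic
    if (!is.null(s$count_distribution)) {
      s$count_distribution <- unlist(s$count_distribution)
    }
    if (!is.null(s$prevalences)) s$prevalences <- unlist(s$prevalences)
    s$taxonomy <- taxonomy
    synth <- do.call(synthetic_config, s)
  }
  args <- list(
    input = y$input, input_format = if (!is.null(y$input_format)) y$input_format else "csv",
    synthetic = synth, taxonomy = taxonomy,
    association = mk_assoc(y$association, association_config()),
    resample_association = mk_assoc(
      y$resample_association,
      association_config(apply_significance_filter = FALSE))
  )
  for (key in c("min_chars", "triad_percentile", "triad_cutoff", "bootstrap_k",
                "bootstrap_seed", "qap_permutations", "qap_seed",
                "noise_levels", "noise_replicates", "noise_seed",
                "stratified_rule", "out_dir")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(args$noise_levels)) {
    args$noise_levels <- as.numeric(unlist(args$noise_levels))
  }
  do.call(pipeline_config, args)
}

run_stage <- function(name, log, expr) {
  t0 <- proc.time()[["elapsed"]]
  result <- tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
  if (log) message(sprintf("[distortnet] stage %-12s %.2fs", name,
                           proc.time()[["elapsed"]] - t0))
  result
}

#' Run the full analysis pipeline
#'
#' Corpus (loaded or generated) -> corpus filters and count summary ->
#' pairwise association table and filtered edges -> triadic ISM table and
#' threshold -> network with topology, centralities and hubs -> bootstrap
#' node stability -> split-half QAP reliability (plus stratified QAP when
#' groups exist and a rule is configured) -> noise-robustness sweep. Any
#' stage failure aborts with the stage name; artifacts of completed
#' stages are retained in `out_dir` when set.
#'
#' @param cfg A [pipeline_config()].
#' @param log Emit per-stage timing messages (default `TRUE`).
#' @return List of class `pipeline_report` with elements `corpus_summary`,
#'   `count_summary`, `pairs`, `edges`, `triads`, `triad_threshold`,
#'   `network`, `topology`, `centralities`, `hubs`, `stability`, `qap`,
#'   `stratified_qap` (or `NULL`), `noise`, and `seeds`.
#' @export
run_pipeline <- function(cfg, log = TRUE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  save_json <- function(x, name) {
    if (!is.null(out_dir)) {
      jsonlite::write_json(x, file.path(out_dir, paste0(name, ".json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows",
                           force = TRUE)
    }
  }

  corpus <- run_stage("corpus", log, {
    if (!is.null(cfg$input)) {
      read_label_matrix(cfg$input, cfg$input_format, cfg$taxonomy)
    } else {
      generate_corpus(cfg$synthetic)
    }
  })
  corpus <- run_stage("filters", log, {
    m <- corpus
    if (!is.null(cfg$min_chars) && !is.null(m$length_chars)) {
      m <- filter_min_length(m, cfg$min_chars)
    }
    drop_unlabeled(m)
  })
  counts <- run_stage("counts", log, summarize_counts(corpus))

  pairs <- run_stage("pairs", log,
                     pair_stats(corpus, cfg$association$continuity_correction))
  edges <- run_stage("edge_filter", log, filter_edges(pairs, cfg$association))
  save_json(pairs, "pairs")

  triads <- run_stage("triads", log, triad_stats(corpus))
  tri_thr <- run_stage("triad_threshold", log,
                       threshold_triads(triads, cfg$triad_percentile,
                                        cfg$triad_cutoff))
  save_json(tri_thr$significant_triads, "significant_triads")

  network <- run_stage("network", log,
                       build_network(edges, isolate_policy = "drop"))
  degenerate <- igraph::vcount(network$graph) < 2L
  topo <- run_stage("topology", log, {
    if (degenerate) {
      list(n_nodes = igraph::vcount(network$graph), n_edges = 0L,
           density = NA_real_, avg_clustering = NA_real_,
           global_transitivity = NA_real_, assortativity = NA_real_)
    } else network_topology(network)
  })
  centr <- run_stage("centralities", log, {
    if (degenerate) NULL else node_centralities(network)
  })
  hubs <- if (degenerate) character(0) else top_hubs(centr, 5L)
  if (!is.null(out_dir)) {
    write_network(network, file.path(out_dir, "network.graphml"), "graphml")
    write_network(network, file.path(out_dir, "network_edges.csv"), "edge_csv")
  }

  stability <- run_stage("bootstrap", log,
                         bootstrap_stability(corpus, k = cfg$bootstrap_k,
                                             cfg = cfg$resample_association,
                                             seed = cfg$bootstrap_seed))
  qap <- run_stage("split_half_qap", log,
                   split_half_qap(corpus, cfg = cfg$resample_association,
                                  n_permutations = cfg$qap_permutations,
                                  seed = cfg$qap_seed))
  strat <- NULL
  if (!is.null(cfg$stratified_rule) && !is.null(corpus$group_id)) {
    strat <- run_stage("stratified_qap", log,
                       stratified_qap(corpus, rule = cfg$stratified_rule,
                                      cfg = cfg$resample_association,
                                      n_permutations = cfg$qap_permutations,
                                      seed = cfg$qap_seed))
  }
  noise <- run_stage("noise_sweep", log,
                     noise_sweep(corpus, levels = cfg$noise_levels,
                                 replicates = cfg$noise_replicates,
                                 cfg = cfg$resample_association,
                                 seed = cfg$noise_seed))

  report <- structure(
    list(
      corpus_summary = list(n_texts = n_texts(corpus),
                            n_labels = n_labels(corpus),
                            marginals = as.list(label_marginals(corpus))),
      count_summary = unclass(counts),
      pairs = pairs, edges = edges,
      triads = triads, triad_threshold = list(
        percentile = tri_thr$percentile,
        cutoff_value = tri_thr$cutoff_value,
        n_significant = nrow(tri_thr$significant_triads),
        significant_triads = tri_thr$significant_triads),
      network = network, topology = unclass(topo),
      centralities = centr, hubs = hubs,
      stability = list(k_iterations = stability$k_iterations,
                       appearance = as.list(stability$appearance),
                       node_class = as.list(stability$node_class),
                       density_ci = stability$density_ci,
                       clustering_ci = stability$clustering_ci,
                       density_point = stability$density_point,
                       clustering_point = stability$clustering_point,
                       seed = stability$seed),
      qap = list(r_observed = qap$r_observed, p_value = qap$p_value,
                 n_permutations = qap$n_permutations,
                 half_sizes = qap$half_sizes, seed = qap$seed),
      stratified_qap = if (!is.null(strat)) {
        list(r_observed = strat$r_observed, p_value = strat$p_value,
             rule = strat$rule, stratum_sizes = as.list(strat$stratum_sizes))
      },
      noise = list(levels = noise$levels,
                   replicates_per_level = noise$replicates_per_level,
                   summary = noise$summary,
                   reference_hubs = noise$reference_hubs,
                   seed = noise$seed),
      seeds = list(bootstrap = cfg$bootstrap_seed, qap = cfg$qap_seed,
                   noise = cfg$noise_seed,
                   synthetic = if (!is.null(cfg$synthetic)) cfg$synthetic$seed)
    ),
    class = "pipeline_report"
  )
  if (!is.null(out_dir)) {
    serializable <- report
    serializable$network <- list(nodes = network_nodes(network),
                                 edges = network_edges(network))
    jsonlite::write_json(lapply(serializable, unclass),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         force = TRUE)
  }
  report
}
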