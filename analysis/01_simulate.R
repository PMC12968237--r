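#!/usr/bin/env Rscript
# Generate the two synthetic corpora the downstream analyses use:
#  - a study-scale corpus (N = 249,414) matching the marginal structure of
#    the naturalistic distortion corpus (mean 1.78 labels/text, 82.3% of
#    texts with 1-2 labels, top prevalence ~15.5%, planted top pair and
#    triad), with thread ids for the stratified analysis;
#  - a 20,000-text planted-structure corpus (hub-and-periphery core) for
#    the resampling and noise analyses.
# Writes CSVs under results/corpora/ plus a JSON of descriptive statistics.

suppressPackageStartupMessages(library(distortnet))

out_dir <- "results/corpora"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
seed <- 20260922L

message("generating study-scale corpus (N = 249,414)...")
study <- generate_corpus(synthetic_config(249414, seed = seed,
                                          group_count = 2000))
write_label_matrix(study, file.path(out_dir, "study_scale.csv"), "csv")

message("generating planted-structure corpus (N = 20,000)...")
planted <- generate_corpus(planted_structure_config(20000, seed = seed + 1L))
write_label_matrix(planted, file.path(out_dir, "planted_structure.csv"), "csv")

s <- summarize_counts(study)
desc <- list(
  n_texts = n_texts(study),
  mean_labels_per_text = s$mean_per_text,
  bucket_proportions = as.list(s$proportion_by_bucket),
  skewness = s$skewness,
  skewness_p = s$skewness_p,
  top_label_prevalence = max(label_marginals(study)) / n_texts(study),
  length_chars_summary = as.list(summary(as.numeric(study$length_chars)))
)
jsonlite::write_json(desc, file.path(out_dir, "descriptives.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf(
  "study corpus: mean %.3f labels/text, skewness %.2f, top prevalence %.1f%%",
  s$mean_per_text, s$skewness,
  100 * max(label_marginals(study)) / n_texts(study)))
message(sprintf("bucket proportions: 1-2: %.1f%%, 3: %.1f%%, 4+: %.1f%%",
                100 * s$proportion_by_bucket[["1-2"]],
                100 * s$proportion_by_bucket[["3"]],
                100 * s$proportion_by_bucket[["4+"]]))
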