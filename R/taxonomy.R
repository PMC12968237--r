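#' Canonical cognitive-distortion taxonomy
#'
#' The 18 cognitive distortion categories from established CBT frameworks,
#' in canonical order. Every analysis in this package is defined over a
#' taxonomy; this is the default one.
#'
#' @return Character vector of 18 label names.
#' @export
#' @examples
#' default_taxonomy()
default_taxonomy <- function() {
  c(
    "All-or-Nothing Thinking",
    "Overgeneralization",
    "Mental Filter",
    "Disqualifying the Positive",
    "Fortune Telling",
    "Mind Reading",
    "Catastrophizing",
    "Emotional Reasoning",
    "Should Statements",
    "Labeling",
    "Personalization",
    "External Locus of Control",
    "Tunnel Vision",
    "Social Comparison",
    "Rationalization",
    "Rumination",
    "Learned Helplessness",
    "Fairness Fallacy"
  )
}

validate_taxonomy <- function(labels) {
  labels <- trimws(as.character(labels))
  if (length(labels) < 1L) stop("taxonomy must contain at least one label")
  if (anyDuplicated(labels)) stop("taxonomy labels must be unique")
  if (any(!nzchar(labels))) stop("taxonomy labels must be non-empty strings")
  labels
}

#' Construct a label matrix
#'
#' The universal container of the pipeline: a binary text x label incidence
#' matrix plus optional per-text metadata (id, character length, group id).
#'
#' @param incidence Numeric/integer/logical matrix of 0/1 values, one row per
#'   text, one column per taxonomy label. Column names, if present, must match
#'   `taxonomy`.
#' @param taxonomy Character vector of label names (default: column names of
#'   `incidence`, else [default_taxonomy()]).
#' @param text_id Optional vector of per-text identifiers.
#' @param length_chars Optional non-negative integer vector of character
#'   counts per text.
#' @param group_id Optional vector of per-text group (e.g. thread) ids.
#' @return An object of class `label_matrix`.
#' @export
label_matrix <- function(incidence, taxonomy = NULL, text_id = NULL,
                         length_chars = NULL, group_id = NULL) {
  incidence <- as.matrix(incidence)
  if (is.logical(incidence)) storage.mode(incidence) <- "integer"
  if (is.null(taxonomy)) {
    taxonomy <- if (!is.null(colnames(incidence))) colnames(incidence) else default_taxonomy()
  }
  taxonomy <- validate_taxonomy(taxonomy)
  if (ncol(incidence) != length(taxonomy)) {
    stop(sprintf("incidence has %d columns but taxonomy has %d labels",
                 ncol(incidence), length(taxonomy)))
  }
  bad <- which(!(incidence == 0 | incidence == 1), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-binary incidence value %s at row %d, column '%s'",
                 format(incidence[bad[1, 1], bad[1, 2]]),
                 bad[1, 1], taxonomy[bad[1, 2]]))
  }
  storage.mode(incidence) <- "integer"
  colnames(incidence) <- taxonomy
  rownames(incidence) <- NULL
  n <- nrow(incidence)
  check_meta <- function(x, name) {
    if (is.null(x)) return(NULL)
    if (length(x) != n) stop(sprintf("%s must have one entry per text", name))
    x
  }
  length_chars <- check_meta(length_chars, "length_chars")
  if (!is.null(length_chars)) {
    length_chars <- as.integer(length_chars)
    if (any(is.na(length_chars)) || any(length_chars < 0L)) {
      stop("length_chars must be non-negative integers")
    }
  }
  structure(
    list(
      incidence = incidence,
      taxonomy = taxonomy,
      text_id = check_meta(text_id, "text_id"),
      length_chars = length_chars,
      group_id = check_meta(group_id, "group_id")
    ),
    class = "label_matrix"
  )
}

#' @export
print.label_matrix <- function(x, ...) {
  cat(sprintf("<label_matrix> %d texts x %d labels, %d positive cells\n",
              n_texts(x), n_labels(x), sum(x$incidence)))
  invisible(x)
}

#' Number of texts in a label matrix
#' @param m A `label_matrix`.
#' @return Integer row count.
#' @export
n_texts <- function(m) nrow(m$incidence)

#' Number of taxonomy labels in a label matrix
#' @param m A `label_matrix`.
#' @return Integer column count.
#' @export
n_labels <- function(m) ncol(m$incidence)

#' Per-label marginal counts
#' @param m A `label_matrix`.
#' @return Named integer vector: number of texts containing each label.
#' @export
label_marginals <- function(m) colSums(m$incidence)

#' Per-text label counts
#' @param m A `label_matrix`.
#' @return Integer vector of labels per text.
#' @export
label_counts <- function(m) rowSums(m$incidence)

subset_rows <- function(m, keep) {
  label_matrix(
    m$incidence[keep, , drop = FALSE],
    taxonomy = m$taxonomy,
    text_id = if (!is.null(m$text_id)) m$text_id[keep],
    length_chars = if (!is.null(m$length_chars)) m$length_chars[keep],
    group_id = if (!is.null(m$group_id)) m$group_id[keep]
  )
}

#' Concatenate label matrices
#'
#' Row-binds two or more label matrices sharing the same taxonomy. Metadata
#' fields present in all inputs are concatenated; fields missing from any
#' input are dropped.
#'
#' @param ... `label_matrix` objects with identical taxonomies.
#' @param deparse.level Unused (S3 signature compatibility).
#' @return A `label_matrix`.
#' @export
rbind.label_matrix <- function(..., deparse.level = 1) {
  ms <- list(...)
  tax <- ms[[1]]$taxonomy
  for (m in ms) {
    if (!identical(m$taxonomy, tax)) stop("taxonomies differ; cannot rbind")
  }
  cat_field <- function(field) {
    if (any(vapply(ms, function(m) is.null(m[[field]]), logical(1)))) return(NULL)
    do.call(c, lapply(ms, `[[`, field))
  }
  label_matrix(
    do.call(rbind, lapply(ms, `[[`, "incidence")),
    taxonomy = tax,
    text_id = cat_field("text_id"),
    length_chars = cat_field("length_chars"),
    group_id = cat_field("group_id")
  )
}

#' Exclude texts shorter than a character threshold
#'
#' Applies the corpus length constraint: texts shorter than `min_chars`
#' characters are excluded; texts of exactly `min_chars` characters are kept.
#'
#' @param m A `label_matrix` whose records carry `length_chars`.
#' @param min_chars Minimum character count retained (default 200).
#' @return The filtered `label_matrix`, with attribute `n_removed`.
#' @export
filter_min_length <- function(m, min_chars = 200L) {
  if (is.null(m$length_chars)) {
    stop("filter_min_length requires length_chars on every record")
  }
  keep <- m$length_chars >= min_chars
  out <- subset_rows(m, keep)
  if (n_texts(out) == 0L) warning("length filter removed every text")
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Drop texts with no labels
#'
#' Removes rows whose label set is empty, mirroring the exclusion of texts
#' lacking valid distortion annotations.
#'
#' @param m A `label_matrix`.
#' @return The filtered `label_matrix`, with attribute `removed_fraction`.
#' @export
drop_unlabeled <- function(m) {
  counts <- label_counts(m)
  keep <- counts > 0L
  out <- subset_rows(m, keep)
  if (n_texts(out) == 0L && n_texts(m) > 0L) {
    warning("every text was unlabeled; result is empty")
  }
  attr(out, "removed_fraction") <-
    if (n_texts(m) > 0L) sum(!keep) / n_texts(m) else 0
  out
}

#' Summarize the per-text label-count distribution
#'
#' Reports the mean number of labels per text, the proportion of texts in
#' the count buckets 0, 1-2, 3 and 4+, the sample skewness (adjusted
#' Fisher-Pearson estimator) of the per-text counts, and the p-value of the
#' D'Agostino skewness z-test of the null of zero skewness.
#'
#' @param m A `label_matrix` with at least one text.
#' @return A list of class `count_summary` with fields `n_texts`,
#'   `mean_per_text`, `proportion_by_bucket` (named numeric over
#'   `"0"`, `"1-2"`, `"3"`, `"4+"`), `skewness` and `skewness_p`
#'   (`NA` when `n_texts < 8`, where the test is undefined).
#' @export
summarize_counts <- function(m) {
  counts <- label_counts(m)
  n <- length(counts)
  if (n < 1L) stop("summarize_counts requires at least one text")
  buckets <- c(
    "0"   = mean(counts == 0),
    "1-2" = mean(counts >= 1 & counts <= 2),
    "3"   = mean(counts == 3),
    "4+"  = mean(counts >= 4)
  )
  skew <- if (n >= 3L && stats::sd(counts) > 0) {
    e1071::skewness(counts, type = 2)
  } else NA_real_
  sk_test <- skewness_test(counts)
  structure(
    list(
      n_texts = n,
      mean_per_text = sum(counts) / n,
      proportion_by_bucket = buckets,
      skewness = skew,
      skewness_p = sk_test$p_value,
      skewness_z = sk_test$z
    ),
    class = "count_summary"
  )
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("Label counts over %d texts: mean %.3f, skewness %.3f (p = %s)\n",
              x$n_texts, x$mean_per_text, x$skewness,
              format.pval(x$skewness_p)))
  print(round(x$proportion_by_bucket, 4))
  invisible(x)
}

#' D'Agostino test of sample skewness
#'
#' Transforms the (biased, type-1) sample skewness coefficient to an
#' approximately standard-normal z statistic under the null of a symmetric
#' (normal) population, following D'Agostino's classical approximation.
#' Requires `n >= 8`; below that the approximation is undefined and `NA` is
#' returned.
#'
#' @param x Numeric vector.
#' @return List with `skew_b1` (type-1 skewness), `z`, and two-sided
#'   `p_value`.
#' @export
skewness_test <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 8L || stats::sd(x) == 0) {
    return(list(skew_b1 = NA_real_, z = NA_real_, p_value = NA_real_))
  }
  m2 <- mean((x - mean(x))^2)
  m3 <- mean((x - mean(x))^3)
  b1 <- m3 / m2^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(w2)))
  alpha <- sqrt(2 / (w2 - 1))
  z <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))
  list(skew_b1 = b1, z = z, p_value = 2 * stats::pnorm(-abs(z)))
}
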