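#' Read a label matrix from CSV or JSON-lines
#'
#' CSV input must carry one binary (0/1) column per taxonomy label, plus
#' optional `text_id`, `length_chars` and `group_id` columns; extra columns
#' are preserved on disk but ignored analytically. JSON-lines input carries
#' one object per line with a `labels` array of label names and the same
#' optional metadata fields. Label names are matched case-sensitively after
#' trimming whitespace.
#'
#' @param path Input file path.
#' @param format `"csv"` or `"jsonl"`.
#' @param taxonomy Label names expected (default [default_taxonomy()]).
#' @return A `label_matrix`; row order is preserved.
#' @export
read_label_matrix <- function(path, format = c("csv", "jsonl"),
                              taxonomy = default_taxonomy()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  taxonomy <- validate_taxonomy(taxonomy)
  if (format == "csv") {
    df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
    missing <- setdiff(taxonomy, trimws(names(df)))
    if (length(missing) > 0L) {
      stop(sprintf("missing label column(s): %s", paste(missing, collapse = ", ")))
    }
    names(df) <- trimws(names(df))
    inc <- as.matrix(df[taxonomy])
    if (!is.numeric(inc)) stop("label columns must be numeric 0/1")
    bad <- which(!(inc == 0 | inc == 1), arr.ind = TRUE)
    if (nrow(bad) > 0L) {
      stop(sprintf("non-binary value '%s' in column '%s' at data row %d",
                   format(inc[bad[1, 1], bad[1, 2]]), taxonomy[bad[1, 2]], bad[1, 1]))
    }
    label_matrix(inc, taxonomy = taxonomy,
                 text_id = df[["text_id"]],
                 length_chars = df[["length_chars"]],
                 group_id = df[["group_id"]])
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    recs <- lapply(lines, jsonlite::fromJSON, simplifyVector = TRUE)
    inc <- matrix(0L, nrow = length(recs), ncol = length(taxonomy),
                  dimnames = list(NULL, taxonomy))
    for (i in seq_along(recs)) {
      labs <- trimws(as.character(recs[[i]]$labels))
      idx <- match(labs, taxonomy)
      if (anyNA(idx)) {
        stop(sprintf("unknown label '%s' at line %d", labs[which(is.na(idx))[1]], i))
      }
      inc[i, unique(idx)] <- 1L
    }
    get_field <- function(field) {
      vals <- lapply(recs, function(r) r[[field]])
      if (all(vapply(vals, is.null, logical(1)))) return(NULL)
      unlist(lapply(vals, function(v) if (is.null(v)) NA else v))
    }
    label_matrix(inc, taxonomy = taxonomy,
                 text_id = get_field("text_id"),
                 length_chars = get_field("length_chars"),
                 group_id = get_field("group_id"))
  }
}

#' Write a label matrix to CSV or JSON-lines
#'
#' Inverse of [read_label_matrix()]: a written file read back yields an
#' identical matrix.
#'
#' @param m A `label_matrix`.
#' @param path Output file path.
#' @param format `"csv"` or `"jsonl"`.
#' @return `path`, invisibly.
#' @export
write_label_matrix <- function(m, path, format = c("csv", "jsonl")) {
  format <- match.arg(format)
  if (format == "csv") {
    df <- as.data.frame(m$incidence, check.names = FALSE)
    if (!is.null(m$group_id)) df <- cbind(group_id = m$group_id, df)
    if (!is.null(m$length_chars)) df <- cbind(length_chars = m$length_chars, df)
    if (!is.null(m$text_id)) df <- cbind(text_id = m$text_id, df)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    con <- file(path, open = "w")
    on.exit(close(con))
    for (i in seq_len(n_texts(m))) {
      rec <- list(labels = m$taxonomy[m$incidence[i, ] == 1L])
      if (!is.null(m$text_id)) rec$text_id <- m$text_id[i]
      if (!is.null(m$length_chars)) rec$length_chars <- m$length_chars[i]
      if (!is.null(m$group_id)) rec$group_id <- m$group_id[i]
      writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
    }
  }
  invisible(path)
}

#' Write a distortion network to disk
#'
#' Supported formats: `"graphml"` (via igraph), `"edge_csv"` (columns
#' source, target, lift, count, p_value) and `"json_report"` (nodes plus
#' edge list with attributes). Edge attributes carry the lift weight,
#' observed co-occurrence count and chi-square p-value, so a round-trip
#' read reproduces the graph.
#'
#' @param g A `distortion_network`.
#' @param path Output file path.
#' @param format One of `"graphml"`, `"edge_csv"`, `"json_report"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(g, path, format = c("graphml", "edge_csv", "json_report")) {
  format <- match.arg(format)
  ed <- network_edges(g)
  if (format == "graphml") {
    igraph::write_graph(g$graph, path, format = "graphml")
  } else if (format == "edge_csv") {
    utils::write.csv(
      data.frame(source = ed$label_i, target = ed$label_j,
                 lift = format_full(ed$lift), count = ed$observed,
                 p_value = format_full(ed$p_value)),
      path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(
      list(nodes = network_nodes(g), edges = ed),
      path, auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) NA_character_ else sprintf("%.17g", v)
  }, character(1))
}

#' Read a distortion network written by [write_network()]
#'
#' @param path Input file path.
#' @param format One of `"graphml"`, `"edge_csv"`, `"json_report"`.
#' @return A `distortion_network` (without filter provenance, which is not
#'   serialized).
#' @export
read_network <- function(path, format = c("graphml", "edge_csv", "json_report")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "graphml") {
    gr <- igraph::read_graph(path, format = "graphml")
    # graphml read-back may carry an "id" vertex attribute; name is canonical
    new_distortion_network(gr, config = NULL)
  } else if (format == "edge_csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    pairs <- data.frame(label_i = df$source, label_j = df$target,
                        observed = df$count, lift = as.numeric(df$lift),
                        p_value = as.numeric(df$p_value),
                        stringsAsFactors = FALSE)
    build_network(pairs, validate = FALSE)
  } else {
    rep <- jsonlite::fromJSON(path)
    if (length(rep$edges) == 0L || is.null(nrow(rep$edges)) || nrow(rep$edges) == 0L) {
      pairs <- data.frame(label_i = character(), label_j = character(),
                          observed = integer(), lift = numeric(),
                          p_value = numeric())
    } else {
      pairs <- rep$edges
    }
    build_network(pairs, nodes = rep$nodes, isolate_policy = "keep",
                  validate = FALSE)
  }
}
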