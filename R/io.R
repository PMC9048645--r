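#' Construct a count table from a data frame
#'
#' The central expression container: a tibble with a `gene_id` character
#' column followed by one non-negative integer column per sample, plus a
#' sample-to-group assignment stored as an attribute. All downstream stages
#' (`tmm_factors()`, `call_degs()`, `sample_qc()`) accept this object.
#'
#' @param x A data frame whose first column is the gene identifier and whose
#'   remaining columns are per-sample counts.
#' @param groups Named character vector mapping sample name to group label,
#'   or a data frame with columns `sample` and `group`. Every named sample
#'   must be a column of `x`; samples without a mapping are dropped with a
#'   warning.
#' @return A tibble of class `count_tbl` with attribute `"groups"`.
#' @examples
#' df <- data.frame(gene_id = c("g1", "g2"),
#'                  s1 = c(5L, 0L), s2 = c(7L, 1L),
#'                  s3 = c(4L, 2L), s4 = c(6L, 0L))
#' ct <- count_tbl(df, c(s1 = "OE", s2 = "OE", s3 = "ctrl", s4 = "ctrl"))
#' sample_groups(ct)
#' @export
count_tbl <- function(x, groups) {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort("`x` must be a data frame with a gene-ID column and >= 1 sample.",
          class = "cernet_format_error")
  }
  x <- as_tibble(x)
  names(x)[1L] <- "gene_id"
  x$gene_id <- as.character(x$gene_id)
  if (anyDuplicated(x$gene_id)) {
    dup <- unique(x$gene_id[duplicated(x$gene_id)])
    abort(sprintf("Duplicate gene ID(s): %s",
                  paste(head(dup, 5L), collapse = ", ")),
          class = "cernet_format_error")
  }
  if (is.data.frame(groups)) {
    groups <- setNames(as.character(groups$group), groups$sample)
  }
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    abort("`groups` must be a named vector (sample -> group).",
          class = "cernet_mapping_error")
  }
  missing_samples <- setdiff(names(groups), names(x)[-1L])
  if (length(missing_samples)) {
    abort(sprintf("Sample(s) in `groups` absent from the table: %s",
                  paste(missing_samples, collapse = ", ")),
          class = "cernet_mapping_error")
  }
  extra <- setdiff(names(x)[-1L], names(groups))
  if (length(extra)) {
    warn(sprintf("Dropping %d sample column(s) without a group mapping: %s",
                 length(extra), paste(extra, collapse = ", ")))
    x <- x[, c("gene_id", names(groups)), drop = FALSE]
  }
  for (s in names(groups)) {
    v <- x[[s]]
    if (!is.numeric(v)) {
      abort(sprintf("Sample column '%s' is not numeric.", s),
            class = "cernet_format_error")
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      abort(sprintf(
        "Invalid count at gene '%s', sample '%s': %s (counts must be non-negative integers).",
        x$gene_id[bad[1L]], s, format(v[bad[1L]])),
        class = "cernet_format_error")
    }
    x[[s]] <- as.integer(v)
  }
  if (length(unique(groups)) < 2L) {
    abort("Need >= 2 groups with >= 1 sample each.",
          class = "cernet_mapping_error")
  }
  structure(x, groups = groups,
            class = c("count_tbl", class(as_tibble(x))))
}

#' @rdname count_tbl
#' @param ct A `count_tbl`.
#' @export
sample_groups <- function(ct) attr(ct, "groups", exact = TRUE)

# internal: integer matrix (genes x samples) view
ct_matrix <- function(ct) {
  m <- as.matrix(ct[, names(sample_groups(ct)), drop = FALSE])
  rownames(m) <- ct$gene_id
  storage.mode(m) <- "double"
  m
}

#' Read a gene-by-sample count matrix from TSV
#'
#' @param path TSV file: gene IDs in the first column, one integer column
#'   per sample, header row with sample names.
#' @param groups Sample-to-group mapping (see [count_tbl()]).
#' @return A `count_tbl`.
#' @export
read_count_matrix <- function(path, groups) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  count_tbl(x, groups)
}

#' Write a count table to TSV
#'
#' @param ct A `count_tbl`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(ct, path) {
  readr::write_tsv(as_tibble(ct), path, progress = FALSE)
  invisible(path)
}

#' Read a STRING-style scored edge table
#'
#' Expects a TSV with two node columns and a combined-score column (the
#' first column whose name contains "score", else the third column). Two
#' score dialects are accepted: fractions on \[0,1\] and STRING's integer
#' export on \[0,1000\]. Any value greater than 1 switches the whole file to
#' the 0--1000 dialect, which is then divided by 1000; the detected dialect
#' is reported via a message.
#'
#' Edges are undirected: duplicate pairs (in either orientation) are
#' collapsed keeping the maximum score, self-loops are dropped, and only
#' edges with score >= `score_min` are returned.
#'
#' @param path TSV file path.
#' @param score_min Minimum retained combined score on the \[0,1\] scale.
#' @return Tibble with columns `node_a`, `node_b`, `score`, where
#'   `node_a < node_b` lexicographically.
#' @export
read_string_edges <- function(path, score_min = 0.9) {
  x <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (ncol(x) < 3L) {
    abort("Edge table needs two node columns and a combined-score column.",
          class = "cernet_format_error")
  }
  score_col <- grep("score", names(x), ignore.case = TRUE, value = TRUE)
  score_col <- if (length(score_col)) score_col[1L] else names(x)[3L]
  edges <- tibble(
    node_a = as.character(x[[1L]]),
    node_b = as.character(x[[2L]]),
    score = as.numeric(x[[score_col]])
  )
  if (any(is.na(edges$score))) {
    abort("Non-numeric combined score encountered.",
          class = "cernet_format_error")
  }
  if (any(edges$score < 0) || any(edges$score > 1000)) {
    abort("Combined scores outside both the [0,1] and [0,1000] dialects.",
          class = "cernet_format_error")
  }
  if (any(edges$score > 1)) {
    inform("read_string_edges: detected 0-1000 score dialect; dividing by 1000.")
    edges$score <- edges$score / 1000
  } else {
    inform("read_string_edges: detected 0-1 score dialect.")
  }
  edges |>
    filter(.data$node_a != .data$node_b) |>
    mutate(
      lo = pmin(.data$node_a, .data$node_b),
      hi = pmax(.data$node_a, .data$node_b)
    ) |>
    group_by(.data$lo, .data$hi) |>
    summarise(score = max(.data$score), .groups = "drop") |>
    rename(node_a = "lo", node_b = "hi") |>
    filter(.data$score >= score_min) |>
    arrange(.data$node_a, .data$node_b)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: tab-separated `set_id<TAB>description<TAB>gene...`.
#' @return Long tibble with columns `set_id`, `description`, `gene`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3L
  if (any(short)) {
    abort(sprintf("GMT line %d has fewer than 3 fields.", which(short)[1L]),
          class = "cernet_format_error")
  }
  purrr::map_dfr(parts, function(p) {
    tibble(set_id = p[[1L]], description = p[[2L]],
           gene = unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  })
}

#' Write a gene-set collection to GMT
#'
#' @param sets Long tibble with `set_id`, `description`, `gene` columns.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- sets |>
    group_by(.data$set_id, .data$description) |>
    summarise(line = paste(unique(.data$gene), collapse = "\t"),
              .groups = "drop") |>
    mutate(line = paste(.data$set_id, .data$description, .data$line,
                        sep = "\t")) |>
    pull("line")
  writeLines(lines, path)
  invisible(path)
}

#' Export a network as edge-list TSV or Cytoscape SIF
#'
#' Works for both the tripartite ceRNA network (edge types `circ-mir`,
#' `mir-mrna`) and the PPI graph (edge type `pp`). SIF rows are
#' `source<TAB>interaction<TAB>target`; the TSV format keeps a header so the
#' file round-trips through [read_network()] exactly.
#'
#' @param net A `cerna_network`, `ppi_graph`, or a plain edge tibble with
#'   columns `from`, `to` and optionally `edge_type`.
#' @param path Output file.
#' @param format `"tsv"` (edge-list with header) or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("tsv", "sif")) {
  format <- tryCatch(match.arg(format), error = function(e) {
    abort(sprintf("Unknown network format '%s'; use \"tsv\" or \"sif\".",
                  format[1L]), class = "cernet_usage_error")
  })
  edges <- network_edges(net)
  if (nrow(edges) == 0L) {
    abort("Refusing to export an empty network.",
          class = "cernet_usage_error")
  }
  if (!"edge_type" %in% names(edges)) edges$edge_type <- "interacts"
  if (format == "sif") {
    writeLines(paste(edges$from, edges$edge_type, edges$to, sep = "\t"), path)
  } else {
    readr::write_tsv(edges[, c("from", "edge_type", "to")], path,
                     progress = FALSE)
  }
  invisible(path)
}

#' Import a network edge list written by [write_network()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"sif"`.
#' @return Tibble with columns `from`, `edge_type`, `to`.
#' @export
read_network <- function(path, format = c("tsv", "sif")) {
  format <- match.arg(format)
  if (format == "sif") {
    parts <- strsplit(readLines(path, warn = FALSE), "\t", fixed = TRUE)
    bad <- lengths(parts) != 3L
    if (any(bad)) {
      abort("SIF rows must have exactly 3 tab-separated fields.",
            class = "cernet_format_error")
    }
    tibble(from = map_chr(parts, 1L), edge_type = map_chr(parts, 2L),
           to = map_chr(parts, 3L))
  } else {
    readr::read_tsv(path, col_types = "ccc", progress = FALSE)
  }
}

# internal: extract a from/edge_type/to tibble from any supported network
network_edges <- function(net) {
  if (inherits(net, "cerna_network")) return(net$edges)
  if (inherits(net, "ppi_graph")) {
    e <- igraph::as_data_frame(net$graph, what = "edges")
    return(tibble(from = e$from, edge_type = "pp", to = e$to))
  }
  if (is.data.frame(net)) {
    stopifnot(all(c("from", "to") %in% names(net)))
    return(as_tibble(net))
  }
  abort("Unsupported network object.", class = "cernet_usage_error")
}
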