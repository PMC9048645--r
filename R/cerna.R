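#' Read a circRNA annotation table
#'
#' Parses a TSV laid out as position, strand, circRNA ID, genomic length,
#' spliced length, gene symbol, RBPs (comma-separated RNA-binding
#' proteins predicted at the flanking regions). The position string
#' `"chrN:start-end"` is split into coordinates, and two structural
#' invariants are enforced per row: the printed genomic length must equal
#' `end - start`, and the spliced length cannot exceed the genomic length.
#'
#' @param path TSV file with a header row.
#' @return Tibble with columns `chrom`, `start`, `end`, `strand`,
#'   `circ_id`, `genomic_length`, `spliced_length`, `gene_symbol`, `rbps`
#'   (list column of character vectors).
#' @export
read_circ_annotation <- function(path) {
  x <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                       progress = FALSE)
  if (ncol(x) < 7L) {
    abort("circRNA annotation needs 7 columns: position, strand, ID, genomic length, spliced length, gene symbol, RBPs.",
          class = "cernet_format_error")
  }
  names(x)[1:7] <- c("position", "strand", "circ_id", "genomic_length",
                     "spliced_length", "gene_symbol", "rbps")
  m <- stringr::str_match(x$position, "^(chr[^:]+):(\\d+)-(\\d+)$")
  bad <- which(is.na(m[, 1L]))
  if (length(bad)) {
    abort(sprintf("Row %d: malformed position string '%s'.",
                  bad[1L], x$position[bad[1L]]),
          class = "cernet_parse_error")
  }
  out <- tibble(
    chrom = m[, 2L],
    start = as.numeric(m[, 3L]),
    end = as.numeric(m[, 4L]),
    strand = x$strand,
    circ_id = x$circ_id,
    genomic_length = as.numeric(x$genomic_length),
    spliced_length = as.numeric(x$spliced_length),
    gene_symbol = x$gene_symbol,
    rbps = purrr::map(x$rbps, function(s) {
      sort(unique(trimws(strsplit(s, ",", fixed = TRUE)[[1L]])))
    })
  )
  if (!all(out$strand %in% c("+", "-"))) {
    abort("Strand must be '+' or '-'.", class = "cernet_parse_error")
  }
  bad <- which(out$start >= out$end)
  if (length(bad)) {
    abort(sprintf("Row %d (%s): start >= end.", bad[1L],
                  out$circ_id[bad[1L]]), class = "cernet_validation_error")
  }
  bad <- which(out$genomic_length != out$end - out$start)
  if (length(bad)) {
    abort(sprintf(
      "Row %d (%s): printed genomic length %g != end - start = %g.",
      bad[1L], out$circ_id[bad[1L]], out$genomic_length[bad[1L]],
      out$end[bad[1L]] - out$start[bad[1L]]),
      class = "cernet_validation_error")
  }
  bad <- which(out$spliced_length > out$genomic_length)
  if (length(bad)) {
    abort(sprintf("Row %d (%s): spliced length exceeds genomic length.",
                  bad[1L], out$circ_id[bad[1L]]),
          class = "cernet_validation_error")
  }
  out
}

#' Unique RNA-binding proteins across circRNA annotations
#'
#' @param annotations Tibble from [read_circ_annotation()].
#' @return Sorted character vector of distinct RBP names.
#' @export
unique_rbps <- function(annotations) {
  if (nrow(annotations) == 0L) {
    abort("Empty annotation table.", class = "cernet_usage_error")
  }
  sort(unique(unlist(annotations$rbps)))
}

#' Check whether any predicted RBP is differentially expressed
#'
#' @param rbps Character vector of RBP names (gene symbols).
#' @param deg_table Per-gene tibble with `gene_id` and `status`.
#' @return Tibble with `rbp`, `status` (`up` / `down` / `ns` /
#'   `not tested`), and attribute `any_differential`.
#' @export
rbp_differential_check <- function(rbps, deg_table) {
  report <- tibble(rbp = rbps) |>
    left_join(deg_table |> select(rbp = "gene_id", status = "status"),
              by = "rbp") |>
    mutate(status = dplyr::coalesce(.data$status, "not tested"))
  attr(report, "any_differential") <-
    any(report$status %in% c("up", "down"))
  report
}

#' Filter circRNA--miRNA pairs by percentile score
#'
#' Retains pairs whose prediction score reaches the percentile cut-off
#' (inclusive: `percentile >= percentile_min`) and deduplicates.
#'
#' @param circ_mir Tibble with columns `circ_id`, `mirna_id`, `percentile`.
#' @param percentile_min Percentile threshold (default 90).
#' @return Tibble of retained pairs.
#' @export
filter_circ_mir <- function(circ_mir, percentile_min = 90) {
  out <- circ_mir |>
    filter(.data$percentile >= percentile_min) |>
    distinct(.data$circ_id, .data$mirna_id, .keep_all = TRUE)
  if (nrow(out) == 0L) {
    warn("No circRNA-miRNA pair reaches the percentile threshold.")
  }
  out
}

#' Six-database consensus of miRNA target predictions
#'
#' Per miRNA, intersects the target-gene sets reported by all six
#' prediction sources; only genes present in every source survive.
#' miRNAs with an empty consensus are dropped.
#'
#' @param per_db_targets Named list of exactly six tibbles, each with
#'   columns `mirna_id` and `gene_id`.
#' @return Tibble with columns `mirna_id`, `gene_id` (the consensus pairs).
#' @export
intersect_target_dbs <- function(per_db_targets) {
  if (length(per_db_targets) != 6L) {
    abort(sprintf("Expected exactly 6 prediction sources, got %d.",
                  length(per_db_targets)), class = "cernet_usage_error")
  }
  long <- purrr::imap(per_db_targets, function(tb, nm) {
    tb |> distinct(.data$mirna_id, .data$gene_id) |> mutate(source = nm)
  }) |> bind_rows()
  long |>
    group_by(.data$mirna_id, .data$gene_id) |>
    summarise(n_sources = dplyr::n_distinct(.data$source),
              .groups = "drop") |>
    filter(.data$n_sources == 6L) |>
    select("mirna_id", "gene_id") |>
    arrange(.data$mirna_id, .data$gene_id)
}

#' Concordant miRNA--mRNA pairs: upregulated targets inside the PPI
#'
#' Under the sponge model an upregulated circRNA derepresses its miRNAs'
#' targets, so consensus target genes are kept only when they are
#' upregulated DEGs **and** nodes of the PPI graph.
#'
#' @param consensus Tibble `mirna_id`, `gene_id` from
#'   [intersect_target_dbs()].
#' @param deg_table Per-gene tibble with `gene_id`, `status`.
#' @param ppi A `ppi_graph` (or character vector of PPI node names).
#' @return Tibble of surviving (`mirna_id`, `gene_id`) pairs.
#' @export
concordance_overlap <- function(consensus, deg_table, ppi) {
  ppi_nodes <- if (inherits(ppi, "ppi_graph")) {
    ppi$nodes$node
  } else {
    as.character(ppi)
  }
  up_genes <- deg_table$gene_id[deg_table$status == "up"]
  out <- consensus |>
    filter(.data$gene_id %in% up_genes, .data$gene_id %in% ppi_nodes) |>
    arrange(.data$mirna_id, .data$gene_id)
  inform(sprintf(
    "concordance_overlap: %d pairs retained (%d miRNAs, %d genes).",
    nrow(out), dplyr::n_distinct(out$mirna_id),
    dplyr::n_distinct(out$gene_id)))
  out
}

#' Assemble the tripartite circRNA--miRNA--mRNA network
#'
#' Joins the percentile-filtered circRNA--miRNA pairs with the concordant
#' miRNA--mRNA pairs, keeping only miRNAs present in both; applies the
#' expression node filter (`fdr < cerna_fdr_max`, `|log2FC| >
#' cerna_abs_log2fc_min`, `p < cerna_p_max`) to mRNA nodes; drops isolated
#' nodes; and computes per-node degree.
#'
#' @param circ_mir Filtered pairs from [filter_circ_mir()].
#' @param mir_mrna Pairs from [concordance_overlap()].
#' @param deg_table Per-gene tibble (`gene_id`, `logFC`, `p_value`, `fdr`).
#' @param config A [pipeline_config()].
#' @return Object of class `cerna_network`: list with `nodes` (tibble
#'   `node`, `node_type`, `degree`), `edges` (tibble `from`, `edge_type`,
#'   `to`) and `empty` flag. An empty result is returned as an explicit
#'   empty network (with a warning), never as an error.
#' @export
assemble_cerna <- function(circ_mir, mir_mrna, deg_table,
                           config = pipeline_config()) {
  if (nrow(circ_mir) == 0L || nrow(mir_mrna) == 0L) {
    abort("Both circRNA-miRNA and miRNA-mRNA pair sets must be nonempty.",
          class = "cernet_usage_error")
  }
  keep_genes <- deg_table |>
    filter(.data$fdr < config$cerna_fdr_max,
           abs(.data$logFC) > config$cerna_abs_log2fc_min,
           .data$p_value < config$cerna_p_max) |>
    pull("gene_id")
  mm <- mir_mrna |>
    filter(.data$gene_id %in% keep_genes) |>
    distinct(.data$mirna_id, .data$gene_id)
  shared_mirnas <- intersect(unique(circ_mir$mirna_id),
                             unique(mm$mirna_id))
  cm <- circ_mir |>
    filter(.data$mirna_id %in% shared_mirnas) |>
    distinct(.data$circ_id, .data$mirna_id)
  mm <- filter(mm, .data$mirna_id %in% shared_mirnas)
  edges <- bind_rows(
    tibble(from = cm$circ_id, edge_type = "circ-mir", to = cm$mirna_id),
    tibble(from = mm$mirna_id, edge_type = "mir-mrna", to = mm$gene_id)
  ) |> arrange(.data$edge_type, .data$from, .data$to)
  if (nrow(edges) == 0L) {
    warn("assemble_cerna: empty network after filtering.")
    net <- list(nodes = tibble(node = character(), node_type = character(),
                               degree = integer()),
                edges = edges, empty = TRUE)
    return(structure(net, class = "cerna_network"))
  }
  nodes <- bind_rows(
    tibble(node = unique(cm$circ_id), node_type = "circRNA"),
    tibble(node = unique(c(cm$mirna_id, mm$mirna_id)), node_type = "miRNA"),
    tibble(node = unique(mm$gene_id), node_type = "mRNA")
  )
  degree_tab <- tibble(node = c(edges$from, edges$to)) |>
    count(.data$node, name = "degree")
  nodes <- nodes |>
    left_join(degree_tab, by = "node") |>
    mutate(degree = dplyr::coalesce(.data$degree, 0L)) |>
    filter(.data$degree > 0L) |>
    arrange(.data$node_type, desc(.data$degree), .data$node)
  inform(sprintf(
    "assemble_cerna: %d nodes (%d circRNA, %d miRNA, %d mRNA), %d edges (%d circ-mir, %d mir-mrna).",
    nrow(nodes), sum(nodes$node_type == "circRNA"),
    sum(nodes$node_type == "miRNA"), sum(nodes$node_type == "mRNA"),
    nrow(edges), sum(edges$edge_type == "circ-mir"),
    sum(edges$edge_type == "mir-mrna")))
  structure(list(nodes = nodes, edges = edges, empty = FALSE),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  if (isTRUE(x$empty)) {
    cat("<cerna_network> empty (no nodes survive filtering)\n")
    return(invisible(x))
  }
  cat(sprintf("<cerna_network> %d nodes (%s), %d edges\n",
              nrow(x$nodes),
              paste(sprintf("%d %s", table(x$nodes$node_type)[
                c("circRNA", "miRNA", "mRNA")],
                c("circRNA", "miRNA", "mRNA")), collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' @export
tidy.cerna_network <- function(x, ...) x$edges

#' @export
glance.cerna_network <- function(x, ...) {
  tibble(
    n_nodes = nrow(x$nodes),
    n_circ = sum(x$nodes$node_type == "circRNA"),
    n_mirna = sum(x$nodes$node_type == "miRNA"),
    n_mrna = sum(x$nodes$node_type == "mRNA"),
    n_edges = nrow(x$edges),
    n_circ_mir = sum(x$edges$edge_type == "circ-mir"),
    n_mir_mrna = sum(x$edges$edge_type == "mir-mrna")
  )
}

#' Plot a ceRNA network
#'
#' Simple ggplot rendering on an igraph layout: circRNAs as diamonds,
#' miRNAs as triangles, mRNAs as circles.
#'
#' @param object A `cerna_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cerna_network <- function(object, ...) {
  if (isTRUE(object$empty)) {
    abort("Cannot plot an empty network.", class = "cernet_usage_error")
  }
  g <- igraph::graph_from_data_frame(
    object$edges[, c("from", "to")], directed = FALSE,
    vertices = object$nodes$node)
  xy <- igraph::layout_with_fr(g)
  pos <- tibble(node = igraph::V(g)$name, x = xy[, 1L], y = xy[, 2L]) |>
    left_join(object$nodes, by = "node")
  seg <- object$edges |>
    left_join(pos |> select(from = "node", x0 = "x", y0 = "y"),
              by = "from") |>
    left_join(pos |> select(to = "node", x1 = "x", y1 = "y"), by = "to")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x0, y = .data$y0,
                   xend = .data$x1, yend = .data$y1),
      colour = "grey70") +
    ggplot2::geom_point(
      data = pos,
      ggplot2::aes(.data$x, .data$y, shape = .data$node_type,
                   colour = .data$node_type, size = .data$degree)) +
    ggplot2::scale_shape_manual(
      values = c(circRNA = 18, miRNA = 17, mRNA = 16)) +
    ggplot2::theme_void() +
    ggplot2::labs(shape = NULL, colour = NULL, size = "degree")
}

#' Hub genes and crucial miRNAs by node degree
#'
#' Ranks mRNA nodes by ceRNA-network degree (ties broken by name) and
#' miRNAs by their number of miRNA target sites (mRNA-side degree).
#'
#' @param net A `cerna_network`.
#' @param top_n Number of top-ranked genes flagged as hubs.
#' @return List of class `hub_ranking`: `genes` (tibble `gene_id`,
#'   `degree`, `rank`, `is_hub`), `mirnas` (tibble `mirna_id`,
#'   `target_sites`, `circ_partners`, `rank`).
#' @export
hub_genes <- function(net, top_n = 5L) {
  if (isTRUE(net$empty) || nrow(net$edges) == 0L) {
    abort("Network is empty.", class = "cernet_usage_error")
  }
  mm <- filter(net$edges, .data$edge_type == "mir-mrna")
  cm <- filter(net$edges, .data$edge_type == "circ-mir")
  genes <- net$nodes |>
    filter(.data$node_type == "mRNA") |>
    select(gene_id = "node", degree = "degree") |>
    arrange(desc(.data$degree), .data$gene_id) |>
    mutate(rank = row_number(), is_hub = row_number() <= top_n)
  mirnas <- net$nodes |>
    filter(.data$node_type == "miRNA") |>
    select(mirna_id = "node") |>
    mutate(
      target_sites = map_int(.data$mirna_id,
                             function(m) sum(mm$from == m)),
      circ_partners = map_int(.data$mirna_id,
                              function(m) sum(cm$to == m))
    ) |>
    arrange(desc(.data$target_sites), .data$mirna_id) |>
    mutate(rank = row_number())
  structure(list(genes = genes, mirnas = mirnas, top_n = as.integer(top_n)),
            class = "hub_ranking")
}

#' @export
print.hub_ranking <- function(x, ...) {
  cat(sprintf("<hub_ranking> top gene(s): %s; top miRNA: %s (%d target sites)\n",
              paste(head(x$genes$gene_id[x$genes$is_hub], x$top_n),
                    collapse = ", "),
              x$mirnas$mirna_id[1L], x$mirnas$target_sites[1L]))
  invisible(x)
}

#' @export
tidy.hub_ranking <- function(x, ...) x$genes
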