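#' Build a protein-protein interaction graph from scored edges
#'
#' Constructs an undirected simple graph from a (pre-filtered) scored edge
#' table and annotates every node with its differential-expression status.
#' Nodes absent from the DEG table get regulation `"none"` with a warning.
#'
#' @param edges Tibble with columns `node_a`, `node_b` and optionally
#'   `score` (as returned by [read_string_edges()]).
#' @param deg_table Per-gene tibble with `gene_id` and `status`
#'   (from [tidy.deg_analysis()]), or `NULL`.
#' @param config A [pipeline_config()]; `ppi_score_min` is applied here if
#'   a `score` column is present.
#' @return Object of class `ppi_graph`: list with `graph` (igraph) and
#'   `nodes` (tibble `node`, `regulation`).
#' @export
build_ppi <- function(edges, deg_table = NULL, config = pipeline_config()) {
  e <- as_tibble(edges)
  if (!all(c("node_a", "node_b") %in% names(e))) {
    names(e)[1:2] <- c("node_a", "node_b")
  }
  if ("score" %in% names(e)) e <- filter(e, .data$score >= config$ppi_score_min)
  e <- e |>
    filter(.data$node_a != .data$node_b) |>
    mutate(lo = pmin(.data$node_a, .data$node_b),
           hi = pmax(.data$node_a, .data$node_b)) |>
    distinct(.data$lo, .data$hi, .keep_all = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = e$lo, to = e$hi), directed = FALSE)
  nodes <- tibble(node = igraph::V(g)$name)
  if (!is.null(deg_table)) {
    nodes <- nodes |>
      left_join(
        deg_table |>
          select(node = "gene_id", regulation = "status") |>
          mutate(regulation = ifelse(.data$regulation == "ns", "none",
                                     .data$regulation)),
        by = "node") |>
      mutate(regulation = dplyr::coalesce(.data$regulation, "none"))
    n_missing <- sum(!nodes$node %in% deg_table$gene_id)
    if (n_missing > 0) {
      warn(sprintf("%d PPI node(s) absent from the DEG table; regulation set to 'none'.",
                   n_missing))
    }
  } else {
    nodes$regulation <- "none"
  }
  inform(sprintf("build_ppi: %d nodes, %d edges.",
                 igraph::vcount(g), igraph::ecount(g)))
  structure(list(graph = g, nodes = nodes), class = "ppi_graph")
}

#' @export
print.ppi_graph <- function(x, ...) {
  cat(sprintf("<ppi_graph> %d nodes, %d edges (%d up, %d down)\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph),
              sum(x$nodes$regulation == "up"),
              sum(x$nodes$regulation == "down")))
  invisible(x)
}

#' Degree, betweenness and closeness centralities
#'
#' Per-node topological metrics on the unweighted simple graph:
#' \itemize{
#'   \item degree: number of incident edges;
#'   \item betweenness: Brandes accumulation over unweighted shortest
#'     paths, endpoints excluded, unnormalized (the sum over unordered
#'     pairs);
#'   \item closeness: component-size-adjusted, `(m / sum_d) * (m /
#'     (|V| - 1))` where `m` is the number of other vertices reachable from
#'     the node and `sum_d` the total distance to them; isolated nodes get
#'     0. With `closeness_compat = TRUE` the plain within-component
#'     `1 / sum_d` is reported instead.
#' }
#'
#' @param ppi A `ppi_graph` (or a bare igraph).
#' @param weighted Must remain `FALSE`; the supported contract is the
#'   unweighted analysis.
#' @param closeness_compat Use the plain reciprocal-farness convention.
#' @return Tibble with `node`, `degree`, `betweenness`, `closeness`,
#'   `regulation`.
#' @export
centralities <- function(ppi, weighted = FALSE, closeness_compat = FALSE) {
  g <- if (inherits(ppi, "ppi_graph")) ppi$graph else ppi
  if (!igraph::is_igraph(g)) {
    abort("`ppi` must be a ppi_graph or igraph object.",
          class = "cernet_usage_error")
  }
  if (igraph::vcount(g) == 0L) {
    abort("Empty graph.", class = "cernet_usage_error")
  }
  if (isTRUE(weighted)) {
    abort("Weighted centralities are not supported; the contract is the unweighted analysis.",
          class = "cernet_usage_error")
  }
  nv <- igraph::vcount(g)
  deg <- igraph::degree(g, mode = "all", loops = FALSE)
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA,
                             normalized = FALSE)
  d <- igraph::distances(g, weights = NA)
  clo <- vapply(seq_len(nv), function(i) {
    di <- d[i, -i]
    reach <- is.finite(di) & di > 0
    m <- sum(reach)
    if (m == 0L) return(0)
    sum_d <- sum(di[reach])
    if (closeness_compat) 1 / sum_d else (m / sum_d) * (m / (nv - 1))
  }, numeric(1L))
  out <- tibble(
    node = igraph::V(g)$name,
    degree = as.integer(deg),
    betweenness = unname(btw),
    closeness = unname(clo)
  )
  if (inherits(ppi, "ppi_graph")) {
    out <- left_join(out, ppi$nodes, by = "node") |>
      mutate(regulation = dplyr::coalesce(.data$regulation, "none"))
  } else {
    out$regulation <- "none"
  }
  out
}

#' @rdname centralities
#' @param x A `ppi_graph`.
#' @param ... Unused.
#' @export
tidy.ppi_graph <- function(x, ...) centralities(x)

#' @export
glance.ppi_graph <- function(x, ...) {
  tibble(
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_up = sum(x$nodes$regulation == "up"),
    n_down = sum(x$nodes$regulation == "down")
  )
}

#' Core proteins: nodes top-k in all three centralities
#'
#' Ranks nodes separately by degree, betweenness and closeness (ties
#' broken by metric value, then node name; boundary ties at the k-th value
#' are resolved deterministically by name and reported) and returns the
#' intersection of the three top-k lists, plus each metric's top-k table.
#'
#' @param records Centrality tibble from [centralities()].
#' @param k Number of top nodes per metric.
#' @return List of class `core_proteins`: `core` (tibble of core nodes
#'   with all three metrics), `top_degree`, `top_betweenness`,
#'   `top_closeness` (each a k-row tibble).
#' @export
core_proteins <- function(records, k = 20L) {
  k <- as.integer(k)
  if (k > nrow(records)) {
    abort(sprintf("k = %d exceeds the number of nodes (%d).",
                  k, nrow(records)), class = "cernet_usage_error")
  }
  top_by <- function(metric) {
    ord <- records |>
      arrange(desc(.data[[metric]]), .data$node)
    boundary <- ord[[metric]][k]
    n_tied <- sum(ord[[metric]] == boundary)
    n_inside <- sum(ord[[metric]][seq_len(k)] == boundary)
    if (n_tied > n_inside) {
      inform(sprintf(
        "core_proteins: %d nodes tie at the rank-%d %s value %g; truncating by name.",
        n_tied, k, metric, boundary))
    }
    ord[seq_len(k), c("node", metric, "regulation")]
  }
  td <- top_by("degree")
  tb <- top_by("betweenness")
  tc <- top_by("closeness")
  core_ids <- Reduce(intersect, list(td$node, tb$node, tc$node))
  core <- records |>
    filter(.data$node %in% core_ids) |>
    arrange(desc(.data$degree), .data$node)
  structure(list(core = core, top_degree = td, top_betweenness = tb,
                 top_closeness = tc, k = k),
            class = "core_proteins")
}

#' @export
print.core_proteins <- function(x, ...) {
  cat(sprintf("<core_proteins> %d node(s) in all three top-%d lists: %s\n",
              nrow(x$core), x$k, paste(x$core$node, collapse = ", ")))
  invisible(x)
}
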