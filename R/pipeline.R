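#' Run the full ceRNA pipeline
#'
#' Orchestrates every stage from raw inputs to hub-gene ranking:
#' differential expression (TMM + exact NB test + BH), sample QC,
#' optional gene-set enrichment of the up- and down-regulated DEGs,
#' score-filtered PPI construction with centrality ranking and
#' core-protein selection, percentile filtering of circRNA--miRNA pairs,
#' six-database target consensus, concordance overlap, ceRNA assembly and
#' degree-based hub selection.
#'
#' @param counts A [count_tbl()].
#' @param ppi_edges Scored edge tibble (`node_a`, `node_b`, `score`).
#' @param circ_mir Tibble `circ_id`, `mirna_id`, `percentile`.
#' @param per_db_targets Named list of six tibbles (`mirna_id`,
#'   `gene_id`).
#' @param config A [pipeline_config()].
#' @param collections Optional GMT tibble for enrichment.
#' @param contrast,pool_controls Passed to [call_degs()].
#' @return List of class `cerna_pipeline`: `deg`, `qc`, `enrichment`
#'   (NULL without collections), `ppi`, `centrality`, `core`, `network`,
#'   `hubs`, `config`.
#' @export
run_pipeline <- function(counts, ppi_edges, circ_mir, per_db_targets,
                         config = pipeline_config(), collections = NULL,
                         contrast = NULL, pool_controls = FALSE) {
  inform(sprintf("run_pipeline: seed = %d, thresholds: DEG FDR < %g, |logFC| > %g; PPI score >= %g; percentile >= %g.",
                 config$seed, config$deg_fdr_max, config$deg_abs_logfc_min,
                 config$ppi_score_min, config$percentile_min))
  deg <- call_degs(counts, config, contrast = contrast,
                   pool_controls = pool_controls)
  deg_table <- tidy(deg)
  qc <- sample_qc(counts)

  enr <- NULL
  if (!is.null(collections)) {
    universe <- deg_table$gene_id
    enr <- list(
      up = enrich(deg_table$gene_id[deg_table$status == "up"], universe,
                  collections, p_max = config$enrich_p_max,
                  fold_min = config$enrich_fold_min),
      down = enrich(deg_table$gene_id[deg_table$status == "down"],
                    universe, collections, p_max = config$enrich_p_max,
                    fold_min = config$enrich_fold_min)
    )
  }

  ppi <- build_ppi(ppi_edges, deg_table, config)
  cent <- centralities(ppi)
  core <- if (nrow(cent) >= config$top_k) {
    core_proteins(cent, config$top_k)
  } else {
    NULL
  }

  cm <- filter_circ_mir(circ_mir, config$percentile_min)
  consensus <- intersect_target_dbs(per_db_targets)
  mm <- concordance_overlap(consensus, deg_table, ppi)
  net <- assemble_cerna(cm, mm, deg_table, config)
  hubs <- if (!isTRUE(net$empty)) hub_genes(net) else NULL

  structure(
    list(deg = deg, qc = qc, enrichment = enr, ppi = ppi,
         centrality = cent, core = core, network = net, hubs = hubs,
         config = config),
    class = "cerna_pipeline"
  )
}

#' @export
print.cerna_pipeline <- function(x, ...) {
  cat("<cerna_pipeline>\n")
  print(x$deg)
  print(x$ppi)
  print(x$network)
  if (!is.null(x$hubs)) print(x$hubs)
  invisible(x)
}

#' Run the pipeline from a directory of input files
#'
#' Expects the layout written by [write_study_inputs()]: `counts.tsv`,
#' `groups.tsv`, `ppi_edges.tsv`, `circ_mir.tsv` and six
#' `targets_<source>.tsv` files.
#'
#' @param dir Input directory.
#' @param config A [pipeline_config()].
#' @param collections Optional GMT tibble.
#' @return A `cerna_pipeline` (see [run_pipeline()]).
#' @export
run_pipeline_dir <- function(dir, config = pipeline_config(),
                             collections = NULL) {
  groups_tbl <- readr::read_tsv(file.path(dir, "groups.tsv"),
                                col_types = "cc", progress = FALSE)
  counts <- read_count_matrix(file.path(dir, "counts.tsv"),
                              setNames(groups_tbl$group, groups_tbl$sample))
  edges <- read_string_edges(file.path(dir, "ppi_edges.tsv"),
                             config$ppi_score_min)
  circ_mir <- readr::read_tsv(file.path(dir, "circ_mir.tsv"),
                              col_types = "ccd", progress = FALSE)
  target_files <- list.files(dir, pattern = "^targets_.*\\.tsv$",
                             full.names = TRUE)
  per_db <- setNames(
    purrr::map(target_files, readr::read_tsv, col_types = "cc",
               progress = FALSE),
    sub("^targets_(.*)\\.tsv$", "\\1", basename(target_files)))
  run_pipeline(counts, edges, circ_mir, per_db, config, collections)
}
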