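#' Pipeline configuration
#'
#' Collects every threshold the pipeline applies, with defaults matching the
#' study design the package implements: DEGs at FDR < 0.05 and |log2FC| > 1,
#' gene-set hits at P < 0.05 with fold enrichment > 5, protein--protein
#' interactions at combined score >= 0.9 (STRING "highest confidence"),
#' top-20 centrality ranking, circRNA--miRNA pairs at the 90th percentile,
#' and ceRNA mRNA nodes at FDR < 1%, |log2FC| > 2 and P < 0.01.
#'
#' @param deg_fdr_max BH-adjusted FDR ceiling for calling a gene
#'   differentially expressed (fraction in \[0,1\]).
#' @param deg_abs_logfc_min Minimum absolute log2 fold change for a DEG call
#'   (log2 units; the comparison is strict, `|logFC| > deg_abs_logfc_min`).
#' @param enrich_p_max Enrichment p-value ceiling (strict `<`).
#' @param enrich_fold_min Minimum fold enrichment (strict `>`).
#' @param ppi_score_min Minimum combined interaction score on the \[0,1\]
#'   scale; edges below it are dropped.
#' @param top_k Number of top-ranked nodes per centrality metric used for
#'   core-protein selection.
#' @param percentile_min Minimum percentile score for retaining a
#'   circRNA--miRNA pair (inclusive `>=`).
#' @param cerna_abs_log2fc_min,cerna_p_max,cerna_fdr_max Node filter applied
#'   to mRNA nodes of the ceRNA network (|log2FC| strict `>`, p and FDR
#'   strict `<`).
#' @param seed Integer seed driving every stochastic step of a pipeline run.
#'
#' @return A list of class `pipeline_config`.
#' @examples
#' cfg <- pipeline_config(top_k = 10)
#' cfg$ppi_score_min
#' @export
pipeline_config <- function(deg_fdr_max = 0.05,
                            deg_abs_logfc_min = 1.0,
                            enrich_p_max = 0.05,
                            enrich_fold_min = 5.0,
                            ppi_score_min = 0.9,
                            top_k = 20L,
                            percentile_min = 90,
                            cerna_abs_log2fc_min = 2.0,
                            cerna_p_max = 0.01,
                            cerna_fdr_max = 0.01,
                            seed = 1L) {
  cfg <- list(
    deg_fdr_max = deg_fdr_max,
    deg_abs_logfc_min = deg_abs_logfc_min,
    enrich_p_max = enrich_p_max,
    enrich_fold_min = enrich_fold_min,
    ppi_score_min = ppi_score_min,
    top_k = as.integer(top_k),
    percentile_min = percentile_min,
    cerna_abs_log2fc_min = cerna_abs_log2fc_min,
    cerna_p_max = cerna_p_max,
    cerna_fdr_max = cerna_fdr_max,
    seed = as.integer(seed)
  )
  for (nm in c("deg_fdr_max", "enrich_p_max", "ppi_score_min",
               "cerna_p_max", "cerna_fdr_max")) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a single fraction in [0, 1], got %s.",
                    nm, format(v)), class = "cernet_config_error")
    }
  }
  if (cfg$top_k < 1L) {
    abort("`top_k` must be >= 1.", class = "cernet_config_error")
  }
  if (cfg$percentile_min < 0 || cfg$percentile_min > 100) {
    abort("`percentile_min` must lie in [0, 100].",
          class = "cernet_config_error")
  }
  if (cfg$deg_abs_logfc_min < 0 || cfg$cerna_abs_log2fc_min < 0) {
    abort("log-fold-change thresholds must be non-negative.",
          class = "cernet_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read a key:value configuration file
#'
#' Plain-text `key: value` lines (one per line, `#` comments allowed)
#' overriding [pipeline_config()] defaults.
#'
#' @param path File path.
#' @return A `pipeline_config`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, ":", fixed = TRUE)
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    abort(sprintf("Malformed config line(s): %s",
                  paste(lines[bad], collapse = "; ")),
          class = "cernet_format_error")
  }
  keys <- trimws(vapply(kv, `[[`, "", 1L))
  vals <- as.numeric(trimws(vapply(kv, `[[`, "", 2L)))
  known <- names(formals(pipeline_config))
  unknown <- setdiff(keys, known)
  if (length(unknown)) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "cernet_format_error")
  }
  do.call(pipeline_config, as.list(setNames(vals, keys)))
}

# Derive a reproducible sub-seed from the master seed so that independent
# generators never share a stream; kept below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + 7919 * offset) %% 2147483647)
}
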