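#' Call differentially expressed genes between two groups
#'
#' The full DE stage: optional low-count filtering, TMM normalization,
#' common-dispersion estimation by conditional maximum likelihood, the
#' exact NB test per gene on library-equalized pseudo-counts,
#' Benjamini-Hochberg FDR across all tested genes, and threshold
#' classification into `up` / `down` / `ns`. `logFC` is the log2 ratio of
#' TMM-adjusted group-mean CPM (prior 0.5), positive when the gene is
#' higher in the first contrast group.
#'
#' @param counts A [count_tbl()].
#' @param config A [pipeline_config()]; `deg_fdr_max` and
#'   `deg_abs_logfc_min` gate the status call (`fdr < deg_fdr_max` and
#'   `|logFC| > deg_abs_logfc_min`, both strict on the logFC side).
#' @param contrast Character vector of two group labels,
#'   `c(treatment, control)`. Defaults to the first two groups in the
#'   mapping.
#' @param pool_controls If `TRUE`, all groups other than the treatment are
#'   pooled into a single control group.
#' @param filter_low If `TRUE` (default) genes with CPM > 1 in fewer than
#'   2 samples are removed before testing.
#' @return An object of class `deg_analysis`: list with elements `table`
#'   (the per-gene tibble: `gene_id`, `logFC`, `logCPM`, `p_value`, `fdr`,
#'   `status`), `factors`, `dispersion`, `contrast`, `config`. Use
#'   [tidy.deg_analysis()] for the table and [glance.deg_analysis()] for a
#'   one-row summary.
#' @export
call_degs <- function(counts, config = pipeline_config(), contrast = NULL,
                      pool_controls = FALSE, filter_low = TRUE) {
  g <- sample_groups(counts)
  lev <- unique(unname(g))
  if (is.null(contrast)) contrast <- lev[1:2]
  if (!contrast[1L] %in% lev) {
    abort(sprintf("Unknown contrast group '%s'.", contrast[1L]),
          class = "cernet_usage_error")
  }
  if (pool_controls) {
    g[g != contrast[1L]] <- "control_pooled"
    contrast <- c(contrast[1L], "control_pooled")
  }
  if (length(contrast) != 2L || !all(contrast %in% g)) {
    abort("`contrast` must name two groups present in the mapping.",
          class = "cernet_usage_error")
  }
  keep_samples <- names(g)[g %in% contrast]
  sub <- count_tbl(as_tibble(counts)[, c("gene_id", keep_samples)],
                   g[keep_samples])

  if (filter_low) {
    cpm0 <- sweep(ct_matrix(sub), 2L, colSums(ct_matrix(sub)) / 1e6, "/")
    keep_genes <- rowSums(cpm0 > 1) >= 2L
    sub <- count_tbl(as_tibble(sub)[keep_genes, , drop = FALSE],
                     sample_groups(sub))
  }

  factors <- tmm_factors(sub)
  phi <- estimate_common_dispersion(sub)
  pseudo <- equalize_libraries(sub, factors)
  gsub <- sample_groups(sub)
  idx_a <- which(gsub[colnames(pseudo)] == contrast[1L])
  idx_b <- which(gsub[colnames(pseudo)] == contrast[2L])

  pvals <- vapply(seq_len(nrow(pseudo)), function(i) {
    nb_exact_test(pseudo[i, idx_a], pseudo[i, idx_b], phi)
  }, numeric(1L))

  m <- ct_matrix(sub)
  eff <- colSums(m) * factors[colnames(m)]
  cpm <- sweep(m + 0.5, 2L, eff / 1e6, "/")
  mean_a <- rowMeans(cpm[, idx_a, drop = FALSE])
  mean_b <- rowMeans(cpm[, idx_b, drop = FALSE])
  logfc <- log2(mean_a) - log2(mean_b)
  logcpm <- log2(rowMeans(cpm))

  fdr <- p.adjust(pvals, method = "BH")
  status <- dplyr::case_when(
    fdr < config$deg_fdr_max & logfc > config$deg_abs_logfc_min ~ "up",
    fdr < config$deg_fdr_max & logfc < -config$deg_abs_logfc_min ~ "down",
    TRUE ~ "ns"
  )
  table <- tibble(
    gene_id = sub$gene_id,
    logFC = unname(logfc),
    logCPM = unname(logcpm),
    p_value = pvals,
    fdr = fdr,
    status = status
  )
  inform(sprintf("call_degs: %d genes tested, %d up, %d down (phi = %.4f).",
                 nrow(table), sum(status == "up"), sum(status == "down"),
                 phi))
  structure(
    list(table = table, factors = factors, dispersion = phi,
         contrast = contrast, config = config),
    class = "deg_analysis"
  )
}

#' @export
print.deg_analysis <- function(x, ...) {
  cat(sprintf("<deg_analysis> %s vs %s: %d genes, %d up, %d down (phi=%.4f)\n",
              x$contrast[1L], x$contrast[2L], nrow(x$table),
              sum(x$table$status == "up"), sum(x$table$status == "down"),
              x$dispersion))
  invisible(x)
}

#' Tidy the per-gene differential-expression table
#'
#' @param x A `deg_analysis`.
#' @param ... Unused.
#' @return The per-gene tibble.
#' @export
tidy.deg_analysis <- function(x, ...) x$table

#' One-row summary of a differential-expression run
#'
#' @param x A `deg_analysis`.
#' @param ... Unused.
#' @return One-row tibble: gene counts by status, dispersion, contrast.
#' @export
glance.deg_analysis <- function(x, ...) {
  tibble(
    n_genes = nrow(x$table),
    n_up = sum(x$table$status == "up"),
    n_down = sum(x$table$status == "down"),
    dispersion = x$dispersion,
    contrast = paste(x$contrast, collapse = " vs ")
  )
}

#' Volcano plot of a differential-expression run
#'
#' @param object A `deg_analysis`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_analysis <- function(object, ...) {
  d <- object$table |>
    mutate(neglog_fdr = -log10(pmax(.data$fdr, 1e-300)))
  ggplot2::ggplot(d, ggplot2::aes(.data$logFC, .data$neglog_fdr,
                                  colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(
      values = c(up = "#d7301f", down = "#0570b0", ns = "grey70")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 FDR",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Sample-level quality control: correlations and PCA
#'
#' Pearson correlations between samples on log2 CPM, within/between-group
#' median correlations, and PCA (SVD of the sample-centred logCPM matrix)
#' with the per-component fraction of total variance.
#'
#' @param counts A [count_tbl()] with >= 3 samples.
#' @param factors Optional TMM factors.
#' @return A list of class `sample_qc`: `pearson_r` (sample x sample
#'   matrix), `pc_variance` (fractions summing to 1), `pc_scores`
#'   (samples x components), `within_group_median_r`,
#'   `between_group_median_r`.
#' @export
sample_qc <- function(counts, factors = NULL) {
  g <- sample_groups(counts)
  if (length(g) < 3L) {
    abort("sample_qc needs >= 3 samples.", class = "cernet_design_error")
  }
  lc <- log_cpm(counts, factors)
  if (any(apply(lc, 2L, sd) == 0)) {
    abort("Constant expression within a sample; correlation undefined.",
          class = "cernet_format_error")
  }
  r <- cor(lc, method = "pearson")
  same <- outer(g[colnames(lc)], g[colnames(lc)], "==")
  off <- !diag(TRUE, ncol(lc))
  pca <- prcomp(t(lc), center = TRUE, scale. = FALSE)
  pv <- pca$sdev^2 / sum(pca$sdev^2)
  structure(
    list(
      pearson_r = r,
      pc_variance = pv,
      pc_scores = pca$x,
      within_group_median_r = median(r[same & off]),
      between_group_median_r = median(r[!same])
    ),
    class = "sample_qc"
  )
}

#' @export
print.sample_qc <- function(x, ...) {
  cat(sprintf(
    "<sample_qc> %d samples; median r within %.3f / between %.3f; PC1+PC2 = %.1f%% variance\n",
    ncol(x$pearson_r), x$within_group_median_r, x$between_group_median_r,
    100 * sum(x$pc_variance[1:min(2, length(x$pc_variance))])))
  invisible(x)
}

#' PCA plot of samples from QC results
#'
#' @param qc A `sample_qc` object.
#' @param groups Optional named group vector for colouring.
#' @return A ggplot object.
#' @export
plot_pca <- function(qc, groups = NULL) {
  d <- tibble(
    sample = rownames(qc$pc_scores),
    PC1 = qc$pc_scores[, 1L],
    PC2 = if (ncol(qc$pc_scores) >= 2L) qc$pc_scores[, 2L] else 0
  )
  d$group <- if (is.null(groups)) "sample" else unname(groups[d$sample])
  ggplot2::ggplot(d, ggplot2::aes(.data$PC1, .data$PC2,
                                  colour = .data$group)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * qc$pc_variance[1L]),
      y = sprintf("PC2 (%.1f%%)",
                  100 * ifelse(length(qc$pc_variance) > 1,
                               qc$pc_variance[2L], 0))) +
    ggplot2::theme_minimal()
}
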