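#' Gene-set over-representation analysis
#'
#' Hypergeometric (Fisher one-tail) or EASE-style over-representation of a
#' query gene list against a gene-set collection. Each set is first
#' intersected with the universe; sets with no member in the universe are
#' skipped. With `k` query hits in a set of size `K` (in a universe of `N`
#' genes, query size `n`):
#' \itemize{
#'   \item `hypergeometric`: p = P(X >= k), the upper hypergeometric tail;
#'   \item `ease`: the same tail evaluated at `k - 1` hits (one hit
#'     removed), the conservative DAVID variant; a single-hit set gets
#'     p = 1.
#' }
#' Fold enrichment is `(k/n) / (K/N)`. A record is flagged significant when
#' `p < p_max` and `fold_enrichment > fold_min` (defaults: P < 0.05,
#' fold > 5). BH FDR is added across all tested sets.
#'
#' @param query Character vector of query genes (must be a subset of
#'   `universe`).
#' @param universe Character vector: the analyzed-gene background.
#' @param collections Long tibble from [read_gmt()] (`set_id`,
#'   `description`, `gene`).
#' @param mode `"ease"` (default) or `"hypergeometric"`.
#' @param p_max,fold_min Significance gates.
#' @return Tibble of class `enrichment_result`, sorted by p-value, with
#'   columns `set_id`, `description`, `k`, `K`, `n`, `N`, `p_value`,
#'   `fold_enrichment`, `bh_fdr`, `significant`.
#' @export
enrich <- function(query, universe, collections,
                   mode = c("ease", "hypergeometric"),
                   p_max = 0.05, fold_min = 5) {
  mode <- match.arg(mode)
  query <- unique(query)
  universe <- unique(universe)
  stray <- setdiff(query, universe)
  if (length(stray)) {
    abort(sprintf("Query gene(s) not in the universe: %s",
                  paste(head(stray, 10L), collapse = ", ")),
          class = "cernet_usage_error")
  }
  N <- length(universe)
  n <- length(query)
  res <- collections |>
    filter(.data$gene %in% universe) |>
    group_by(.data$set_id, .data$description) |>
    summarise(
      K = dplyr::n_distinct(.data$gene),
      k = dplyr::n_distinct(intersect(.data$gene, query)),
      .groups = "drop"
    ) |>
    mutate(
      n = n, N = N,
      p_value = overrep_p(.data$k, .data$K, n, N, mode),
      fold_enrichment = ifelse(.data$k == 0, 0,
                               (.data$k / n) / (.data$K / N)),
      bh_fdr = p.adjust(.data$p_value, method = "BH"),
      significant = .data$p_value < p_max & .data$fold_enrichment > fold_min
    ) |>
    arrange(.data$p_value, .data$set_id) |>
    select("set_id", "description", "k", "K", "n", "N", "p_value",
           "fold_enrichment", "bh_fdr", "significant")
  class(res) <- c("enrichment_result", class(res))
  res
}

# vectorized upper-tail p for both modes
overrep_p <- function(k, K, n, N, mode) {
  k_eff <- if (mode == "ease") pmax(k - 1L, 0L) else k
  p <- phyper(k_eff - 1L, K, N - K, n, lower.tail = FALSE)
  p[k == 0] <- 1
  if (mode == "ease") p[k == 1L] <- 1
  pmin(p, 1)
}
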