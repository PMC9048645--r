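#' Trimmed mean of M-values (TMM) normalization factors
#'
#' Between-sample scaling factors for count data. For each sample a
#' log2 ratio M and average abundance A are computed per gene against a
#' reference sample (the column whose upper-quartile-to-library ratio is
#' closest to the across-sample mean); genes with a zero in either sample
#' are excluded, both tails of the M and A distributions are trimmed
#' (`trim_m` and `trim_a` per tail), and the factor is the precision-
#' weighted mean of the surviving M-values, with weights from the delta-
#' method (approximately inverse binomial) variance of M. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts A [count_tbl()].
#' @param trim_m Fraction trimmed from each tail of the M distribution.
#' @param trim_a Fraction trimmed from each tail of the A distribution.
#' @return Named numeric vector of per-sample factors (geometric mean 1).
#' @examples
#' df <- data.frame(g = paste0("g", 1:4),
#'                  a = c(10L, 20L, 30L, 40L), b = c(20L, 40L, 60L, 80L))
#' ct <- count_tbl(df, c(a = "x", b = "y"))
#' tmm_factors(ct)  # pure depth change: both factors 1
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- ct_matrix(counts)
  if (ncol(m) < 2L) {
    abort("TMM needs >= 2 samples.", class = "cernet_design_error")
  }
  lib <- colSums(m)
  zero <- lib == 0
  if (any(zero)) {
    abort(sprintf("Sample(s) with all-zero counts: %s",
                  paste(colnames(m)[zero], collapse = ", ")),
          class = "cernet_format_error")
  }
  uq <- apply(m, 2L, function(x) quantile(x, 0.75)) / lib
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(m)), function(k) {
    tmm_pair_factor(m[, k], m[, ref], lib[k], lib[ref], trim_m, trim_a)
  }, numeric(1L))
  f <- f / exp(mean(log(f)))
  setNames(f, colnames(m))
}

# One sample against the reference: weighted doubly-trimmed mean of M-values.
tmm_pair_factor <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (!length(obs)) return(1)
  p_o <- obs / n_obs
  p_r <- ref / n_ref
  M <- log2(p_o / p_r)
  A <- 0.5 * log2(p_o * p_r)
  # delta-method variance of M under binomial sampling
  w <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(M) & is.finite(A) & is.finite(w) & w > 0
  M <- M[fin]; A <- A[fin]; w <- w[fin]
  n <- length(M)
  if (n == 0L) return(1)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rM <- rank(M, ties.method = "first")
  rA <- rank(A, ties.method = "first")
  keep2 <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep2)) return(1)
  logf <- sum(M[keep2] / w[keep2]) / sum(1 / w[keep2])
  if (!is.finite(logf) || abs(logf) < 1e-6) logf <- 0
  2^logf
}

#' Log2 counts per million
#'
#' `log2((count + prior) / (effective library size / 1e6))`, with the
#' effective library size being the raw library size times its TMM factor.
#'
#' @param counts A [count_tbl()].
#' @param factors Per-sample normalization factors from [tmm_factors()];
#'   computed if `NULL`.
#' @param prior Pseudo-count added to every cell before the log.
#' @return Numeric matrix (genes x samples) of log2 CPM values.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  m <- ct_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  factors <- factors[colnames(m)]
  eff <- colSums(m) * factors
  if (any(!is.finite(eff) | eff <= 0)) {
    abort("Non-positive effective library size.",
          class = "cernet_format_error")
  }
  out <- log2(sweep(m + prior, 2L, eff / 1e6, "/"))
  dimnames(out) <- dimnames(m)
  out
}
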