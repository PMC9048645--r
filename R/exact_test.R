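#' Exact negative-binomial test for a two-group count split
#'
#' Conditional exact test of equal means between two groups of counts
#' sharing a common NB dispersion, assuming equal effective library sizes
#' (see [equalize_libraries()]). The group sums are NB distributed
#' (sum of n iid NB(mu, phi) is NB(n*mu, phi/n)); conditioning on the total
#' gives a discrete distribution over the possible splits, and the
#' two-sided p-value is the total probability of all splits at most as
#' probable as the observed one (the "method of small p-values"). At
#' `dispersion = 0` the NB degenerates to Poisson and the conditional law
#' is binomial, reproducing the exact binomial split test.
#'
#' @param counts_a,counts_b Integer count vectors for the two groups
#'   (library-equalized pseudo-counts).
#' @param dispersion Common NB dispersion phi >= 0
#'   (variance = mu + phi * mu^2).
#' @return Two-sided p-value in (0, 1].
#' @examples
#' nb_exact_test(c(5, 5, 5), c(5, 5, 5), 0.1)  # symmetric split: p = 1
#' @export
nb_exact_test <- function(counts_a, counts_b, dispersion) {
  if (dispersion < 0) {
    abort("`dispersion` must be >= 0.", class = "cernet_usage_error")
  }
  a <- sum(counts_a); b <- sum(counts_b)
  n_a <- length(counts_a); n_b <- length(counts_b)
  s <- a + b
  if (s == 0) return(1)  # no evidence either way
  x <- 0:s
  lp <- split_log_prob(x, s, n_a, n_b, dispersion)
  lp_obs <- lp[a + 1L]
  # relative tolerance guards against ties lost to floating-point noise
  p <- sum(exp(lp[lp <= lp_obs + 1e-8])) / sum(exp(lp))
  min(p, 1)
}

# log joint probability of (x, s - x) as the group sums, up to a constant
split_log_prob <- function(x, s, n_a, n_b, phi) {
  mu <- s / (n_a + n_b)
  if (phi == 0) {
    dpois(x, n_a * mu, log = TRUE) + dpois(s - x, n_b * mu, log = TRUE)
  } else {
    dnbinom(x, size = n_a / phi, mu = n_a * mu, log = TRUE) +
      dnbinom(s - x, size = n_b / phi, mu = n_b * mu, log = TRUE)
  }
}

#' Scale counts to a common effective library size
#'
#' Rescales every sample to the geometric mean of the effective library
#' sizes (raw library x TMM factor) and rounds to the nearest integer,
#' yielding pseudo-counts on which the equal-library exact test applies.
#'
#' @param counts A [count_tbl()].
#' @param factors Normalization factors from [tmm_factors()]; computed if
#'   `NULL`.
#' @return Integer matrix of pseudo-counts with the common library size in
#'   attribute `"common_lib"`.
#' @export
equalize_libraries <- function(counts, factors = NULL) {
  m <- ct_matrix(counts)
  if (is.null(factors)) factors <- tmm_factors(counts)
  eff <- colSums(m) * factors[colnames(m)]
  common <- exp(mean(log(eff)))
  out <- round(sweep(m, 2L, common / eff, "*"))
  attr(out, "common_lib") <- common
  out
}

#' Estimate the common NB dispersion by conditional maximum likelihood
#'
#' Maximizes the conditional (qCML-style) log-likelihood of the
#' library-equalized pseudo-counts, summed over genes and groups, by a
#' bounded one-dimensional search on log(phi). Conditioning on each
#' group's sum removes the per-gene mean, leaving a likelihood in the
#' dispersion alone:
#' `sum_i lgamma(y_i + r) - lgamma(z + n*r) + lgamma(n*r) - n*lgamma(r)`
#' where r is the inverse dispersion 1/phi, n the group size and z the
#' group sum.
#'
#' @param counts A [count_tbl()].
#' @param groups Optional two group labels to use (defaults to all groups;
#'   each needs >= 2 samples).
#' @param interval Search interval for phi.
#' @return Estimated dispersion phi (scalar).
#' @export
estimate_common_dispersion <- function(counts, groups = NULL,
                                       interval = c(1e-6, 5)) {
  g <- sample_groups(counts)
  if (!is.null(groups)) g <- g[g %in% groups]
  split_samples <- split(names(g), g)
  if (any(lengths(split_samples) < 2L)) {
    abort("Common-dispersion estimation needs >= 2 samples per group.",
          class = "cernet_design_error")
  }
  pseudo <- equalize_libraries(counts)
  pseudo <- pseudo[, unlist(split_samples, use.names = FALSE), drop = FALSE]
  keep <- rowSums(pseudo) > 0
  pseudo <- pseudo[keep, , drop = FALSE]
  if (nrow(pseudo) == 0L) {
    abort("No genes with positive counts.", class = "cernet_format_error")
  }
  nll <- function(log_phi) {
    r <- 1 / exp(log_phi)
    ll <- 0
    for (samples in split_samples) {
      y <- pseudo[, samples, drop = FALSE]
      n <- length(samples)
      z <- rowSums(y)
      ll <- ll + sum(rowSums(lgamma(y + r)) - lgamma(z + n * r) +
                       lgamma(n * r) - n * lgamma(r))
    }
    -ll
  }
  opt <- optimize(nll, interval = log(interval))
  exp(opt$minimum)
}
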