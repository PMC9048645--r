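test_that("TMM factors are exact on identity and pure depth-change designs", {
  m <- matrix(c(10L, 20L, 30L, 40L, 10L, 20L, 30L, 40L), ncol = 2)
  expect_equal(unname(tmm_factors(make_ct(m))), c(1, 1))

  m2 <- cbind(a = c(10L, 20L, 30L, 40L), b = c(20L, 40L, 60L, 80L))
  expect_equal(unname(tmm_factors(make_ct(m2))), c(1, 1))

  zero <- cbind(a = c(1L, 2L), b = c(0L, 0L))
  expect_error(tmm_factors(make_ct(zero)), regexp = "b",
               class = "cernet_format_error")
})

test_that("TMM matches a direct weighted trimmed-mean computation on a toy matrix", {
  # 5 genes, one strongly inflated in sample b; trim keeps the middle
  # M-ranks, factor = weighted mean of surviving M-values
  a <- c(100L, 200L, 300L, 400L, 500L)
  b <- c(110L, 190L, 310L, 390L, 5000L)
  ct <- make_ct(cbind(a = a, b = b), c(a = "x", b = "y"))
  f <- tmm_factors(ct)

  # oracle: evaluate the definition directly (b against reference a)
  na <- sum(a); nb <- sum(b)
  M <- log2((b / nb) / (a / na))
  A <- 0.5 * log2((b / nb) * (a / na))
  w <- (nb - b) / (nb * b) + (na - a) / (na * a)
  n <- length(M)
  keep_m <- rank(M, ties.method = "first")
  keep_m <- keep_m >= floor(n * 0.3) + 1 & keep_m <= n + 1 - (floor(n * 0.3) + 1)
  keep_a <- rank(A, ties.method = "first")
  keep_a <- keep_a >= floor(n * 0.05) + 1 & keep_a <= n + 1 - (floor(n * 0.05) + 1)
  keep <- keep_m & keep_a
  f_b <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  expected <- c(1 / sqrt(f_b), f_b / sqrt(f_b))  # geometric-mean rescale

  # reference selection must have picked sample a (uninflated quartile)
  expect_equal(unname(f), expected, tolerance = 1e-10)
})

test_that("TMM agrees with edgeR on random matrices and is order-invariant", {
  skip_if_not_installed("edgeR")
  set.seed(101)
  for (i in 1:5) {
    m <- matrix(rnbinom(200 * 4, mu = 150, size = 3), ncol = 4)
    m[m == 0] <- 1L
    colnames(m) <- paste0("s", 1:4)
    f_pkg <- tmm_factors(make_ct(m))
    f_ref <- edgeR::calcNormFactors(edgeR::DGEList(counts = m),
                                    method = "TMM")$samples$norm.factors
    expect_equal(unname(f_pkg), f_ref, tolerance = 1e-8)
    # gene order invariance
    perm <- sample.int(nrow(m))
    expect_equal(unname(tmm_factors(make_ct(m[perm, ]))), unname(f_pkg),
                 tolerance = 1e-12)
    # geometric mean is 1
    expect_equal(exp(mean(log(f_pkg))), 1, tolerance = 1e-12)
  }
})

test_that("logCPM follows its defining formula", {
  m <- cbind(a = c(0L, 10L), b = c(5L, 20L))
  # pad so each library is exactly 1e6
  ct <- make_ct(rbind(m, c(999990L, 999975L)), c(a = "x", b = "y"))
  lc <- log_cpm(ct, factors = c(a = 1, b = 1), prior = 0.5)
  # count 0, library 1e6, factor 1, prior 0.5 -> log2(0.5) = -1
  expect_equal(lc[1, 1], log2(0.5), tolerance = 1e-12)
  expect_equal(lc[2, 2], log2(20.5), tolerance = 1e-12)

  # doubling counts and library together leaves logCPM unchanged at prior 0
  m1 <- cbind(a = c(10L, 90L))
  m2 <- cbind(a = c(20L, 180L))
  ct1 <- count_tbl(data.frame(gene_id = c("g1", "g2"), m1, b = c(5L, 95L)),
                   c(a = "x", b = "y"))
  ct2 <- count_tbl(data.frame(gene_id = c("g1", "g2"), m2, b = c(5L, 95L)),
                   c(a = "x", b = "y"))
  l1 <- log_cpm(ct1, factors = c(a = 1, b = 1), prior = 0)
  l2 <- log_cpm(ct2, factors = c(a = 1, b = 1), prior = 0)
  expect_equal(l1[, "a"], l2[, "a"], tolerance = 1e-12)
})

test_that("exact NB test: symmetric splits, binomial limit, enumeration oracle", {
  # symmetric split is the most probable outcome
  expect_equal(nb_exact_test(c(5, 5, 5), c(5, 5, 5), 0.1), 1)
  expect_equal(nb_exact_test(0, 0, 0.2), 1)  # no evidence

  # phi = 0 with all counts in one group equals the two-sided binomial test
  p_pkg <- nb_exact_test(10, 0, 0)
  probs <- dbinom(0:10, 10, 0.5)
  p_binom <- sum(probs[probs <= probs[11] * (1 + 1e-8)])
  expect_equal(p_pkg, p_binom, tolerance = 1e-12)

  # small totals: equals the convolution-built conditional distribution
  set.seed(7)
  for (i in 1:20) {
    na <- sample(2:3, 1); nb <- sample(2:3, 1)
    a <- rpois(na, 4); b <- rpois(nb, 4)
    if (sum(a, b) == 0 || sum(a, b) > 50) next
    phi <- sample(c(0, 0.05, 0.3, 1), 1)
    expect_equal(nb_exact_test(a, b, phi), oracle_nb_exact_p(a, b, phi),
                 tolerance = 1e-10,
                 info = sprintf("case %d: phi=%g", i, phi))
  }

  expect_error(nb_exact_test(1, 1, -0.1), class = "cernet_usage_error")
})

test_that("exact NB test matches edgeR under equal libraries", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  m <- matrix(rnbinom(300, mu = 50, size = 10), nrow = 50)
  colnames(m) <- paste0("s", 1:6)
  d <- edgeR::DGEList(counts = m, group = rep(c("A", "B"), each = 3))
  d$samples$lib.size <- rep(1e5, 6)
  d$samples$norm.factors <- rep(1, 6)
  p_ref <- edgeR::exactTest(d, dispersion = 0.1)$table$PValue
  p_pkg <- vapply(1:50, function(i) nb_exact_test(m[i, 1:3], m[i, 4:6], 0.1),
                  numeric(1))
  expect_equal(p_pkg, p_ref, tolerance = 1e-10)
})

test_that("common dispersion is recovered from simulated data", {
  # Poisson data: estimate collapses toward the lower bound
  set.seed(21)
  phis <- replicate(5, {
    m <- matrix(rpois(1000 * 6, lambda = 100), ncol = 6)
    colnames(m) <- paste0("s", 1:6)
    estimate_common_dispersion(make_ct(m))
  })
  expect_lt(mean(phis), 0.01)

  # phi = 0.2 data: estimate lands in [0.1, 0.3]
  set.seed(22)
  phis2 <- replicate(5, {
    m <- matrix(rnbinom(1000 * 6, mu = 100, size = 5), ncol = 6)
    colnames(m) <- paste0("s", 1:6)
    estimate_common_dispersion(make_ct(m))
  })
  expect_gt(mean(phis2), 0.1)
  expect_lt(mean(phis2), 0.3)

  # identical replicate columns: estimate hits the lower search bound
  m <- matrix(rep(c(10L, 50L, 200L, 1000L), 4), ncol = 4)
  colnames(m) <- paste0("s", 1:4)
  expect_lt(estimate_common_dispersion(make_ct(m)), 1e-5)

  # no replication is an error
  m2 <- cbind(a = c(1L, 2L), b = c(3L, 4L))
  expect_error(estimate_common_dispersion(make_ct(m2, c(a = "A", b = "B"))),
               class = "cernet_design_error")
})

test_that("DEG status applies the FDR and logFC thresholds strictly", {
  # classification rule applied to a hand-built table via the same gates
  cfg <- pipeline_config()
  classify <- function(fdr, logfc) {
    dplyr::case_when(
      fdr < cfg$deg_fdr_max & logfc > cfg$deg_abs_logfc_min ~ "up",
      fdr < cfg$deg_fdr_max & logfc < -cfg$deg_abs_logfc_min ~ "down",
      TRUE ~ "ns")
  }
  expect_equal(classify(0.04, 1.2), "up")
  expect_equal(classify(0.04, 0.9), "ns")
  expect_equal(classify(0.06, 3.0), "ns")
  expect_equal(classify(0.04, -1.2), "down")

  # end to end: genes sitting exactly on either side of the gates
  sim <- simulate_counts(sim_params(n_genes = 300, seed = 33))
  deg <- suppressMessages(call_degs(sim$counts))
  tab <- tidy(deg)
  expect_true(all(tab$status[tab$fdr < 0.05 & tab$logFC > 1] == "up"))
  expect_true(all(tab$status[tab$fdr >= 0.05] == "ns"))
  expect_true(all(tab$fdr >= tab$p_value - 1e-12))
})

test_that("DEG table is invariant to sample order", {
  sim <- simulate_counts(sim_params(n_genes = 200, seed = 14))
  ct <- sim$counts
  g <- sample_groups(ct)
  perm <- sample(names(g))
  ct2 <- count_tbl(tibble::as_tibble(ct)[, c("gene_id", perm)], g[perm])
  t1 <- tidy(suppressMessages(call_degs(ct)))
  t2 <- tidy(suppressMessages(call_degs(ct2)))
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("BH adjustment is monotone and bounded", {
  sim <- simulate_counts(sim_params(n_genes = 500, seed = 9))
  tab <- tidy(suppressMessages(call_degs(sim$counts)))
  ord <- order(tab$p_value)
  expect_true(all(diff(tab$fdr[ord]) >= -1e-12))
  expect_lte(max(tab$fdr), 1)
  # single-test case: fdr equals p
  expect_equal(p.adjust(0.031, "BH"), 0.031)
})

test_that("sample QC yields valid correlations and PCA variance fractions", {
  sim <- simulate_counts(sim_params(n_genes = 300, seed = 4))
  qc <- sample_qc(sim$counts)
  r <- qc$pearson_r
  expect_equal(r, t(r))
  expect_equal(unname(diag(r)), rep(1, ncol(r)))
  expect_true(all(r >= -1 & r <= 1))
  expect_equal(sum(qc$pc_variance), 1, tolerance = 1e-9)
  expect_true(all(diff(qc$pc_variance) <= 1e-12))  # non-increasing

  # pc_variance matches the eigendecomposition of the sample covariance
  lc <- log_cpm(sim$counts)
  cc <- scale(t(lc), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(cc), symmetric = TRUE)$values
  ev <- ev[ev > 1e-10]
  expect_equal(qc$pc_variance[seq_along(ev)], ev / sum(ev),
               tolerance = 1e-8)

  # duplicated sample columns correlate at 1
  m <- ct_dup <- tibble::as_tibble(sim$counts)
  m$OE_2 <- m$OE_1
  ct2 <- count_tbl(m, sample_groups(sim$counts))
  qc2 <- sample_qc(ct2)
  expect_equal(qc2$pearson_r["OE_1", "OE_2"], 1, tolerance = 1e-12)

  # three distinct samples duplicated pairwise: centred logCPM has rank
  # <= 2, so PC1 + PC2 must carry all the variance
  m3 <- tibble::as_tibble(sim$counts)[, 1:4]
  m3$s5 <- m3[[2]]
  m3$s6 <- m3[[3]]
  ct3 <- count_tbl(m3, setNames(rep_len(c("A", "B"), ncol(m3) - 1L),
                                names(m3)[-1]))
  qc3 <- sample_qc(ct3)
  expect_equal(sum(qc3$pc_variance[1:2]), 1, tolerance = 1e-9)

  expect_error(sample_qc(make_ct(cbind(a = 1L, b = 2L),
                                 c(a = "A", b = "B"))),
               class = "cernet_design_error")
})

test_that("null exact-test p-values are valid at nominal levels", {
  sim <- simulate_counts(sim_params(seed = 11, de_fraction = 0))
  tab <- tidy(suppressMessages(call_degs(sim$counts)))
  n <- nrow(tab)
  for (alpha in c(0.01, 0.05)) {
    mc <- sqrt(alpha * (1 - alpha) / n)
    expect_lte(mean(tab$p_value <= alpha), alpha + 2 * mc)
  }
  # two exchangeable groups: DEG count stays near the type-I level
  expect_lte(sum(tab$status != "ns"), ceiling(0.01 * n))
})
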