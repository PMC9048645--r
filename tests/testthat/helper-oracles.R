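# Independent oracles used to validate the package's implementations.
# Each deliberately takes a different computational route from the code
# under test (enumeration, convolution, brute-force path counting).

# Build a count_tbl from a bare matrix.
make_ct <- function(m, groups = NULL) {
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  if (is.null(groups)) {
    half <- ncol(m) / 2
    groups <- stats::setNames(rep(c("A", "B"), times = c(half, ncol(m) - half)),
                              colnames(m))
  }
  df <- data.frame(gene_id = paste0("g", seq_len(nrow(m))), m,
                   check.names = FALSE)
  count_tbl(df, groups)
}

# Exact pmf of the sum of n iid NB(mu, phi) variables by explicit
# convolution of the per-sample pmfs (never uses the closed-form
# aggregation identity the implementation relies on).
oracle_group_sum_pmf <- function(n, mu, phi, upto) {
  x <- 0:upto
  pmf1 <- if (phi == 0) dpois(x, mu) else dnbinom(x, size = 1 / phi, mu = mu)
  out <- pmf1
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      new <- numeric(upto + 1)
      for (s in 0:upto) {
        new[s + 1] <- sum(out[seq_len(s + 1)] * pmf1[s + 1 - (0:s)])
      }
      out <- new
    }
  }
  out
}

# Conditional two-sided exact p for the observed split, built entirely
# from the convolution pmfs above.
oracle_nb_exact_p <- function(counts_a, counts_b, phi) {
  a <- sum(counts_a); b <- sum(counts_b); s <- a + b
  n_a <- length(counts_a); n_b <- length(counts_b)
  mu <- s / (n_a + n_b)
  pa <- oracle_group_sum_pmf(n_a, mu, phi, s)
  pb <- oracle_group_sum_pmf(n_b, mu, phi, s)
  joint <- pa[1:(s + 1)] * rev(pb[1:(s + 1)])  # P(A = x) P(B = s - x)
  obs <- joint[a + 1]
  sum(joint[joint <= obs * (1 + 1e-8)]) / sum(joint)
}

# Hypergeometric upper-tail p by full enumeration of all C(N, n) draws.
oracle_hyper_p <- function(k, K, n, N) {
  universe <- seq_len(N)
  hits <- seq_len(K)
  draws <- utils::combn(N, n)
  tally <- apply(draws, 2, function(d) sum(d %in% hits))
  mean(tally >= k)
}

# Betweenness by brute-force enumeration of all simple paths between
# every vertex pair; counts shortest paths through each interior vertex.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  btw <- numeric(n)
  all_paths <- function(from, to) {
    paths <- list()
    walk <- function(v, visited) {
      if (v == to) {
        paths[[length(paths) + 1]] <<- visited
        return(invisible())
      }
      for (w in which(adj[v, ] == 1)) {
        if (!w %in% visited) walk(w, c(visited, w))
      }
    }
    walk(from, from)
    paths
  }
  for (s in 1:(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (!length(paths)) next
      lens <- lengths(paths)
      shortest <- paths[lens == min(lens)]
      for (v in setdiff(seq_len(n), c(s, t))) {
        through <- vapply(shortest, function(p) v %in% p, logical(1))
        btw[v] <- btw[v] + sum(through) / length(shortest)
      }
    }
  }
  btw
}

# Random simple graph as a symmetric 0/1 adjacency matrix.
random_adjacency <- function(n, p_edge = 0.4) {
  adj <- matrix(0L, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p_edge) adj[i, j] <- adj[j, i] <- 1L
    }
  }
  adj
}

adj_to_edges <- function(adj, names = NULL) {
  if (is.null(names)) names <- sprintf("v%02d", seq_len(nrow(adj)))
  idx <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  tibble::tibble(node_a = names[idx[, 1]], node_b = names[idx[, 2]],
                 score = 0.95)
}

# A tiny deterministic prediction set for ceRNA unit tests.
toy_predictions <- function() {
  circ_mir <- tibble::tibble(
    circ_id = c("c1", "c1", "c2", "c2", "c3"),
    mirna_id = c("m1", "m2", "m1", "m3", "m2"),
    percentile = c(95, 92, 91, 89, 97)
  )
  dbs <- c("miRWalk", "MicroT4", "miRanda", "miRDB", "PITA", "RNA22")
  full <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3"),
    gene_id = c("gA", "gB", "gA", "gC")
  )
  per_db <- stats::setNames(lapply(dbs, function(s) full), dbs)
  list(circ_mir = circ_mir, per_db_targets = per_db)
}
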