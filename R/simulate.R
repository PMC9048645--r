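#' Simulation parameters
#'
#' Conditions for the synthetic-data generators, defaulting to a
#' desk-scale version of the 3-vs-3 overexpression design the package
#' targets: 2000 genes, three samples per group, 5% of genes
#' differentially expressed at |log2FC| = 2, NB dispersion 0.1
#' (variance = mu + phi * mu^2, the edgeR convention), library sizes of
#' 0.8-1.2 million reads, 13 circRNAs, 56 candidate miRNAs and ~40 true
#' targets per miRNA with a 90% per-source reporting probability across
#' the six prediction databases.
#'
#' @param n_genes Number of genes.
#' @param n_per_group Samples per group (>= 2; the design needs
#'   replication for dispersion estimation).
#' @param de_fraction Fraction of genes with a planted effect.
#' @param de_log2fc Planted absolute log2 fold change (half up, half
#'   down).
#' @param nb_dispersion NB dispersion phi >= 0.
#' @param lib_size_range Two positive integers: min/max library size.
#' @param n_circ Number of circRNAs.
#' @param n_mirna Number of miRNAs.
#' @param n_targets_per_mirna True targets drawn per miRNA.
#' @param db_agreement Probability that a true target is reported by any
#'   one of the six sources.
#' @param seed Integer master seed.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000L, n_per_group = 3L,
                       de_fraction = 0.05, de_log2fc = 2,
                       nb_dispersion = 0.1,
                       lib_size_range = c(8e5, 1.2e6),
                       n_circ = 13L, n_mirna = 56L,
                       n_targets_per_mirna = 40L,
                       db_agreement = 0.9, seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            n_per_group = as.integer(n_per_group),
            de_fraction = de_fraction, de_log2fc = de_log2fc,
            nb_dispersion = nb_dispersion,
            lib_size_range = as.numeric(lib_size_range),
            n_circ = as.integer(n_circ), n_mirna = as.integer(n_mirna),
            n_targets_per_mirna = as.integer(n_targets_per_mirna),
            db_agreement = db_agreement, seed = as.integer(seed))
  if (p$de_fraction < 0 || p$de_fraction > 1 ||
      p$db_agreement < 0 || p$db_agreement > 1) {
    abort("`de_fraction` and `db_agreement` must lie in [0, 1].",
          class = "cernet_usage_error")
  }
  if (p$nb_dispersion < 0) {
    abort("`nb_dispersion` must be >= 0.", class = "cernet_usage_error")
  }
  if (any(p$lib_size_range < 1) || diff(p$lib_size_range) < 0) {
    abort("`lib_size_range` must be an increasing pair of positive sizes.",
          class = "cernet_usage_error")
  }
  if (p$n_genes < 1 || p$n_circ < 1 || p$n_mirna < 1) {
    abort("Counts must be >= 1.", class = "cernet_usage_error")
  }
  structure(p, class = "sim_params")
}

new_ground_truth <- function(de_genes_up = character(),
                             de_genes_down = character(),
                             planted_ppi_hubs = character(),
                             planted_top_mirna = NA_character_,
                             planted_hub_genes = character(),
                             true_targets = NULL) {
  structure(list(de_genes_up = de_genes_up, de_genes_down = de_genes_down,
                 planted_ppi_hubs = planted_ppi_hubs,
                 planted_top_mirna = planted_top_mirna,
                 planted_hub_genes = planted_hub_genes,
                 true_targets = true_targets),
            class = "ground_truth")
}

#' Simulate a two-group NB count matrix with planted effects
#'
#' Gene abundances are log-normal; library sizes are uniform over
#' `lib_size_range`; counts are NB(mu, phi) with
#' variance = mu + phi * mu^2 (Poisson when phi = 0). A `de_fraction` of
#' genes carries a planted effect: the treatment-group mean is multiplied
#' by `2^(+de_log2fc)` (up half) or `2^(-de_log2fc)` (down half).
#'
#' @param params A [sim_params()].
#' @return List with `counts` (a [count_tbl()], groups `OE` and `ctrl`)
#'   and `truth` (a `ground_truth` with `de_genes_up` / `de_genes_down`).
#' @export
simulate_counts <- function(params = sim_params()) {
  if (params$n_per_group < 2L) {
    abort("Need >= 2 samples per group (dispersion is not estimable otherwise).",
          class = "cernet_design_error")
  }
  set.seed(derive_seed(params$seed, 1L))
  ng <- params$n_genes
  npg <- params$n_per_group
  genes <- sprintf("gene_%05d", seq_len(ng))
  w <- stats::rlnorm(ng, meanlog = 0, sdlog = 1.2)
  p_g <- w / sum(w)
  n_de <- round(params$de_fraction * ng)
  de_idx <- sample.int(ng, n_de)
  up_idx <- de_idx[seq_len(ceiling(n_de / 2))]
  down_idx <- setdiff(de_idx, up_idx)
  fc <- rep(1, ng)
  fc[up_idx] <- 2^params$de_log2fc
  fc[down_idx] <- 2^(-params$de_log2fc)

  samples <- c(sprintf("OE_%d", seq_len(npg)),
               sprintf("ctrl_%d", seq_len(npg)))
  groups <- setNames(rep(c("OE", "ctrl"), each = npg), samples)
  lib <- round(runif(2 * npg, params$lib_size_range[1L],
                     params$lib_size_range[2L]))
  counts <- matrix(0L, nrow = ng, ncol = 2 * npg,
                   dimnames = list(genes, samples))
  for (j in seq_len(2 * npg)) {
    mult <- if (groups[j] == "OE") fc else rep(1, ng)
    mu <- p_g * mult
    mu <- mu / sum(mu) * lib[j]  # renormalize so the library size holds
    counts[, j] <- if (params$nb_dispersion == 0) {
      rpois(ng, mu)
    } else {
      rnbinom(ng, size = 1 / params$nb_dispersion, mu = mu)
    }
  }
  ct <- count_tbl(
    tibble(gene_id = genes) |> dplyr::bind_cols(as_tibble(counts)),
    groups)
  list(
    counts = ct,
    truth = new_ground_truth(de_genes_up = genes[up_idx],
                             de_genes_down = genes[down_idx]),
    base_abundance = setNames(p_g, genes)
  )
}

#' Simulate a scored PPI edge list with planted hubs
#'
#' Background edges are drawn uniformly over unordered node pairs;
#' planted hubs are then wired to random partners until their degree
#' exceeds both three times the background median degree and the maximum
#' background degree plus the number of hubs, so the hubs deterministically
#' occupy the top degree ranks. Each edge's combined score falls in
#' \[0.9, 1\] with probability `frac_pass` and in \[0.4, 0.9) otherwise.
#'
#' @param n_nodes Number of nodes (ignored if `nodes` given).
#' @param n_edges Number of background edges
#'   (<= `n_nodes * (n_nodes - 1) / 2`).
#' @param planted_hubs Number of planted high-degree nodes.
#' @param frac_pass Probability an edge scores >= 0.9.
#' @param nodes Optional character vector of node names.
#' @param seed Integer seed.
#' @return List with `edges` (tibble `node_a`, `node_b`, `score`),
#'   `nodes` (all node names) and `truth` (`planted_ppi_hubs`).
#' @export
simulate_ppi <- function(n_nodes = 100L, n_edges = 300L, planted_hubs = 0L,
                         frac_pass = 0.8, nodes = NULL, seed = 1L) {
  if (!is.null(nodes)) n_nodes <- length(nodes)
  n_nodes <- as.integer(n_nodes)
  max_edges <- n_nodes * (n_nodes - 1) / 2
  if (n_edges > max_edges) {
    abort(sprintf("n_edges (%d) exceeds the %d possible pairs.",
                  n_edges, max_edges), class = "cernet_usage_error")
  }
  if (planted_hubs > n_nodes) {
    abort("planted_hubs cannot exceed n_nodes.",
          class = "cernet_usage_error")
  }
  set.seed(derive_seed(seed, 2L))
  if (is.null(nodes)) nodes <- sprintf("node_%04d", seq_len(n_nodes))
  pair_id <- sample.int(max_edges, n_edges)
  # unrank an unordered pair (a < b) from its index in the lower triangle
  b <- ceiling((1 + sqrt(1 + 8 * pair_id)) / 2)
  a <- pair_id - (b - 1) * (b - 2) / 2
  bad <- a < 1          # floating-point guard at block boundaries
  b[bad] <- b[bad] - 1
  a[bad] <- pair_id[bad] - (b[bad] - 1) * (b[bad] - 2) / 2
  bad <- a >= b
  b[bad] <- b[bad] + 1
  a[bad] <- pair_id[bad] - (b[bad] - 1) * (b[bad] - 2) / 2
  edges <- distinct(tibble(i = a, j = b))
  hubs <- if (planted_hubs > 0) sample(nodes, planted_hubs) else character()
  deg <- tabulate(c(edges$i, edges$j), nbins = n_nodes)
  if (planted_hubs > 0) {
    med <- max(median(deg), 1)
    target <- max(ceiling(3 * med), max(deg) + planted_hubs + 1)
    for (h in match(hubs, nodes)) {
      have <- unique(c(edges$j[edges$i == h], edges$i[edges$j == h]))
      need <- target - length(have)
      if (need > 0) {
        partners <- sample(setdiff(seq_len(n_nodes), c(h, have)),
                           min(need, n_nodes - 1 - length(have)))
        edges <- bind_rows(edges,
                           tibble(i = pmin(h, partners),
                                  j = pmax(h, partners)))
      }
    }
    edges <- distinct(edges)
  }
  pass <- runif(nrow(edges)) < frac_pass
  score <- ifelse(pass, runif(nrow(edges), 0.9, 1),
                  runif(nrow(edges), 0.4, 0.8999))
  out <- tibble(node_a = nodes[edges$i], node_b = nodes[edges$j],
                score = round(score, 4)) |>
    mutate(lo = pmin(.data$node_a, .data$node_b),
           hi = pmax(.data$node_a, .data$node_b)) |>
    select(node_a = "lo", node_b = "hi", "score") |>
    arrange(.data$node_a, .data$node_b)
  list(edges = out, nodes = nodes,
       truth = new_ground_truth(planted_ppi_hubs = hubs))
}

#' Simulate circRNA--miRNA pairs and six miRNA-target prediction tables
#'
#' Emulates the prediction inputs of a ceRNA analysis with a known truth:
#' every miRNA receives a true target set; each true (miRNA, target) pair
#' is reported by each of the six sources independently with probability
#' `db_agreement`; decoy pairs are reported by at most five sources (a
#' random subset of size Binomial(5, db_agreement / 2)), so at
#' `db_agreement = 1` the six-way consensus equals the planted truth
#' exactly. The circRNA--miRNA table carries percentile scores; pairs
#' involving planted miRNAs score >= 90 by construction, background pairs
#' draw their percentile uniformly from \[50, 100\].
#'
#' The planted structure follows `truth`: `planted_top_mirna` targets all
#' `planted_hub_genes` plus extra genes (so it has the largest target
#' fan-out), and four further "partner" miRNAs also target every planted
#' hub gene, giving each hub gene at least five miRNA partners that all
#' pair with circRNAs above the percentile cut-off.
#'
#' @param params A [sim_params()].
#' @param truth A `ground_truth` carrying `planted_top_mirna` and
#'   `planted_hub_genes`; `de_genes_up` (plus `extra_pool`) supplies the
#'   pool for the top miRNA's extra targets.
#' @param gene_universe Character vector of gene IDs targets are drawn
#'   from.
#' @param extra_pool Optional genes favoured as extra targets of the top
#'   miRNA (defaults to `truth$de_genes_up`).
#' @return List of class `prediction_set`: `circ_mir` (tibble `circ_id`,
#'   `mirna_id`, `percentile`), `per_db_targets` (named list of six
#'   tibbles `mirna_id`, `gene_id`), `circ_ids`, `mirna_ids`, and the
#'   updated `truth` (with `true_targets`).
#' @export
simulate_predictions <- function(params, truth, gene_universe,
                                 extra_pool = NULL) {
  if (is.na(truth$planted_top_mirna) &&
      length(truth$planted_hub_genes) == 0L) {
    # allow fully unplanted use, but require explicit NA awareness
    truth$planted_top_mirna <- NA_character_
  }
  set.seed(derive_seed(params$seed, 3L))
  circ_ids <- sprintf("circ_%03d", seq_len(params$n_circ))
  mirna_ids <- sprintf("mir_%03d", seq_len(params$n_mirna))
  top_mir <- truth$planted_top_mirna
  if (!is.na(top_mir) && !top_mir %in% mirna_ids) {
    mirna_ids[1L] <- top_mir
  }
  hubs <- truth$planted_hub_genes
  if (length(setdiff(hubs, gene_universe))) {
    abort("planted_hub_genes must be drawn from `gene_universe`.",
          class = "cernet_usage_error")
  }
  partners <- character()
  if (!is.na(top_mir) && length(hubs)) {
    partners <- head(setdiff(mirna_ids, top_mir), 4L)
  }
  planted_mirs <- c(if (!is.na(top_mir)) top_mir, partners)

  if (is.null(extra_pool)) extra_pool <- truth$de_genes_up
  extra_pool <- setdiff(extra_pool, hubs)

  # true target sets
  true_targets <- purrr::map(setNames(mirna_ids, mirna_ids), function(m) {
    base <- sample(setdiff(gene_universe, hubs),
                   min(params$n_targets_per_mirna,
                       length(gene_universe) - length(hubs)))
    if (m %in% planted_mirs) base <- c(hubs, base)
    if (!is.na(top_mir) && m == top_mir && length(extra_pool)) {
      base <- c(base, sample(extra_pool, min(5L, length(extra_pool))))
    }
    unique(base)
  })
  tt_tbl <- purrr::imap(true_targets, function(g, m) {
    tibble(mirna_id = m, gene_id = g)
  }) |> bind_rows() |> arrange(.data$mirna_id, .data$gene_id)

  # circRNA-miRNA pairs
  cm <- purrr::map(mirna_ids, function(m) {
    n_pair <- sample(1:3, 1L)
    circs <- sample(circ_ids, n_pair)
    perc <- if (m %in% planted_mirs) {
      runif(n_pair, 90, 100)
    } else {
      runif(n_pair, 50, 100)
    }
    tibble(circ_id = circs, mirna_id = m, percentile = round(perc, 2))
  }) |> bind_rows() |> arrange(.data$circ_id, .data$mirna_id)

  # six prediction sources
  sources <- c("miRWalk", "MicroT4", "miRanda", "miRDB", "PITA", "RNA22")
  decoys <- purrr::map(setNames(mirna_ids, mirna_ids), function(m) {
    pool <- setdiff(gene_universe, c(true_targets[[m]], hubs))
    sample(pool, min(ceiling(params$n_targets_per_mirna / 2), length(pool)))
  })
  per_db <- setNames(vector("list", 6L), sources)
  rows_true <- purrr::imap(true_targets, function(g, m) {
    if (!length(g)) return(NULL)
    keep <- matrix(runif(length(g) * 6L) < params$db_agreement,
                   nrow = length(g))
    tibble(mirna_id = m, gene_id = rep(g, 6L),
           source = rep(sources, each = length(g)),
           keep = as.vector(keep))
  }) |> bind_rows()
  rows_decoy <- purrr::imap(decoys, function(g, m) {
    if (!length(g)) return(NULL)
    n_src <- rbinom(length(g), 5L, params$db_agreement / 2)
    purrr::map2(g, n_src, function(gene, k) {
      if (k == 0L) return(NULL)
      tibble(mirna_id = m, gene_id = gene,
             source = sample(sources, k), keep = TRUE)
    }) |> bind_rows()
  }) |> bind_rows()
  all_rows <- bind_rows(rows_true, rows_decoy) |> filter(.data$keep)
  for (s in sources) {
    per_db[[s]] <- all_rows |>
      filter(.data$source == s) |>
      distinct(.data$mirna_id, .data$gene_id) |>
      arrange(.data$mirna_id, .data$gene_id)
  }
  truth$true_targets <- tt_tbl
  structure(
    list(circ_mir = cm, per_db_targets = per_db, circ_ids = circ_ids,
         mirna_ids = mirna_ids, truth = truth),
    class = "prediction_set"
  )
}

#' Simulate a complete planted-truth study
#'
#' Chains the three generators into one coherent scenario: NB counts with
#' planted DE genes (default |log2FC| = 3 so planted effects clear the
#' ceRNA node filter of |log2FC| > 2), a PPI over the true DE genes whose
#' planted hubs are three well-expressed upregulated genes, and
#' prediction tables in which those same three genes are the planted
#' ceRNA hub genes. One master seed drives all three generators through
#' derived sub-seeds.
#'
#' @param params A [sim_params()]; `de_log2fc` defaults to 3 here.
#' @param n_hub_genes Number of planted hub genes (and PPI hubs).
#' @param ppi_edges_per_node Background PPI edges per node.
#' @param frac_pass Fraction of PPI edges scoring >= 0.9.
#' @return List: `counts`, `ppi` (edges + nodes), `predictions`,
#'   `truth` (merged), `params`.
#' @export
simulate_study <- function(params = sim_params(de_log2fc = 3),
                           n_hub_genes = 3L, ppi_edges_per_node = 3,
                           frac_pass = 1) {
  sim <- simulate_counts(params)
  truth <- sim$truth
  de_genes <- c(truth$de_genes_up, truth$de_genes_down)
  if (length(de_genes) < 10L) {
    abort("Too few planted DE genes to build a study; raise n_genes or de_fraction.",
          class = "cernet_usage_error")
  }
  # hub genes: upregulated, well expressed (abundance above the median),
  # so they comfortably clear the expression node filter downstream
  ab <- sim$base_abundance[truth$de_genes_up]
  pool <- names(sort(ab, decreasing = TRUE))
  pool <- pool[seq_len(max(n_hub_genes, ceiling(length(pool) / 2)))]
  set.seed(derive_seed(params$seed, 4L))
  hubs <- sample(pool, n_hub_genes)
  truth$planted_ppi_hubs <- hubs
  truth$planted_top_mirna <- "mir_001"
  truth$planted_hub_genes <- hubs

  ppi <- simulate_ppi_planted(de_genes, round(ppi_edges_per_node *
                                                length(de_genes)),
                              hubs, frac_pass, params$seed)

  preds <- simulate_predictions(params, truth,
                                gene_universe = sim$counts$gene_id,
                                extra_pool = intersect(truth$de_genes_up,
                                                       de_genes))
  list(counts = sim$counts, ppi = ppi, predictions = preds,
       truth = preds$truth, params = params)
}

# internal: background PPI over `nodes` with specific named hubs planted
simulate_ppi_planted <- function(nodes, n_edges, hub_names, frac_pass,
                                 seed) {
  base <- simulate_ppi(n_edges = n_edges, planted_hubs = 0L,
                       frac_pass = frac_pass, nodes = nodes, seed = seed)
  set.seed(derive_seed(seed, 6L))
  deg <- table(c(base$edges$node_a, base$edges$node_b))
  med <- max(median(as.numeric(deg)), 1)
  target <- max(ceiling(3 * med), max(as.numeric(deg)) + length(hub_names) + 1)
  extra <- purrr::map(hub_names, function(h) {
    have <- unique(c(base$edges$node_b[base$edges$node_a == h],
                     base$edges$node_a[base$edges$node_b == h]))
    need <- target - length(have)
    if (need <= 0) return(NULL)
    partners <- sample(setdiff(nodes, c(h, have)),
                       min(need, length(nodes) - 1 - length(have)))
    tibble(node_a = pmin(h, partners), node_b = pmax(h, partners),
           score = round(runif(length(partners), 0.9, 1), 4))
  }) |> bind_rows()
  edges <- bind_rows(base$edges, extra) |>
    distinct(.data$node_a, .data$node_b, .keep_all = TRUE) |>
    arrange(.data$node_a, .data$node_b)
  list(edges = edges, nodes = nodes,
       truth = new_ground_truth(planted_ppi_hubs = hub_names))
}

#' Write every simulated input to a directory
#'
#' Emits the tables in the exact dialects the readers consume: counts TSV,
#' STRING-style scored edge TSV, circRNA--miRNA TSV, one TSV per
#' prediction source, a groups TSV and a ground-truth TSV.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_count_matrix(study$counts, file.path(dir, "counts.tsv"))
  g <- sample_groups(study$counts)
  readr::write_tsv(tibble(sample = names(g), group = unname(g)),
                   file.path(dir, "groups.tsv"), progress = FALSE)
  readr::write_tsv(study$ppi$edges, file.path(dir, "ppi_edges.tsv"),
                   progress = FALSE)
  readr::write_tsv(study$predictions$circ_mir,
                   file.path(dir, "circ_mir.tsv"), progress = FALSE)
  for (s in names(study$predictions$per_db_targets)) {
    readr::write_tsv(study$predictions$per_db_targets[[s]],
                     file.path(dir, sprintf("targets_%s.tsv", s)),
                     progress = FALSE)
  }
  tr <- study$truth
  truth_tbl <- bind_rows(
    tibble(kind = "de_up", id = tr$de_genes_up),
    tibble(kind = "de_down", id = tr$de_genes_down),
    tibble(kind = "ppi_hub", id = tr$planted_ppi_hubs),
    tibble(kind = "top_mirna", id = tr$planted_top_mirna),
    tibble(kind = "hub_gene", id = tr$planted_hub_genes)
  )
  readr::write_tsv(truth_tbl, file.path(dir, "ground_truth.tsv"),
                   progress = FALSE)
  invisible(dir)
}
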