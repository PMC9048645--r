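circ_annot_path <- function() {
  system.file("extdata", "anril_circrna_annotation.tsv", package = "cernet")
}

test_that("circRNA annotation parsing validates coordinates and lengths", {
  ann <- read_circ_annotation(circ_annot_path())
  expect_equal(nrow(ann), 13L)
  expect_true(all(ann$genomic_length == ann$end - ann$start))
  expect_true(all(ann$spliced_length <= ann$genomic_length))

  lens <- setNames(ann$genomic_length, ann$circ_id)
  expect_equal(lens[["hsa_circ_0008574"]], 9637)
  expect_equal(lens[["hsa_circ_0086590"]], 7767)
  expect_equal(lens[["hsa_circ_0086587"]], 71563)

  # malformed position string
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("position\tstrand\tcirc_id\tgenomic_length\tspliced_length\tgene_symbol\trbps",
               "9:100-200\t+\tc1\t100\t50\tG\tEIF4A3"), bad)
  expect_error(read_circ_annotation(bad), class = "cernet_parse_error")

  # start >= end
  writeLines(c("position\tstrand\tcirc_id\tgenomic_length\tspliced_length\tgene_symbol\trbps",
               "chr9:200-100\t+\tc1\t100\t50\tG\tEIF4A3"), bad)
  expect_error(read_circ_annotation(bad), class = "cernet_validation_error")

  # printed genomic length disagreeing with the coordinates
  writeLines(c("position\tstrand\tcirc_id\tgenomic_length\tspliced_length\tgene_symbol\trbps",
               "chr9:100-200\t+\tc1\t150\t50\tG\tEIF4A3"), bad)
  expect_error(read_circ_annotation(bad), regexp = "c1",
               class = "cernet_validation_error")
})

test_that("unique_rbps returns the six distinct flanking-region proteins", {
  ann <- read_circ_annotation(circ_annot_path())
  rbps <- unique_rbps(ann)
  expect_equal(rbps, c("AUF1", "EIF4A3", "FUS", "PTB", "TIAL1", "U2AF65"))
  expect_length(rbps, 6L)

  one <- ann[1, ]
  one$rbps <- list("EIF4A3")
  expect_equal(unique_rbps(one), "EIF4A3")
  # union cardinality never exceeds the sum of the parts
  two <- ann[1:2, ]
  expect_lte(length(unique_rbps(two)), sum(lengths(two$rbps)))
  expect_error(unique_rbps(ann[0, ]), class = "cernet_usage_error")
})

test_that("RBP differential check reports statuses and the overall flag", {
  deg_tab <- tibble::tibble(
    gene_id = c("EIF4A3", "FUS", "PTB"),
    status = c("ns", "ns", "ns"))
  rep1 <- rbp_differential_check(c("EIF4A3", "FUS", "PTB"), deg_tab)
  expect_false(attr(rep1, "any_differential"))

  deg_tab$status[2] <- "up"
  rep2 <- rbp_differential_check(c("EIF4A3", "FUS", "PTB"), deg_tab)
  expect_true(attr(rep2, "any_differential"))

  rep3 <- rbp_differential_check(c("EIF4A3", "ABSENT"), deg_tab)
  expect_equal(rep3$status[rep3$rbp == "ABSENT"], "not tested")
})

test_that("percentile filter is inclusive at the boundary", {
  pairs <- tibble::tibble(circ_id = c("c1", "c2", "c3"),
                          mirna_id = c("m1", "m2", "m3"),
                          percentile = c(89.9, 90.0, 95))
  kept <- filter_circ_mir(pairs, 90)
  expect_equal(nrow(kept), 2L)
  expect_setequal(kept$mirna_id, c("m2", "m3"))
  expect_warning(filter_circ_mir(pairs, 99.9), regexp = "No circ")
})

test_that("target consensus keeps only genes present in all six sources", {
  toy <- toy_predictions()
  # gene in 6/6 sources is kept
  cons <- intersect_target_dbs(toy$per_db_targets)
  expect_true(nrow(cons) == 4L)
  # removing one gene from one source drops it (5/6 is not enough)
  crippled <- toy$per_db_targets
  crippled$RNA22 <- crippled$RNA22[-1, ]  # drop (m1, gA) from one source
  cons2 <- intersect_target_dbs(crippled)
  expect_false(any(cons2$mirna_id == "m1" & cons2$gene_id == "gA"))
  expect_true(any(cons2$mirna_id == "m1" & cons2$gene_id == "gB"))
  # identical sources: consensus equals any single source
  expect_equal(cons, toy$per_db_targets$miRWalk |>
                 dplyr::arrange(mirna_id, gene_id))
  expect_error(intersect_target_dbs(toy$per_db_targets[1:5]),
               class = "cernet_usage_error")
})

test_that("concordance keeps only upregulated targets inside the PPI", {
  consensus <- tibble::tibble(
    mirna_id = c("m1", "m1", "m2", "m3"),
    gene_id = c("gUp", "gDown", "gUpNoPpi", "gUp"))
  deg_tab <- tibble::tibble(
    gene_id = c("gUp", "gDown", "gUpNoPpi"),
    status = c("up", "down", "up"))
  kept <- suppressMessages(
    concordance_overlap(consensus, deg_tab, c("gUp", "gDown", "gOther")))
  expect_setequal(kept$gene_id, "gUp")
  expect_setequal(kept$mirna_id, c("m1", "m3"))
})

test_that("ceRNA assembly enforces typing, filters and the join on miRNAs", {
  circ_mir <- tibble::tibble(circ_id = c("c1", "c2", "c3"),
                             mirna_id = c("m1", "m2", "mLonely"),
                             percentile = c(95, 95, 99))
  mir_mrna <- tibble::tibble(mirna_id = c("m1", "m2", "mNoCirc"),
                             gene_id = c("gA", "gB", "gC"))
  deg_tab <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"),
    logFC = c(3.5, 1.5, 4.2), p_value = c(1e-6, 1e-6, 1e-6),
    fdr = c(1e-4, 1e-4, 1e-4), status = "up")
  net <- suppressMessages(assemble_cerna(circ_mir, mir_mrna, deg_tab))

  # gB fails |log2FC| > 2, so m2 loses its only target and drops out;
  # mLonely has no targets and mNoCirc no circRNA partner
  expect_setequal(net$nodes$node[net$nodes$node_type == "mRNA"], "gA")
  expect_setequal(net$nodes$node[net$nodes$node_type == "miRNA"], "m1")
  expect_setequal(net$nodes$node[net$nodes$node_type == "circRNA"], "c1")

  # node count identity and bipartite edge typing
  gl <- glance(net)
  expect_equal(gl$n_nodes, gl$n_circ + gl$n_mirna + gl$n_mrna)
  circ_ids <- net$nodes$node[net$nodes$node_type == "circRNA"]
  mrna_ids <- net$nodes$node[net$nodes$node_type == "mRNA"]
  cm_edges <- net$edges[net$edges$edge_type == "circ-mir", ]
  mm_edges <- net$edges[net$edges$edge_type == "mir-mrna", ]
  expect_true(all(cm_edges$from %in% circ_ids))
  expect_true(all(mm_edges$to %in% mrna_ids))

  expect_error(suppressMessages(
    assemble_cerna(circ_mir[0, ], mir_mrna, deg_tab)),
    class = "cernet_usage_error")

  # empty-after-filter is an explicit empty network, not a crash
  deg_strict <- deg_tab
  deg_strict$fdr <- 0.5
  expect_warning(net_empty <- suppressMessages(
    assemble_cerna(circ_mir, mir_mrna, deg_strict)), regexp = "empty")
  expect_true(net_empty$empty)
})

test_that("assembly is invariant to input row order", {
  set.seed(13)
  circ_mir <- tibble::tibble(circ_id = rep(paste0("c", 1:4), each = 2),
                             mirna_id = rep(paste0("m", 1:4), 2),
                             percentile = 95)
  mir_mrna <- tibble::tibble(mirna_id = rep(paste0("m", 1:4), 2),
                             gene_id = paste0("g", c(1:4, 3:6)))
  deg_tab <- tibble::tibble(gene_id = paste0("g", 1:6), logFC = 3,
                            p_value = 1e-5, fdr = 1e-4, status = "up")
  n1 <- suppressMessages(assemble_cerna(circ_mir, mir_mrna, deg_tab))
  n2 <- suppressMessages(assemble_cerna(circ_mir[sample.int(8), ],
                                        mir_mrna[sample.int(8), ], deg_tab))
  expect_equal(n1$nodes, n2$nodes)
  expect_equal(n1$edges, n2$edges)
})

test_that("hub ranking follows node degree with deterministic ties", {
  circ_mir <- tibble::tibble(circ_id = c("c1", "c1", "c2"),
                             mirna_id = c("m1", "m2", "m1"),
                             percentile = 95)
  mir_mrna <- tibble::tibble(mirna_id = c("m1", "m2", "m1", "m2"),
                             gene_id = c("gBoth", "gBoth", "gOne", "gTwo"))
  deg_tab <- tibble::tibble(gene_id = c("gBoth", "gOne", "gTwo"),
                            logFC = 3, p_value = 1e-5, fdr = 1e-4,
                            status = "up")
  net <- suppressMessages(assemble_cerna(circ_mir, mir_mrna, deg_tab))
  hubs <- hub_genes(net, top_n = 2)
  # gBoth (2 miRNAs) outranks single-miRNA genes; ties break by name
  expect_equal(hubs$genes$gene_id, c("gBoth", "gOne", "gTwo"))
  expect_equal(hubs$genes$degree, c(2L, 1L, 1L))
  expect_equal(hubs$genes$is_hub, c(TRUE, TRUE, FALSE))
  # miRNA target-site counts equal their mRNA-side degree
  expect_equal(hubs$mirnas$target_sites[hubs$mirnas$mirna_id == "m1"], 2L)
  # per-node degree equals a direct edge count
  for (nd in net$nodes$node) {
    expect_equal(net$nodes$degree[net$nodes$node == nd],
                 sum(net$edges$from == nd) + sum(net$edges$to == nd))
  }
})

test_that("tightening thresholds never enlarges the ceRNA network", {
  study <- simulate_study(sim_params(n_genes = 400, seed = 23,
                                     db_agreement = 1))
  deg_tab <- tidy(suppressMessages(call_degs(study$counts)))
  ppi <- suppressMessages(suppressWarnings(
    build_ppi(study$ppi$edges, deg_tab)))
  consensus <- intersect_target_dbs(study$predictions$per_db_targets)
  mm <- suppressMessages(concordance_overlap(consensus, deg_tab, ppi))

  sizes <- purrr::map_int(c(80, 90, 95, 99), function(pc) {
    cm <- suppressWarnings(filter_circ_mir(study$predictions$circ_mir, pc))
    if (nrow(cm) == 0 || nrow(mm) == 0) return(0L)
    net <- suppressMessages(suppressWarnings(
      assemble_cerna(cm, mm, deg_tab)))
    nrow(net$edges)
  })
  expect_true(all(diff(sizes) <= 0))

  # tightening the node filter shrinks (or preserves) the network too
  cm90 <- filter_circ_mir(study$predictions$circ_mir, 90)
  cfg_loose <- pipeline_config(cerna_abs_log2fc_min = 1,
                               cerna_p_max = 0.05, cerna_fdr_max = 0.05)
  cfg_tight <- pipeline_config()  # |log2FC| > 2, p < 0.01, fdr < 0.01
  n_loose <- suppressMessages(suppressWarnings(
    assemble_cerna(cm90, mm, deg_tab, cfg_loose)))
  n_tight <- suppressMessages(suppressWarnings(
    assemble_cerna(cm90, mm, deg_tab, cfg_tight)))
  expect_lte(nrow(n_tight$edges), nrow(n_loose$edges))
  expect_lte(nrow(n_tight$nodes), nrow(n_loose$nodes))
})
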