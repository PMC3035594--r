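test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_case = 0), "positive")
  expect_error(sim_config(n_de_genes = 5000), "n_de_genes")
  expect_error(sim_config(n_tfs = 3000), "n_tfs")
  expect_error(sim_config(frac_absent = 1.2), "frac_absent")
  expect_error(sim_config(repression_strength = 2), "repression_strength")
  expect_error(sim_config(effect_log2fc = -1), "effect_log2fc")
})

test_that("identical seeds reproduce byte-identical cohorts and knowledge", {
  cfg <- sim_config(n_genes = 300, n_mirnas = 50, n_tfs = 20,
                    n_de_genes = 20, n_de_mirnas = 10,
                    n_target_pairs_true = 10, n_target_pairs_decoy = 30,
                    n_regulons = 3, n_ffls_planted = 2, seed = 7)
  a <- simulate_cohort(cfg); b <- simulate_cohort(cfg)
  expect_identical(a$mrna, b$mrna)
  expect_identical(a$mirna, b$mirna)
  expect_identical(a$truth$de_genes, b$truth$de_genes)
  expect_identical(simulate_knowledge(a$truth, cfg),
                   simulate_knowledge(b$truth, cfg))
})

test_that("zero effect size plants labels but no mean difference", {
  cfg <- sim_config(n_genes = 400, n_mirnas = 40, n_de_genes = 40,
                    n_de_mirnas = 10, effect_log2fc = 0,
                    n_case = 40, n_control = 40, n_target_pairs_true = 0,
                    n_regulons = 0, n_ffls_planted = 0, seed = 3)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth$de_genes), 40)
  is_case <- co$metadata$group == "ILD"
  diffs <- rowMeans(co$mrna[co$truth$de_genes$id, is_case]) -
    rowMeans(co$mrna[co$truth$de_genes$id, !is_case])
  # mean difference 0 in expectation: |mean| < 4 se
  se <- cfg$noise_sd * sqrt(1 / 40 + 1 / 40) / sqrt(40)
  expect_lt(abs(mean(diffs)), 4 * se)
})

test_that("planted effect sizes are recovered in expectation (Monte Carlo)", {
  reps <- 50
  cfg <- sim_config(seed = 1)
  acc <- c(); n_up <- 0
  for (r in seq_len(reps)) {
    cfg$seed <- 100 + r
    co <- simulate_cohort(cfg)
    tr <- co$truth
    # direct up-genes free of TF coupling and repression
    coupled <- unique(c(tr$tf_regulons$target, tr$true_targets$gene,
                        tr$tf_regulons$tf))
    direct_up <- tr$de_genes$id[tr$de_genes$mode == "direct" &
                                  tr$de_genes$direction > 0]
    pure <- setdiff(direct_up, coupled)
    is_case <- co$metadata$group == "ILD"
    d <- rowMeans(co$mrna[pure, is_case, drop = FALSE]) -
      rowMeans(co$mrna[pure, !is_case, drop = FALSE])
    acc <- c(acc, d)
    n_up <- n_up + length(pure)
  }
  se_diff <- cfg$noise_sd * sqrt(1 / cfg$n_case + 1 / cfg$n_control)
  expect_lt(abs(mean(acc) - cfg$effect_log2fc), 3 * se_diff / sqrt(length(acc)))
})

test_that("knowledge tables are consistent with the ground truth", {
  cfg <- sim_config(n_genes = 500, n_mirnas = 60, n_tfs = 30,
                    n_de_genes = 30, n_de_mirnas = 15,
                    n_target_pairs_true = 15, n_target_pairs_decoy = 100,
                    n_regulons = 4, n_ffls_planted = 3, seed = 11)
  co <- simulate_cohort(cfg)
  kb <- simulate_knowledge(co$truth, cfg)
  tr <- co$truth
  key <- function(df, a, b) paste(df[[a]], df[[b]])

  # true targets are a subset of the predictions; decoys are disjoint
  expect_true(all(key(tr$true_targets, "mirna", "gene") %in%
                    key(kb$target_predictions, "mirna", "gene")))
  decoys <- setdiff(key(kb$target_predictions, "mirna", "gene"),
                    key(tr$true_targets, "mirna", "gene"))
  expect_length(decoys, cfg$n_target_pairs_decoy)
  expect_length(intersect(decoys, key(tr$true_targets, "mirna", "gene")), 0)

  # regulons covered by the binding table; planted FFLs realizable
  expect_true(all(key(tr$tf_regulons, "tf", "target") %in%
                    key(kb$tf_binding, "tf", "target")))
  pf <- tr$planted_ffls
  expect_gt(nrow(pf), 0)
  expect_true(all(key(pf, "tf", "mirna") %in% key(kb$tf_binding, "tf", "target")))
  expect_true(all(key(pf, "tf", "gene") %in% key(kb$tf_binding, "tf", "target")))
  expect_true(all(key(pf, "mirna", "gene") %in%
                    key(kb$target_predictions, "mirna", "gene")))
  # and consistent with the regulon signs
  for (i in seq_len(nrow(pf))) {
    s <- tr$tf_regulons$sign[tr$tf_regulons$tf == pf$tf[i] &
                               tr$tf_regulons$target == pf$mirna[i]]
    expect_equal(s[1], pf$s_tm[i])
  }

  # no self edges in context tables
  expect_false(any(kb$ppi_edges$a == kb$ppi_edges$b))
  expect_false(any(kb$pathway_edges$source == kb$pathway_edges$target))

  # every referenced id exists in the simulated universe
  universe <- c(tr$gene_ids, tr$mirna_ids)
  expect_true(all(unlist(kb$target_predictions) %in% universe))
  expect_true(all(unlist(kb$tf_binding) %in% universe))
})

test_that("zero decoys leaves predictions equal to the true targets", {
  cfg <- sim_config(n_genes = 200, n_mirnas = 30, n_de_genes = 10,
                    n_de_mirnas = 5, n_target_pairs_true = 8,
                    n_target_pairs_decoy = 0, n_regulons = 2,
                    n_ffls_planted = 1, seed = 5)
  co <- simulate_cohort(cfg)
  kb <- simulate_knowledge(co$truth, cfg)
  expect_equal(nrow(kb$target_predictions), 8)
  expect_setequal(paste(kb$target_predictions$mirna, kb$target_predictions$gene),
                  paste(co$truth$true_targets$mirna, co$truth$true_targets$gene))
})

test_that("simulation exports round-trip through plain-text files", {
  cfg <- sim_config(n_genes = 120, n_mirnas = 20, n_tfs = 10,
                    n_de_genes = 10, n_de_mirnas = 5,
                    n_target_pairs_true = 5, n_target_pairs_decoy = 10,
                    n_regulons = 2, n_ffls_planted = 1, seed = 9)
  co <- simulate_cohort(cfg)
  kb <- simulate_knowledge(co$truth, cfg)
  d <- withr::local_tempdir()
  export_simulation(co, kb, d)
  m2 <- read_expression_tsv(file.path(d, "mrna.tsv"))
  expect_equal(m2, co$mrna, tolerance = 1e-12)
  sets <- read_gmt(file.path(d, "gene_sets.gmt"))
  expect_identical(sets, lapply(kb$gene_sets, as.character))
  expect_identical(readLines(file.path(d, "tf_catalog.txt")), co$truth$tf_ids)
})
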