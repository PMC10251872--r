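noise_free_study <- function(effects, n_persons = 5) {
  # effects: named log2 tumor shifts per gene; zero noise everywhere
  genes <- names(effects)
  design <- simulation_design(n_persons = n_persons, n_genes = length(genes),
                              sd_person = 0, sd_sample = 0, sd_error = 0,
                              gene_baseline_sd = 0, grand_mean = 5, seed = 1)
  st <- simulate_expression_study(design)
  rownames(st$values) <- genes
  st$probe_to_gene <- setNames(genes, genes)
  tumor <- st$samples$tissue == "tumor"
  for (g in genes) st$values[g, tumor] <- st$values[g, tumor] + effects[[g]]
  st
}

test_that("homogeneous noise-free sets report the common effect", {
  st <- noise_free_study(c(a = -1, b = -1, c = -1))
  f <- fit_gene_set_model(st, c("a", "b", "c"), name = "S")
  expect_equal(f$d_bar, -1, tolerance = 1e-10)
  expect_equal(f$fc, -2, tolerance = 1e-9)
})

test_that("set effect is the unweighted mean of member-gene effects", {
  st <- noise_free_study(c(a = -1, b = 0, c = 1))
  f <- fit_gene_set_model(st, c("a", "b", "c"), name = "S")
  expect_equal(f$d_bar, 0, tolerance = 1e-10)
  expect_equal(f$fc, 1, tolerance = 1e-9)
  # averaging contract on noisy data: set d equals mean of per-gene paired fits
  des <- simulation_design(n_persons = 10, n_genes = 6, seed = 13)
  stn <- simulate_expression_study(des)
  genes <- rownames(stn$values)[1:4]
  fs <- fit_gene_set_model(stn, genes, name = "S")
  per <- vapply(genes, function(g) {
    fit_paired_model(stn$values[g, ], stn$samples$tissue,
                     stn$samples$person_id)$d
  }, 0)
  expect_equal(fs$d_bar, mean(per), tolerance = 1e-10)
  # invariance to gene ordering
  fs_rev <- fit_gene_set_model(stn, rev(genes), name = "S")
  expect_equal(fs$d_bar, fs_rev$d_bar, tolerance = 1e-12)
  expect_equal(fs$se, fs_rev$se, tolerance = 1e-10)
})

test_that("pathways with fewer than two platform genes are skipped", {
  des <- simulation_design(n_persons = 6, n_genes = 5, seed = 2)
  st <- simulate_expression_study(des)
  expect_error(fit_gene_set_model(st, c("gene_1", "absent_gene"), name = "X"),
               "need >= 2")
  pw <- pathway_collection(list(ok = c("gene_1", "gene_2"),
                                tiny = "gene_3",
                                gone = c("zz1", "zz2")))
  tab <- fit_gene_sets(st, pw)
  expect_equal(tab$pathway, "ok")
  expect_named(attr(tab, "skipped"), c("tiny", "gone"))
})

test_that("planted set effects are recovered with calibrated intervals", {
  pw <- generate_pathways(60, 1, 20, seed = 3)
  d_true <- log2_from_fold_change(-1.7)
  eff <- list(pathway_effect(names(pw), pw[[1]], d_true))
  covered <- 0L
  n_rep <- 120
  for (i in seq_len(n_rep)) {
    des <- simulation_design(n_persons = 60, n_genes = 60, pathways = eff,
                             seed = 5000 + i)
    st <- simulate_expression_study(des)
    f <- fit_gene_set_model(st, pw[[1]], name = names(pw))
    ci_d <- f$d_bar + c(-1, 1) * qt(0.975, f$df) * f$se
    if (ci_d[1] <= d_true && d_true <= ci_d[2]) covered <- covered + 1L
  }
  # nominal 95% coverage within binomial noise at 120 reps
  expect_gte(covered / n_rep, 0.89)
  expect_lte(covered / n_rep, 0.995)
})

test_that("unbalanced studies (missing sample) still fit", {
  pw <- generate_pathways(20, 1, 8, seed = 4)
  des <- simulation_design(n_persons = 12, n_genes = 20,
                           pathways = list(pathway_effect(names(pw), pw[[1]], -1)),
                           seed = 6)
  st <- simulate_expression_study(des)
  st <- inject_missing(st, st$samples$sample_id[st$samples$tissue == "normal"][1])
  f <- fit_gene_set_model(st, pw[[1]], name = names(pw))
  expect_true(is.finite(f$p))
  expect_equal(f$d_bar, -1, tolerance = 0.6)
})
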