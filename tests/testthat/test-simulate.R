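test_that("generate_pathways honours size, saturation and determinism", {
  pw <- generate_pathways(100, 5, 10, seed = 1)
  expect_length(pw, 5)
  expect_true(all(lengths(pw) == 10))
  universe <- sprintf("gene_%03d", 1:100)
  expect_true(all(unlist(pw) %in% universe))
  # saturation: one set of the whole universe
  pw1 <- generate_pathways(10, 1, 10, seed = 0)
  expect_setequal(pw1[[1]], sprintf("gene_%02d", 1:10))
  expect_identical(generate_pathways(100, 5, 10, seed = 7),
                   generate_pathways(100, 5, 10, seed = 7))
  expect_error(generate_pathways(5, 1, 10), "exceeds")
  expect_error(generate_pathways(0, 1, 1), "positive")
})

test_that("noise-free designs reproduce their fixed effects exactly", {
  des <- simulation_design(n_persons = 4, n_genes = 3, grand_mean = 5,
                           sd_person = 0, sd_sample = 0, sd_error = 0,
                           gene_baseline_sd = 0, seed = 1)
  st <- simulate_expression_study(des)
  expect_true(all(st$values == 5))
  # with a planted pathway effect the tumor columns shift by exactly the effect
  eff <- pathway_effect("P", c("gene_1", "gene_2"), -1)
  des2 <- simulation_design(n_persons = 4, n_genes = 3, pathways = list(eff),
                            grand_mean = 5, sd_person = 0, sd_sample = 0,
                            sd_error = 0, gene_baseline_sd = 0, seed = 1)
  st2 <- simulate_expression_study(des2)
  tumor <- st2$samples$tissue == "tumor"
  expect_true(all(st2$values[c("gene_1", "gene_2"), tumor] == 4))
  expect_true(all(st2$values["gene_3", ] == 5))
})

test_that("planted pathway effects are recovered by direct averaging", {
  pw_genes <- sprintf("gene_%03d", 1:20)
  des <- simulation_design(
    n_persons = 200, n_genes = 100,
    pathways = list(pathway_effect("P1", pw_genes, -1)), seed = 11
  )
  st <- simulate_expression_study(des)
  tumor <- st$samples$tissue == "tumor"
  diff <- mean(st$values[pw_genes, tumor]) - mean(st$values[pw_genes, !tumor])
  # Monte-Carlo error at n = 200 persons x 20 genes is a few hundredths
  expect_equal(diff, -1, tolerance = 0.05)
  expect_identical(simulate_expression_study(des)$values, st$values)
})

test_that("person-mean variance matches its moment decomposition", {
  # var of person means over k samples and m genes:
  #   sd_person^2 + sd_sample^2 / k + sd_error^2 / (k m)
  des <- simulation_design(n_persons = 600, n_genes = 10, sd_person = 0.5,
                           sd_sample = 0.3, sd_error = 0.5,
                           gene_baseline_sd = 0, seed = 21)
  st <- simulate_expression_study(des)
  pm <- tapply(colMeans(st$values), st$samples$person_id, mean)
  expected <- 0.5^2 + 0.3^2 / 2 + 0.5^2 / (2 * 10)
  expect_equal(unname(var(pm)), expected, tolerance = 0.10 * expected)
})

test_that("stratum-by-tumor interaction deltas act on the configured level", {
  eff <- pathway_effect("P", sprintf("gene_%02d", 1:10), -1,
                        interaction_factor = "MSI",
                        interaction_deltas = c(MSI = -0.5, MSS = 0))
  des <- simulation_design(n_persons = 400, n_genes = 10,
                           pathways = list(eff), sd_person = 0.2,
                           sd_sample = 0.1, sd_error = 0.3,
                           gene_baseline_sd = 0, seed = 31)
  st <- simulate_expression_study(des)
  s <- st$samples
  d_of <- function(msi) {
    sel_t <- s$tissue == "tumor" & s$MSI == msi
    sel_n <- s$tissue == "normal" & s$MSI == msi
    mean(st$values[, sel_t]) - mean(st$values[, sel_n])
  }
  expect_equal(d_of("MSI"), -1.5, tolerance = 0.06)
  expect_equal(d_of("MSS"), -1.0, tolerance = 0.06)
})

test_that("inject_missing removes samples and cascades to persons", {
  des <- simulation_design(n_persons = 5, n_genes = 4, seed = 2)
  st <- simulate_expression_study(des)
  drop1 <- st$samples$sample_id[st$samples$tissue == "normal"][1]
  st1 <- inject_missing(st, drop1)
  expect_equal(ncol(st1$values), 9)          # 2n - 1 samples remain
  expect_false(drop1 %in% st1$samples$sample_id)
  expect_identical(inject_missing(st, character(0)), st)
  both <- st$samples$sample_id[st$samples$person_id == "person_2"]
  st2 <- inject_missing(st, both)
  expect_false("person_2" %in% st2$samples$person_id)
  expect_error(inject_missing(st, "no_such_sample"), "unknown")
})

test_that("simulated methylation respects range, null and planted deltas", {
  genes <- sprintf("gene_%02d", 1:10)
  des <- simulation_design(n_persons = 200, n_genes = 40,
                           pathways = list(pathway_effect("P", genes, -1)),
                           seed = 41)
  # null design: no hyper pathways
  md0 <- methylation_design(markers_per_gene = 5, seed = 42)
  st0 <- simulate_methylation_study(des, md0)
  expect_true(all(st0$beta >= 0 & st0$beta <= 1, na.rm = TRUE))
  tumor <- st0$samples$tissue == "tumor"
  expect_equal(mean(st0$beta[, tumor]) - mean(st0$beta[, !tumor]), 0,
               tolerance = 0.01)
  # planted promoter-island hyper-methylation of +0.2
  md <- methylation_design(markers_per_gene = 5,
                           hyper_pathways = c(P = 0.2), seed = 42)
  st <- simulate_methylation_study(des, md)
  ann <- st$annotation
  sel <- ann$functional_group == "promoter" &
    ann$relation_to_island == "Island" & ann$gene %in% genes
  dd <- mean(st$beta[sel, tumor]) - mean(st$beta[sel, !tumor])
  expect_equal(dd, 0.2, tolerance = 0.02)
  # same expression layout: identical sample tables
  expect_identical(st$samples, simulate_expression_study(des)$samples)
  expect_identical(simulate_methylation_study(des, md)$beta, st$beta)
})
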