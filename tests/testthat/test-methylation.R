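test_that("beta value reproduces the intensity worked examples", {
  expect_equal(beta_from_intensities(50, 50), 0.5)
  expect_equal(beta_from_intensities(0, 120), 0)
  expect_equal(beta_from_intensities(80, 0), 1)
  # scale invariance: (cX, cY) gives the same beta for any c > 0
  set.seed(6)
  X <- runif(50, 1, 100); Y <- runif(50, 1, 100)
  for (c_ in c(0.01, 3, 1e4)) {
    expect_equal(beta_from_intensities(c_ * X, c_ * Y),
                 beta_from_intensities(X, Y), tolerance = 1e-12)
  }
  # zero total intensity becomes a counted missing value, not an error
  expect_message(b <- beta_from_intensities(c(0, 10), c(0, 10)), "zero total")
  expect_true(is.na(b[1]) && b[2] == 0.5)
  expect_error(beta_from_intensities(-1, 5), "non-negative")
})

mk_meth_study <- function(n_persons = 6, seed = 1, hyper = numeric(0)) {
  genes <- sprintf("gene_%02d", 1:8)
  des <- simulation_design(n_persons = n_persons, n_genes = 20,
                           pathways = list(pathway_effect("P", genes, -1)),
                           seed = seed)
  md <- methylation_design(markers_per_gene = 6, hyper_pathways = hyper,
                           seed = seed + 1)
  simulate_methylation_study(des, md)
}

test_that("marker filtering follows the annotation categories", {
  st <- mk_meth_study()
  # chip-wide convention: exclude open sea
  f1 <- suppressMessages(filter_markers(st, exclude_relations = "OpenSea"))
  expect_setequal(unique(f1$annotation$relation_to_island),
                  c("Island", "Shore", "Shelf"))
  # promoter-island analysis universe
  f2 <- suppressMessages(filter_markers(
    st, exclude_relations = c("Shore", "Shelf", "OpenSea"),
    keep_functional = "promoter"))
  expect_true(all(f2$annotation$relation_to_island == "Island"))
  expect_true(all(f2$annotation$functional_group == "promoter"))
  # empty exclusion and universal keep is the identity
  f3 <- filter_markers(st)
  expect_identical(f3$beta, st$beta)
  expect_error(filter_markers(st, exclude_relations = "Moon"), "unknown")
  expect_error(
    suppressMessages(filter_markers(st,
      exclude_relations = c("Island", "Shore", "Shelf", "OpenSea"))),
    "removed all")
})

test_that("direction classification is sign-based with a boundary flag", {
  d <- classify_direction(c(0.1, -0.1, 0))
  expect_equal(as.character(d), c("hyper", "hypo", "hypo"))
  expect_equal(attr(d, "boundary"), c(FALSE, FALSE, TRUE))
  expect_error(classify_direction(NA_real_), "finite")
})

test_that("delta-beta gene-set analysis recovers planted hyper-methylation", {
  st <- mk_meth_study(n_persons = 100, seed = 51, hyper = c(P = 0.2))
  stf <- suppressMessages(filter_markers(
    st, exclude_relations = c("Shore", "Shelf", "OpenSea"),
    keep_functional = "promoter"))
  genes <- sprintf("gene_%02d", 1:8)
  f <- delta_beta_gene_set(stf, genes, name = "P")
  expect_equal(f$delta_beta, 0.2, tolerance = 0.04)
  expect_equal(as.character(f$direction), "hyper")
  expect_lt(f$p, 1e-6)
  # antisymmetry under tissue-label swap
  st2 <- stf
  st2$samples$tissue <- ifelse(st2$samples$tissue == "tumor",
                               "normal", "tumor")
  f2 <- delta_beta_gene_set(st2, genes, name = "P")
  expect_equal(f2$delta_beta, -f$delta_beta, tolerance = 1e-10)
  expect_equal(as.character(f2$direction), "hypo")
})

test_that("filtering then fitting equals fitting a pre-filtered study", {
  st <- mk_meth_study(n_persons = 20, seed = 61, hyper = c(P = 0.15))
  genes <- sprintf("gene_%02d", 1:8)
  stf <- suppressMessages(filter_markers(
    st, exclude_relations = c("Shore", "Shelf", "OpenSea"),
    keep_functional = "promoter"))
  f1 <- delta_beta_gene_set(stf, genes, name = "P")
  # manual pre-filter via constructor
  ann <- st$annotation
  keep <- ann$relation_to_island == "Island" & ann$functional_group == "promoter"
  st_manual <- methylation_study(st$beta[ann$marker[keep], , drop = FALSE],
                                 ann[keep, ], st$samples)
  f2 <- delta_beta_gene_set(st_manual, genes, name = "P")
  expect_equal(f1$delta_beta, f2$delta_beta, tolerance = 1e-12)
  expect_equal(f1$p, f2$p, tolerance = 1e-10)
})

test_that("pathways without enough annotated genes are skipped with reasons", {
  st <- mk_meth_study()
  expect_error(delta_beta_gene_set(st, c("gene_01", "unknown")), "skipped")
  pw <- pathway_collection(list(ok = sprintf("gene_%02d", 1:8),
                                gone = c("zz1", "zz2")))
  tab <- delta_beta_gene_sets(st, pw)
  expect_equal(tab$pathway, "ok")
  expect_named(attr(tab, "skipped"), "gone")
})
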