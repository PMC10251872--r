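test_that("unpaired fit reduces to the pooled two-sample t-test", {
  y <- c(6, 7, 8, 4, 5, 6)
  gr <- rep(c("tumor", "normal"), each = 3)
  f <- fit_unpaired_model(y, gr)
  tt <- t.test(y[gr == "tumor"], y[gr == "normal"], var.equal = TRUE)
  expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(f$d, 2)
  # exact null
  f0 <- fit_unpaired_model(rep(c(5, 5, 5), 2), gr)
  expect_equal(f0$d, 0)
  expect_equal(f0$F, 0)
  expect_equal(f0$fc, 1)
  # d is tumor minus normal by definition
  f1 <- fit_unpaired_model(c(4, 4, 4, 5, 5, 5), gr)
  expect_equal(f1$d, -1)
  expect_error(fit_unpaired_model(c(1, 2, 3), c("a", "a", "b")),
               "insufficient")
})

test_that("paired F equals the squared paired t on balanced data", {
  # oracle equivalence across many random instances
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:20, 1)
    dat <- make_paired(n, effect = rnorm(1), sd_person = rexp(1),
                       sd_error = rexp(1), seed = 1000 + i)
    f <- fit_paired_model(dat$y, dat$tissue, dat$person)
    d <- dat$y[dat$tissue == "tumor"] - dat$y[dat$tissue == "normal"]
    tt <- t.test(d)
    expect_equal(f$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(f$d, mean(d), tolerance = 1e-10)
    expect_equal(f$df, n - 1, tolerance = 1e-6)
  }
})

test_that("paired noise-free differences are recovered exactly", {
  person <- rep(paste0("p", 1:4), each = 2)
  tissue <- rep(c("tumor", "normal"), 4)
  base <- c(5, 5, 7, 7, 6, 6, 9, 9)
  y <- base + ifelse(tissue == "tumor", -1, 0)
  f <- fit_paired_model(y, tissue, person)
  expect_equal(f$d, -1, tolerance = 1e-10)
  expect_equal(f$variance_components$residual, 0, tolerance = 1e-10)
  expect_equal(f$fc, -2, tolerance = 1e-9)
})

test_that("method-of-moments components match the balanced closed form", {
  # balanced two-way: sigma_P^2 = (MS_person - MS_resid) / 2
  dat <- make_paired(30, effect = 1, sd_person = 1.3, sd_error = 0.6,
                     seed = 5)
  f <- fit_paired_model(dat$y, dat$tissue, dat$person)
  a <- anova(lm(dat$y ~ factor(dat$tissue) + factor(dat$person)))
  ms_p <- a["factor(dat$person)", "Mean Sq"]
  ms_e <- a["Residuals", "Mean Sq"]
  expect_equal(unname(f$variance_components$components["person"]),
               (ms_p - ms_e) / 2, tolerance = 1e-8)
  expect_equal(f$variance_components$residual, ms_e, tolerance = 1e-8)
})

test_that("negative component solutions clamp to zero and are flagged", {
  # no person variance at all, tiny noise: MoM solution often negative
  set.seed(8)
  person <- rep(paste0("p", 1:6), each = 2)
  tissue <- rep(c("tumor", "normal"), 6)
  found <- FALSE
  for (i in 1:20) {
    y <- rnorm(12)
    # force MS_person < MS_resid by centering each person pair
    y <- y - ave(y, person)
    f <- fit_paired_model(y, tissue, person)
    if (f$variance_components$clamped["person"]) {
      found <- TRUE
      expect_equal(unname(f$variance_components$components["person"]), 0)
      break
    }
  }
  expect_true(found)
})

test_that("paired fit handles the unbalanced one-sample-missing case", {
  dat <- make_paired(10, effect = -1, sd_person = 1, sd_error = 0.3, seed = 9)
  keep <- -2L   # drop person 1's normal sample
  f <- fit_paired_model(dat$y[keep], dat$tissue[keep], dat$person[keep])
  expect_true(is.finite(f$F) && is.finite(f$p))
  expect_equal(f$d, -1, tolerance = 0.5)
  # all persons single-sample: unidentifiable
  one <- seq(1, 20, by = 2)
  expect_error(fit_paired_model(dat$y[one], dat$tissue[one], dat$person[one]),
               "unpaired")
  expect_error(fit_paired_model(1:6, c("tumor", "normal", "tumor",
                                       "normal", "tumor", "normal"),
                                c("p1", "p1", "p1", "p2", "p2", "p3")),
               "at most one")
})

test_that("interaction model detects and rejects per its contracts", {
  tis <- rep(c("tumor", "normal"), 20)
  strt <- rep(c("A", "B"), each = 20)
  # identical tumor effect, no noise: interaction F = 0
  y <- ifelse(tis == "tumor", -1, 0) + rep(c(0, 3), each = 20) +
    rep(seq(0, 0.95, by = 0.05), each = 2)  # within-stratum spread
  f <- fit_interaction_model(y, tis, strt)
  expect_equal(f$interaction_F, 0, tolerance = 1e-20)
  # distinct effects, vanishing noise: p -> 0
  set.seed(12)
  y2 <- ifelse(tis == "tumor", ifelse(strt == "A", -1, -2), 0) +
    rnorm(40, 0, 1e-4)
  f2 <- fit_interaction_model(y2, tis, strt)
  expect_lt(f2$interaction_p, 1e-10)
  expect_equal(f2$strata$d, c(-1, -2), tolerance = 1e-3)
  expect_equal(f2$strata$fc, c(-2, -4), tolerance = 1e-3)
  # single-level stratum refuses
  expect_error(fit_interaction_model(y2, tis, rep("A", 40)), "single-level")
  # a stratum with one tissue is dropped with a warning
  tis3 <- c(tis, rep("tumor", 4))
  strt3 <- c(strt, rep("C", 4))
  y3 <- c(y2, rnorm(4))
  expect_warning(f3 <- fit_interaction_model(y3, tis3, strt3), "dropping")
  expect_setequal(f3$strata$stratum, c("A", "B"))
})

test_that("interaction test holds its nominal size under the null", {
  # 400-rep spot check at alpha = 0.10 (the acceptance suite runs the full
  # 2000-rep calibration at alpha = 0.05)
  set.seed(77)
  rej <- 0L
  for (i in 1:400) {
    tis <- rep(c("tumor", "normal"), 12)
    strt <- rep(c("A", "B"), each = 12)
    y <- rnorm(24) + ifelse(tis == "tumor", -1, 0)
    f <- fit_interaction_model(y, tis, strt)
    if (f$interaction_p <= 0.10) rej <- rej + 1L
  }
  expect_lte(abs(rej / 400 - 0.10), 0.045)
})

test_that("fit_all_genes returns a coherent adjusted table", {
  des <- simulation_design(n_persons = 8, n_genes = 12, seed = 3,
                           pathways = list(pathway_effect(
                             "P", sprintf("gene_%02d", 1:3), -2)))
  st <- simulate_expression_study(des)
  tab <- fit_all_genes(st, model = "paired")
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$q >= tab$p))
  expect_true(all(abs(tab$fc) >= 1))
  expect_true(all(tab$fc_lo <= tab$fc & tab$fc <= tab$fc_hi))
})

test_that("person-blocked interaction variant keeps contrasts estimable", {
  set.seed(19)
  n_p <- 16
  person <- rep(paste0("p", seq_len(n_p)), each = 2)
  tis <- rep(c("tumor", "normal"), n_p)
  strt <- rep(sample(c("MSI", "MSS"), n_p, replace = TRUE), each = 2)
  y <- rnorm(2 * n_p) + ifelse(tis == "tumor", -1, 0) +
    rep(rnorm(n_p), each = 2)
  f0 <- fit_interaction_model(y, tis, strt)
  f1 <- fit_interaction_model(y, tis, strt, person = person)
  # blocking absorbs person noise: per-stratum effects agree, se shrinks
  expect_equal(f1$strata$d, f0$strata$d, tolerance = 0.5)
  expect_true(all(f1$strata$se <= f0$strata$se + 1e-12))
  expect_true(is.finite(f1$interaction_p))
})
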