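mk_results <- function(q, fc) {
  data.frame(pathway = sprintf("PW_%02d", seq_along(q)), q = q, fc = fc,
             stringsAsFactors = FALSE)
}

test_that("differential calling filters on FDR and fold change", {
  res <- mk_results(q = c(0.01, 0.01, 0.2), fc = c(-2.5, -1.5, -3))
  d <- call_differential(res, fdr_max = 0.05, min_abs_fc = 2)
  expect_equal(nrow(d), 1)
  expect_equal(d$pathway, "PW_01")
  expect_equal(d$direction, "down")
  # no-filter limit passes everything
  d_all <- call_differential(res, fdr_max = 1, min_abs_fc = 1)
  expect_equal(nrow(d_all), 3)
  expect_equal(nrow(call_differential(res[0, ], 0.05, 2)), 0)
  expect_error(call_differential(res, 0.05, 0.5), "signed convention")
  # idempotence: re-filtering with the same thresholds returns it unchanged
  d2 <- call_differential(as.data.frame(d_all), fdr_max = 1, min_abs_fc = 1)
  expect_equal(as.data.frame(d2), as.data.frame(d_all))
})

test_that("venn partition produces a true set partition", {
  lists <- list(A = c("p1", "p2", "p3"), B = c("p2", "p3", "p4"),
                C = c("p3", "p5"))
  vp <- venn_partition(lists)
  # regions are disjoint and reconstruct the union
  all_members <- unlist(vp$members)
  expect_false(any(duplicated(all_members)))
  expect_setequal(all_members, unique(unlist(lists)))
  expect_equal(sum(vp$counts), length(unique(unlist(lists))))
  # each input list equals the union of the regions containing it
  for (nm in names(lists)) {
    in_regions <- vp$members[grepl(nm, names(vp$members), fixed = TRUE)]
    expect_setequal(unlist(in_regions), lists[[nm]])
  }
  expect_equal(unname(vp$counts[["A&B&C"]]), 1)
  # disjoint lists: no shared regions
  vd <- venn_partition(list(X = c("a", "b"), Y = c("c", "d")))
  expect_setequal(names(vd$counts), c("X", "Y"))
  # identical lists: one all-lists region
  vi <- venn_partition(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(names(vi$counts), "X&Y")
  expect_error(venn_partition(list(A = c("a", "a"), B = "b")), "duplicate")
  expect_error(venn_partition(list(A = "a")), "2-4")
})

test_that("overlap percentages reproduce the published intersection figures", {
  lists <- make_published_venn_lists()
  vp <- venn_partition(lists)
  expect_equal(unname(vp$counts[["UC&UC_CRC&sporadic_CRC"]]), 29)
  expect_equal(unname(vp$counts[["UC&UC_CRC"]]), 14)
  expect_equal(round(overlap_percentage(vp, "UC", "UC_CRC")), 81)
  expect_equal(round(overlap_percentage(vp, "UC_CRC", "UC")), 70)
  expect_equal(round(overlap_percentage(vp, "sporadic_CRC", "UC")), 49)
  expect_equal(overlap_percentage(vp, "UC", "UC"), 100)
  expect_error(overlap_percentage(vp, "nope", "UC"), "unknown")
})

test_that("direction concordance counts shared directions", {
  a <- data.frame(pathway = c("p1", "p2", "p3", "p4"),
                  direction = c("down", "down", "up", "down"))
  b <- data.frame(pathway = c("p1", "p2", "p3", "p4"),
                  direction = c("down", "down", "down", "up"))
  expect_equal(direction_concordance(a, a), 1)
  expect_equal(direction_concordance(a, b), 0.5)
  flip <- b; flip$direction <- ifelse(a$direction == "down", "up", "down")
  expect_equal(direction_concordance(a, flip), 0)
  expect_error(direction_concordance(a, data.frame(pathway = "zz",
                                                   direction = "up")),
               "empty intersection")
})
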