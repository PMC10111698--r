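test_that("subset-deletion counts validate and evaluate", {
  expect_equal(pair_count(3, 2), 3)
  expect_equal(pair_count(100, 1), 100)
  expect_error(pair_count(5, 5), "0 < d < n")
  expect_error(pair_count(5, 0), "0 < d < n")
})

test_that("duplicated rows give exchangeable deletion records", {
  d <- make_fuzz_data(19, n = 30)
  d <- rbind(d, d[7, ])                    # rows 7 and 31 are copies
  scan <- fp_influence(d, "y", "x", d = 1)
  rec <- tidy(scan)
  cols <- c("dd_fp2_null", "dd_fp2_linear", "dd_fp2_fp1")
  expect_equal(unlist(rec[rec$id1 == 7, cols]),
               unlist(rec[rec$id1 == 31, cols]), tolerance = 1e-8)

  scan2 <- fp_influence(d, "y", "x", d = 2)
  rec2 <- tidy(scan2)
  # pair (7, k) matches pair (k, 31) for any third row k
  a <- rec2[rec2$id1 == 7 & rec2$id2 == 12, cols]
  b <- rec2[rec2$id1 == 12 & rec2$id2 == 31, cols]
  expect_equal(unlist(a), unlist(b), tolerance = 1e-8)
})

test_that("leave-one-out records match the naive refit oracle", {
  d <- make_fuzz_data(3, n = 28)
  rec <- tidy(fp_influence(d, "y", "x", d = 1))
  for (i in c(1, 9, 17, 28)) {
    o <- oracle_fsp_devs(d, "y", "x", drop = i)
    got <- unlist(rec[rec$id1 == i,
                      c("dd_fp2_null", "dd_fp2_linear", "dd_fp2_fp1")])
    expect_equal(unname(got), unname(o), tolerance = 1e-8)
  }
})

test_that("a planted high-leverage point is flagged and only it", {
  d <- make_planted_ip(4)
  scan <- fp_influence(d, "y", "x", d = 1)
  # the full-data fit is dragged to FP2 by the planted point
  expect_equal(scan$full_decision, "fp2")
  rep05 <- flag_influential(scan, 0.05)
  expect_equal(rep05$flagged_ids, 50L)
  # deleting it restores simplicity: oracle cross-check
  after <- fsp_drop(d, "y", "x", ids = 50)
  expect_true(after$decision %in% c("linear", "fp1"))
})

test_that("flagging levels use their own thresholds independently", {
  d <- make_planted_ip(4)
  scan <- fp_influence(d, "y", "x", d = 1)
  rec <- tidy(scan)
  expect_true(all(rec$sig05_fp1 == (rec$dd_fp2_fp1 >= 5.991459),
                  na.rm = TRUE))
  expect_true(all(rec$sig01_fp1 == (rec$dd_fp2_fp1 >= 9.21034),
                  na.rm = TRUE))
  # an observation can change status at 0.05 without changing it at 0.01
  r05 <- flag_influential(scan, 0.05)$flagged
  r01 <- flag_influential(scan, 0.01)$flagged
  expect_false(identical(r05$id1, r01$id1) &&
                 nrow(r05) == 0 && nrow(r01) == 0)
})

test_that("stable smooth data produces no flags", {
  set.seed(1)
  x <- rlnorm(150, 1, 0.6)
  y <- 2 + 3 * log(x) + rnorm(150, 0, 0.3)   # strong, clean FP1 signal
  scan <- fp_influence(data.frame(y = y, x = x), "y", "x", d = 1)
  expect_equal(nrow(flag_influential(scan, 0.05)$flagged), 0)
})

test_that("pair records match the naive oracle exhaustively at small n", {
  d <- make_fuzz_data(8, n = 25)
  rec <- tidy(fp_influence(d, "y", "x", d = 2))
  expect_equal(nrow(rec), choose(25, 2))
  idx <- c(1, 50, 123, 200, 300)
  for (k in idx) {
    o <- oracle_fsp_devs(d, "y", "x", drop = c(rec$id1[k], rec$id2[k]))
    got <- unlist(rec[k, c("dd_fp2_null", "dd_fp2_linear", "dd_fp2_fp1")])
    expect_equal(unname(got), unname(o), tolerance = 1e-8)
  }
})

test_that("pair groups separate joint influential points as in the boxplot display", {
  for (seed in c(2, 19, 28)) {
    d <- make_planted_pair(seed)
    scan <- fp_influence(d, "y", "x", d = 2, min_n = 10)
    g <- group_pairs(scan, candidates = c(39, 40))
    g1 <- g[g$group == "G1" & g$test == "fp2_fp1", ]
    expect_equal(g1$n, sum(!scan$records$failed))
    g2 <- g[g$group == "G2" & g$test == "fp2_fp1", ]
    g3 <- g[g$group == "G3" & g$test == "fp2_fp1", ]
    # G2 (pairs hitting a planted point) collapses below the threshold,
    # G3 (both points still present) stays above
    expect_lt(g2$median, 5.991)
    expect_gte(g3$median, 5.991)
    expect_equal(g2$n + g3$n, g1$n)
  }
})

test_that("empty candidate sets degenerate G3 to the full pair set", {
  d <- make_fuzz_data(6, n = 24)
  scan <- fp_influence(d, "y", "x", d = 2)
  g <- group_pairs(scan, candidates = integer())
  g1 <- g[g$group == "G1", ]
  g3 <- g[g$group == "G3", ]
  expect_equal(g3$median, g1$median)
  expect_equal(g3$n, g1$n)
  expect_false("G2" %in% g$group && any(g$n[g$group == "G2"] > 0))
})

test_that("targeted multi-point deletion re-runs selection on the remainder", {
  d <- make_planted_ip(10, n = 60)
  r <- fsp_drop(d, "y", "x", ids = c(60, 3, 5))
  ref <- fsp(d[-c(60, 3, 5), ], "y", "x")
  expect_equal(r$decision, ref$decision)
  expect_equal(r$dd, ref$dd, tolerance = 1e-10)
  expect_error(fsp_drop(d, "y", "x", ids = 99))
})

test_that("sequential elimination removes the planted point first", {
  d <- make_planted_ip(12)
  sq <- sequential_deletion(d, "y", "x", max_steps = 3)
  expect_equal(sq$removed[1], 50)
  expect_equal(nrow(flag_influential(sq$final, 0.05)$flagged), 0)
})
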