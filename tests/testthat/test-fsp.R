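test_that("grid search recovers noiseless generating functions", {
  x <- seq(0.5, 20, length.out = 60)
  b <- best_fp(data.frame(y = log(x), x = x), "y", "x", degree = 1)
  expect_equal(b$p1, 0)
  expect_lt(b$rss, 1e-15)

  d <- data.frame(y = x + x^2, x = x)
  b2 <- best_fp(d, "y", "x", degree = 2)
  expect_equal(c(b2$p1, b2$p2), c(1, 2))  # the quadratic lives in the grid
  expect_lt(b2$rss, 1e-10)
})

test_that("grid search matches an exhaustive lm() loop on random data", {
  for (seed in c(5, 23, 77)) {
    d <- make_fuzz_data(seed, n = 45)
    sh <- fp_shift(d$x); sc <- fp_scale(d$x, sh)
    z <- (d$x + sh) / sc
    tr <- function(p) if (p == 0) log(z) else z^p
    grid <- fp_powers(2)
    devs <- vapply(seq_len(nrow(grid)), function(i) {
      p1 <- grid$p1[i]; p2 <- grid$p2[i]
      X <- if (grid$degree[i] == 1) cbind(tr(p1))
      else if (p1 == p2) cbind(tr(p1), tr(p1) * log(z))
      else cbind(tr(p1), tr(p2))
      oracle_deviance(lm(d$y ~ X))
    }, numeric(1))
    for (deg in 1:2) {
      b <- best_fp(d, "y", "x", degree = deg)
      expect_equal(b$deviance, min(devs[grid$degree == deg]),
                   tolerance = 1e-8)
    }
  }
})

test_that("closed test stops at the first non-significant step", {
  for (seed in 1:40) {
    d <- make_fuzz_data(seed)
    r <- fsp(d, "y", "x", alpha = 0.05)
    if (r$decision == "out") {
      expect_gt(r$p_fp2_null, 0.05)
      expect_true(is.na(r$p_fp2_linear) && is.na(r$p_fp2_fp1))
    } else if (r$decision == "linear") {
      expect_lte(r$p_fp2_null, 0.05)
      expect_gt(r$p_fp2_linear, 0.05)
      expect_true(is.na(r$p_fp2_fp1))
    } else if (r$decision == "fp1") {
      expect_lte(r$p_fp2_null, 0.05)
      expect_lte(r$p_fp2_linear, 0.05)
      expect_gt(r$p_fp2_fp1, 0.05)
      expect_true(r$powers != 1)
    } else {
      expect_lte(r$p_fp2_null, 0.05)
      expect_lte(r$p_fp2_linear, 0.05)
      # p_fp2_fp1 is NA only via the linear-FP1 shortcut
      expect_true(is.na(r$p_fp2_fp1) || r$p_fp2_fp1 <= 0.05)
    }
    # monotone nesting of the four model classes
    expect_true(all(r$dd >= 0))
    dev <- r$deviances
    expect_true(dev["fp2"] <= dev["fp1"] + 1e-8 &&
                  dev["fp1"] <= dev["linear"] + 1e-8 &&
                  dev["linear"] <= dev["null"] + 1e-8)
  }
})

test_that("forcing a variable skips the first step", {
  set.seed(9)
  d <- data.frame(y = rnorm(100), x = rlnorm(100))  # pure noise
  r <- fsp(d, "y", "x", alpha_select = 1, alpha_function = 0.05)
  expect_true(is.na(r$p_fp2_null))
  expect_true(r$decision != "out")
  # the same data is excluded when not forced
  r2 <- fsp(d, "y", "x", alpha = 0.05)
  expect_equal(r2$decision, "out")
})

test_that("adjustment columns change the test but not its coherence", {
  set.seed(15)
  n <- 120
  a <- rnorm(n)
  x <- rlnorm(n, 1, 0.6)
  y <- 2 * a + 0.5 * log(x) + rnorm(n, 0, 0.4)
  d <- data.frame(y = y, x = x, a = a)
  r_adj <- fsp(d, "y", "x", adjust = "a")
  expect_true(r_adj$decision %in% c("linear", "fp1", "fp2"))
  # oracle check of the adjusted deviance differences
  o <- oracle_fsp_devs(d, "y", "x", adjust = "a")
  expect_equal(unname(r_adj$dd), unname(o), tolerance = 1e-8)
})

test_that("F-statistic variant gives coherent, similar decisions", {
  set.seed(31)
  x <- rlnorm(200, 1, 0.7)
  y <- 0.8 * log(x) + rnorm(200, 0, 0.5)
  d <- data.frame(y = y, x = x)
  rc <- fsp(d, "y", "x")
  rf <- fsp(d, "y", "x", test = "f")
  expect_equal(rc$decision, rf$decision)
  # F p-values are larger than chi-squared ones at moderate n
  expect_gte(rf$p_fp2_null, rc$p_fp2_null)
})

test_that("invalid significance levels are rejected", {
  d <- data.frame(y = rnorm(30), x = rlnorm(30))
  expect_error(fsp(d, "y", "x", alpha_select = 0), "alpha_select")
  expect_error(fsp(d, "y", "x", alpha_function = 1.5), "alpha_function")
})

test_that("the univariable table stacks one tidy row per variable", {
  d <- simulate_art(150, seed = 42)
  tab <- fsp_table(d, "y", art_continuous)
  expect_equal(tab$variable, art_continuous)
  expect_true(all(tab$decision %in% c("out", "linear", "fp1", "fp2")))
  expect_true(all(is.na(tab$p_fp2_null) | tab$p_fp2_null <= 1))
})
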