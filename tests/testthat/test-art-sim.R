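test_that("the generator is exactly reproducible and seed-sensitive", {
  a <- simulate_art(200, seed = 99)
  b <- simulate_art(200, seed = 99)
  expect_identical(a, b)
  c <- simulate_art(200, seed = 100)
  expect_false(identical(a$y, c$y))
  expect_named(a, c("y", "x1", "x2", "x3", "x4a", "x4b", "x5", "x6", "x7",
                    "x8", "x9a", "x9b", "x10"))
})

test_that("covariates respect their structural constraints", {
  d <- simulate_art(2000, seed = 1)
  expect_true(all(d$x5 >= 2))
  expect_true(min(d$x6) == 0)              # zeros force the +1 shift
  expect_equal(fp_shift(d$x6), 1)
  expect_true(all(d$x2 %in% 0:1) && all(d$x8 %in% 0:1))
  # ordinal dummies are nested, reference dummies exclusive
  expect_true(all(d$x4a >= d$x4b))
  expect_true(all(d$x9a + d$x9b <= 1))
})

test_that("zero noise makes the outcome an exact function of the covariates", {
  spec <- art_true_model()
  spec$sigma2 <- 0
  d <- simulate_art(500, seed = 7, spec = spec)
  f <- fit_gaussian(d$y, art_true_basis(d))
  expect_lt(f$rss, 1e-18)
})

test_that("large-sample fits recover the generating coefficients", {
  d <- simulate_art(50000, seed = 2)
  X <- art_true_basis(d)
  f <- lm(d$y ~ X)
  est <- coef(f)
  se <- sqrt(diag(vcov(f)))
  truth <- c(-4, 3.5, -0.25, -0.018, -0.4, 4, 0.25, 0.4, 0.021)
  expect_true(all(abs(est - truth) <= 2.5 * se))
})

test_that("descriptive flags reproduce the documented covariate pattern", {
  flags <- sapply(1:100, function(s) {
    ds <- describe_covariates(simulate_art(250, seed = 400 + s))
    g <- function(v, col) ds[[col]][ds$variable == v]
    c(g("x5", "skew_flag"), g("x7", "skew_flag"),
      g("x3", "kurt_flag"), g("x5", "kurt_flag"),
      g("x6", "kurt_flag"), g("x7", "kurt_flag"))
  })
  expect_true(all(rowMeans(flags) >= 0.9))
})

test_that("moment flags behave on known distributions", {
  set.seed(10)
  d <- data.frame(norm = rnorm(5000), heavy = rlnorm(5000, 0, 1.5),
                  konst = rep(2, 5000))
  ds <- describe_covariates(d)
  expect_false(ds$skew_flag[ds$variable == "norm"])
  expect_false(ds$kurt_flag[ds$variable == "norm"])
  expect_true(ds$skew_flag[ds$variable == "heavy"])
  expect_true(ds$kurt_flag[ds$variable == "heavy"])
  expect_true(ds$degenerate[ds$variable == "konst"])
  expect_true(is.na(ds$skewness[ds$variable == "konst"]))
})

test_that("R-squared reduction ranks the dominant variables first", {
  d <- simulate_art(30000, seed = 3)
  red <- vapply(c("x1", "x3", "x5", "x6", "x10"),
                function(v) r2_reduction(d, "y", variable = v), numeric(1))
  expect_gt(red[["x5"]], red[["x6"]])
  expect_true(all(red[["x6"]] > red[c("x1", "x3", "x10")]))
})

test_that("R-squared reduction matches the orthogonal closed form", {
  set.seed(21)
  n <- 4000
  # exactly orthogonal, mean-centred columns
  Q <- qr.Q(qr(scale(matrix(rnorm(n * 2), n, 2), scale = FALSE)))
  x1 <- Q[, 1]; x2 <- Q[, 2]
  y <- 3 * x1 + 1 * x2                         # noiseless
  d <- data.frame(y = y)
  basis <- cbind(a = x1, b = x2)
  # R2_full = 1; dropping b leaves R2 = var(3 x1)/var(y)
  expected <- 100 * (1 - 9 * stats::var(x1) / stats::var(y))
  expect_equal(r2_reduction(d, "y", basis = basis, variable = "b"),
               expected, tolerance = 1e-8)
  # a zero-coefficient term contributes nothing
  basis2 <- cbind(basis, c = rnorm(n))
  y2 <- 3 * x1
  expect_equal(r2_reduction(data.frame(y = y2), "y", basis = basis2,
                            variable = "c"), 0, tolerance = 1e-6)
  expect_error(r2_reduction(d, "y", basis = basis, variable = "zz"),
               "basis column")
})

test_that("external datasets load, validate and subset by the standard ranges", {
  d <- simulate_art(4500, seed = 55)
  path <- file.path(tempdir(), "synthetic_art.csv")
  utils::write.csv(d, path, row.names = FALSE)
  loaded <- art_load(path)
  attr(d, "seed") <- NULL
  attr(d, "sigma2") <- NULL
  expect_equal(as.data.frame(loaded), as.data.frame(d), tolerance = 1e-12)
  expect_equal(nrow(art_subset(loaded, "A250")), 250)
  expect_equal(art_subset(loaded, "B250")$y, d$y[2001:2250])
  expect_equal(art_subset(loaded, "D1000")$y, d$y[3501:4500])
  expect_equal(nrow(art_subset(loaded, c(11, 20))), 10)
  expect_error(art_subset(loaded, "Z9"), "Unknown subset")
  expect_error(art_subset(loaded[1:100, ], "A250"), "exceeds")
  # raw 3-level coding is expanded into the dummy layout
  raw <- data.frame(y = 1:6, x1 = 1:6, x2 = 0, x3 = 1:6,
                    x4 = c(1, 2, 3, 1, 2, 3), x5 = 1:6, x6 = 0:5,
                    x7 = 1:6, x8 = 1, x9 = c(1, 1, 2, 2, 3, 3), x10 = 1:6)
  path2 <- file.path(tempdir(), "synthetic_raw.csv")
  utils::write.csv(raw, path2, row.names = FALSE)
  l2 <- art_load(path2)
  expect_equal(l2$x4a, c(0, 1, 1, 0, 1, 1))
  expect_equal(l2$x4b, c(0, 0, 1, 0, 0, 1))
  expect_equal(l2$x9b, c(0, 0, 0, 0, 1, 1))
})

test_that("correlation summaries cover both rank and linear association", {
  d <- simulate_art(3000, seed = 6)
  cp <- covariate_correlations(d[c("x1", "x3", "x5", "x6")])
  cs <- covariate_correlations(d[c("x1", "x3", "x5", "x6")],
                               method = "spearman")
  expect_equal(nrow(cp), choose(4, 2))
  get <- function(tab, a, b) {
    tab$correlation[(tab$var1 == a & tab$var2 == b) |
                      (tab$var1 == b & tab$var2 == a)]
  }
  expect_gt(get(cs, "x1", "x3"), 0.1)      # copula-induced association
  expect_lt(get(cs, "x5", "x6"), 0)
})
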