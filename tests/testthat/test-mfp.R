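test_that("selection matches the generating model's structure at n = 500", {
  hit <- sapply(1:30, function(s) {
    d <- simulate_art(500, seed = s)
    sel <- mfp(d, "y", art_continuous, art_binary)$selection
    st <- function(v) sel$status[sel$variable == v]
    c(x7_out = st("x7") == "out",
      x5_nonlin = st("x5") %in% c("fp1", "fp2"),
      x6_nonlin = st("x6") %in% c("fp1", "fp2"),
      x8_in = st("x8") == "in")
  })
  expect_true(all(rowMeans(hit) > 0.5))  # each in a majority of seeds
})

test_that("the final fit is self-consistent and convergent", {
  d <- simulate_art(300, seed = 8)
  m <- mfp(d, "y", art_continuous, art_binary)
  expect_true(m$converged)
  expect_lte(m$cycles, 5)
  # reported deviance equals a fresh fit of the final design
  y <- d$y
  X <- mfpdx:::mfp_design(m$selection, d)
  expect_equal(m$deviance, fit_gaussian(y, X)$deviance, tolerance = 1e-10)
  # refit on the training data is the identity
  m2 <- refit(m, d)
  expect_equal(m2$coefficients, m$coefficients, tolerance = 1e-10)
})

test_that("refit freezes structure and re-estimates coefficients", {
  d1 <- simulate_art(400, seed = 21)
  d2 <- simulate_art(400, seed = 22)
  m <- mfp(d1, "y", art_continuous, art_binary)
  r <- refit(m, d2)
  expect_identical(r$selection, m$selection)
  expect_equal(names(r$coefficients), names(m$coefficients))
  expect_false(isTRUE(all.equal(r$coefficients, m$coefficients)))
  # dropping a row cannot increase the training RSS
  r_drop <- refit(m, d1[-17, ])
  expect_lte(r_drop$rss, m$rss + 1e-10)
  expect_error(refit(m, d1[, 1:3]), "not found")
})

test_that("pure-noise covariates are mostly eliminated", {
  empty <- sapply(1:40, function(s) {
    set.seed(1000 + s)
    n <- 300
    d <- data.frame(y = rnorm(n), c1 = rlnorm(n), c2 = rlnorm(n),
                    b1 = rbinom(n, 1, 0.5))
    m <- mfp(d, "y", continuous = c("c1", "c2"), binary = "b1")
    sum(m$selection$status != "out") == 0
  })
  # roughly (1 - alpha)^3 of replicates keep nothing; test loosely
  expect_gt(mean(empty), 0.6)
  expect_lt(mean(empty), 0.98)
})

test_that("forced variables survive even under pure noise", {
  set.seed(77)
  n <- 200
  d <- data.frame(y = rnorm(n), a = rlnorm(n), b = rbinom(n, 1, 0.4))
  m <- mfp(d, "y", continuous = "a", binary = "b", forced = c("a", "b"))
  expect_true(all(m$selection$status != "out"))
})

test_that("a vanishing function-selection level degenerates to linear backward elimination", {
  d <- simulate_art(300, seed = 31)
  m <- mfp(d, "y", art_continuous, art_binary, alpha_select = 0.05,
           alpha_function = 1e-300)
  sel <- m$selection[m$selection$role == "continuous", ]
  expect_true(all(sel$status %in% c("out", "linear")))
})

test_that("tidy and glance expose the selection and fit summaries", {
  d <- simulate_art(200, seed = 12)
  m <- mfp(d, "y", art_continuous, art_binary)
  td <- tidy(m)
  expect_equal(nrow(td), 12)
  expect_true(all(c("variable", "status", "label") %in% names(td)))
  co <- tidy(m, type = "coefficients")
  expect_equal(co$term[1], "(Intercept)")
  gl <- glance(m)
  expect_equal(gl$n, 200)
  expect_true(gl$r.squared > 0 && gl$r.squared < 1)
  pr <- predict(m, d)
  expect_equal(mean((d$y - pr)^2) * 200, m$rss, tolerance = 1e-8)
})
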