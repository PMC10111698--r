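# Independent oracles and data constructors shared across tests.
#
# The oracle routines deliberately avoid the package's cross-product /
# case-deletion machinery: every fit is a fresh stats::lm() on explicitly
# rebuilt data, so agreement with the package is a genuine cross-check.

# Deviance of an lm fit under the Gaussian -2 log-likelihood convention.
oracle_deviance <- function(fit) {
  n <- length(fit$residuals)
  rss <- sum(fit$residuals^2)
  n * log(2 * pi * rss / n) + n
}

# The three closed-test deviance differences for variable `x` of `data`,
# optionally after deleting rows `drop`, re-searching both grids from
# scratch with plain lm() fits.  Shift/scale are taken from the full data,
# matching the scan's convention.
oracle_fsp_devs <- function(data, outcome, x, drop = NULL, adjust = NULL,
                            offset = NULL) {
  sh <- fp_shift(data[[x]])
  sc <- fp_scale(data[[x]], sh)
  keep <- if (is.null(drop)) seq_len(nrow(data)) else
    setdiff(seq_len(nrow(data)), drop)
  d <- data[keep, , drop = FALSE]
  y <- d[[outcome]]
  if (!is.null(offset)) y <- y - offset[keep]
  A <- if (is.null(adjust)) NULL else as.matrix(data[adjust])[keep, , drop = FALSE]
  z <- (d[[x]] + sh) / sc
  tr <- function(p) if (p == 0) log(z) else z^p
  grid <- fp_powers(2)
  devs <- vapply(seq_len(nrow(grid)), function(i) {
    p1 <- grid$p1[i]; p2 <- grid$p2[i]
    X <- if (grid$degree[i] == 1) cbind(tr(p1))
    else if (p1 == p2) cbind(tr(p1), tr(p1) * log(z))
    else cbind(tr(p1), tr(p2))
    oracle_deviance(stats::lm(y ~ cbind(A, X)))
  }, numeric(1))
  dev_null <- oracle_deviance(if (is.null(A)) stats::lm(y ~ 1) else
    stats::lm(y ~ A))
  dev_lin <- oracle_deviance(stats::lm(y ~ cbind(A, z)))
  fp2 <- min(devs[grid$degree == 2])
  c(fp2_null = dev_null - fp2, fp2_linear = dev_lin - fp2,
    fp2_fp1 = min(devs[grid$degree == 1]) - fp2)
}

# Linear data plus one high-leverage observation pulled far below the
# trend: only an FP2 (non-monotone) function can chase it, and removing it
# restores the simple linear fit.  The planted index is the last row.
make_planted_ip <- function(seed, n = 50) {
  set.seed(seed)
  x <- stats::runif(n - 1, 1, 10)
  y <- 2 + 0.5 * x + stats::rnorm(n - 1, 0, 0.3)
  data.frame(y = c(y, 2 + 0.5 * 5), x = c(x, 30))
}

# Linear data plus a duplicated moderate outlier: the two copies jointly
# drive the FP2-vs-FP1 test, but neither alone suffices, so pairs hitting
# at least one of them fall below the threshold.  Planted indices: n-1, n.
make_planted_pair <- function(seed, n = 40, delta = 1.0, x0 = 22) {
  set.seed(seed)
  x <- stats::runif(n - 2, 1, 10)
  y <- 2 + 0.5 * x + stats::rnorm(n - 2, 0, 0.3)
  data.frame(y = c(y, rep(2 + 0.5 * x0 - delta, 2)), x = c(x, x0, x0))
}

# Small random dataset with a skewed positive covariate and a smooth
# signal; used for fuzzed property checks.
make_fuzz_data <- function(seed, n = 40) {
  set.seed(seed)
  x <- stats::rlnorm(n, 1, 0.8)
  g <- sample(1:4, 1)
  f <- switch(g, 0.4 * log(x), 0.1 * x, 0.3 * sqrt(x), rep(0, n))
  data.frame(y = f + stats::rnorm(n, 0, sample(c(0.2, 0.5, 1), 1)), x = x)
}

art_continuous <- c("x1", "x3", "x5", "x6", "x7", "x10")
art_binary <- c("x2", "x4a", "x4b", "x8", "x9a", "x9b")
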