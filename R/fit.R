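# Gaussian least-squares engine backing the FP grid searches.
#
# All model comparisons use the Gaussian deviance (-2 maximised
# log-likelihood), D = n log(2*pi*RSS/n) + n, so a difference between nested
# fits is n log(RSS_reduced / RSS_full).

#' Gaussian deviance from a residual sum of squares
#'
#' @param rss Residual sum of squares (non-negative).
#' @param n Number of observations.
#' @return `n * log(2 * pi * rss / n) + n`, the -2 maximised Gaussian
#'   log-likelihood.
#' @export
gaussian_deviance <- function(rss, n) n * log(2 * pi * rss / n) + n

#' Upper-tail chi-squared critical value
#'
#' The deviance-difference thresholds used throughout the closed test and the
#' influence diagnostics, e.g. 9.488 / 7.815 / 5.991 for k = 4, 3, 2 at the
#' 0.05 level.
#'
#' @param k Degrees of freedom (positive integer).
#' @param alpha Significance level in (0, 1).
#' @return The upper-`alpha` quantile of the chi-squared distribution.
#' @export
chi2_critical <- function(k, alpha) {
  if (!is.numeric(k) || any(k < 1) || any(k != round(k))) {
    stop("`k` must be a positive integer.", call. = FALSE)
  }
  if (!is.numeric(alpha) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must be in (0, 1).", call. = FALSE)
  }
  stats::qchisq(1 - alpha, df = k)
}

#' Ordinary least squares with Gaussian deviance
#'
#' Fits `y` on a design matrix (an intercept is prepended unless one is
#' present) and records the quantities the function selection procedure
#' needs: coefficients, residual sum of squares, and deviance.
#'
#' @param y Numeric response.
#' @param design Numeric matrix of covariate columns (may be `NULL` for an
#'   intercept-only fit).
#' @param offset Optional numeric offset subtracted from `y` before fitting.
#' @return An object of class `fp_fit`: a list with `coefficients`, `rss`,
#'   `n`, `deviance`, `rank` and `df.residual`.
#' @export
fit_gaussian <- function(y, design = NULL, offset = NULL) {
  y <- as.numeric(y)
  if (!is.null(offset)) y <- y - offset
  n <- length(y)
  X <- cbind(`(Intercept)` = rep(1, n), design)
  if (n < ncol(X) + 1) {
    stop("Need at least ncol(design) + 2 observations.", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("Design is rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  beta <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  structure(
    list(coefficients = beta, rss = rss, n = n,
         deviance = gaussian_deviance(rss, n),
         rank = qx$rank, df.residual = n - qx$rank,
         qr = qx, residuals = res),
    class = "fp_fit"
  )
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("Gaussian least-squares fit: n =", x$n,
      " rss =", format(x$rss, digits = 6),
      " deviance =", format(x$deviance, digits = 6), "\n")
  print(x$coefficients)
  invisible(x)
}

#' @export
glance.fp_fit <- function(x, ...) {
  tibble::tibble(n = x$n, rss = x$rss, deviance = x$deviance,
                 df.residual = x$df.residual)
}

# ---- internal cross-product grid engine -----------------------------------
#
# For one continuous variable, the 46 models of interest (null, linear,
# 8 FP1, 36 FP2) are column subsets of [1 | A | master(16)].  A single
# cross-product of that matrix with y appended supports every fit via small
# normal-equation solves.

# Build the engine state for variable x with adjustment matrix A (may be
# NULL).  Returns list(C, n, nadj, sets, grid, yty).
fp_engine <- function(y, x, adjust = NULL, offset = NULL,
                      shift = fp_shift(x), scale = fp_scale(x, shift)) {
  y <- as.numeric(y)
  if (!is.null(offset)) y <- y - offset
  n <- length(y)
  M <- fp_master_basis(x, shift, scale)
  A <- if (is.null(adjust)) NULL else as.matrix(adjust)
  Z <- cbind(1, A, M, y)
  nadj <- if (is.null(A)) 0L else ncol(A)
  grid <- fp_powers(2)
  sets <- fp_model_columns(grid)
  base_idx <- seq_len(1 + nadj)              # intercept + adjustment
  fp_off <- 1 + nadj                          # offset of master cols in Z
  list(C = crossprod(Z), Z = Z, n = n, nadj = nadj, base_idx = base_idx,
       fp_off = fp_off, sets = sets, grid = grid,
       pref = fp_preference_order(grid), shift = shift, scale = scale)
}

# RSS for the model using Z-columns `idx` (response is last column of C).
# Returns NA on a (near-)singular normal matrix.
fp_rss <- function(C, idx) {
  yc <- ncol(C)
  A <- C[idx, idx, drop = FALSE]
  b <- C[idx, yc]
  R <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(R)) return(NA_real_)
  beta <- backsolve(R, forwardsolve(t(R), b))
  max(C[yc, yc] - sum(b * beta), 0)
}

# Deviances of every grid model plus null and linear.
# Returns list(dev_null, dev_linear, dev: vector over grid rows).
fp_grid_deviances <- function(eng) {
  C <- eng$C; n <- eng$n
  dev <- function(rss) gaussian_deviance(rss, n)
  rss_null <- fp_rss(C, eng$base_idx)
  lin_col <- eng$fp_off + match(1, FP_POWER_SET)
  rss_lin <- fp_rss(C, c(eng$base_idx, lin_col))
  rss_grid <- vapply(eng$sets, function(s) fp_rss(C, c(eng$base_idx, eng$fp_off + s)),
                     numeric(1))
  list(dev_null = dev(rss_null), dev_linear = dev(rss_lin),
       dev = dev(rss_grid), rss_null = rss_null, rss_linear = rss_lin,
       rss = rss_grid)
}

# Index (into eng$grid) of the best model of a given degree, with the
# deterministic tie-break: minimum deviance, ties within 1e-10 relative
# resolved towards powers closest to 1 then lexicographically smaller.
fp_best_index <- function(eng, devs, degree) {
  rows <- which(eng$grid$degree == degree)
  d <- devs$dev[rows]
  if (all(is.na(d))) return(NA_integer_)
  dmin <- min(d, na.rm = TRUE)
  # dmin is -Inf for an exact fit; any model achieving it ties
  tol <- if (is.finite(dmin)) 1e-10 * max(1, abs(dmin)) else 0
  cand <- rows[!is.na(d) & d <= dmin + tol]
  cand[order(match(cand, eng$pref))][1]
}
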