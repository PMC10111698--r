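# Function selection procedure: three-step closed test over the FP grid.

#' Best-fitting fractional polynomial of a given degree
#'
#' Exhaustively searches the FP grid of the stated degree (8 FP1 or 36 FP2
#' candidates) for the minimum-deviance fit of `x` against `outcome`,
#' optionally adjusted for other columns entered linearly.  Ties in deviance
#' (within 1e-10 relative) are broken towards powers closest to 1, then
#' lexicographically.
#'
#' @param data A data frame.
#' @param outcome Name of the continuous outcome column.
#' @param x Name of the continuous covariate.
#' @param degree FP degree to search, 1 or 2.
#' @param adjust Character vector of adjustment columns (entered untransformed),
#'   or a numeric matrix with `nrow(data)` rows.
#' @param offset Optional numeric offset subtracted from the outcome.
#' @return A one-row tibble: `degree`, `p1`, `p2`, `rss`, `deviance`, `n`.
#' @export
best_fp <- function(data, outcome, x, degree = 2, adjust = NULL,
                    offset = NULL) {
  v <- fsp_inputs(data, outcome, x, adjust)
  eng <- fp_engine(v$y, v$x, v$A, offset)
  devs <- fp_grid_deviances(eng)
  i <- fp_best_index(eng, devs, degree)
  if (is.na(i)) stop("All degree-", degree, " fits failed.", call. = FALSE)
  tibble::tibble(degree = eng$grid$degree[i], p1 = eng$grid$p1[i],
                 p2 = eng$grid$p2[i], rss = devs$rss[i],
                 deviance = devs$dev[i], n = eng$n)
}

# resolve and validate data-frame inputs shared by fsp / best_fp / scans
fsp_inputs <- function(data, outcome, x, adjust = NULL) {
  stopifnot(is.data.frame(data))
  for (nm in c(outcome, x)) {
    if (!nm %in% names(data)) stop("Column `", nm, "` not found.", call. = FALSE)
  }
  A <- NULL
  if (is.matrix(adjust)) {
    A <- adjust
  } else if (!is.null(adjust) && length(adjust)) {
    miss <- setdiff(adjust, names(data))
    if (length(miss)) stop("Adjustment columns not found: ",
                           paste(miss, collapse = ", "), call. = FALSE)
    A <- as.matrix(data[adjust])
  }
  list(y = as.numeric(data[[outcome]]), x = as.numeric(data[[x]]), A = A)
}

#' Function selection procedure (closed test) for one continuous variable
#'
#' Decides between excluding `x`, a linear term, the best FP1, or the best
#' FP2 function, using the three-step closed test: best FP2 against the null
#' model (4 df), against the linear model (3 df), and against the best FP1
#' (2 df).  Each p-value comes from the chi-squared survival function of the
#' deviance difference, and testing stops at the first non-significant step,
#' so the overall type-I error stays close to the nominal level.
#'
#' Two significance levels can be supplied: `alpha_select` for the first
#' step (variable inclusion) and `alpha_function` for the second and third
#' (choice of functional form).  A forced variable (`alpha_select = 1`)
#' skips the first step.  When the best FP1 is the linear function, the
#' third step is redundant and is skipped.
#'
#' @inheritParams best_fp
#' @param alpha Significance level used for both components unless
#'   overridden.
#' @param alpha_select Level for step 1 (set to 1 to force the variable in).
#' @param alpha_function Level for steps 2 and 3.
#' @param test `"chisq"` (default, matching the printed thresholds) or
#'   `"f"` for the small-sample F approximation.
#' @return An object of class `fsp_result`; see [tidy.fsp_result()].
#' @export
fsp <- function(data, outcome, x, adjust = NULL, alpha = 0.05,
                alpha_select = alpha, alpha_function = alpha,
                offset = NULL, test = c("chisq", "f")) {
  test <- match.arg(test)
  if (!is.numeric(alpha_select) || alpha_select <= 0 || alpha_select > 1) {
    stop("`alpha_select` must be in (0, 1].", call. = FALSE)
  }
  if (!is.numeric(alpha_function) || alpha_function <= 0 ||
      alpha_function > 1) {
    stop("`alpha_function` must be in (0, 1].", call. = FALSE)
  }
  v <- fsp_inputs(data, outcome, x, adjust)
  eng <- fp_engine(v$y, v$x, v$A, offset)
  devs <- fp_grid_deviances(eng)
  res <- fsp_decide(eng, devs, alpha_select, alpha_function, test)
  res$variable <- x
  res$alpha_select <- alpha_select
  res$alpha_function <- alpha_function
  res$n <- eng$n
  res$shift <- eng$shift
  res$scale <- eng$scale
  class(res) <- "fsp_result"
  res
}

# closed test on precomputed grid deviances; shared with the scans
fsp_decide <- function(eng, devs, alpha_select, alpha_function, test = "chisq") {
  n <- eng$n
  i1 <- fp_best_index(eng, devs, 1)
  i2 <- fp_best_index(eng, devs, 2)
  dev_fp1 <- devs$dev[i1]
  dev_fp2 <- devs$dev[i2]
  pow1 <- eng$grid$p1[i1]
  pow2 <- c(eng$grid$p1[i2], eng$grid$p2[i2])
  pval <- function(dd, k, rss_full) {
    if (test == "chisq") {
      stats::pchisq(dd, df = k, lower.tail = FALSE)
    } else {
      # F approximation: translate the deviance difference back to RSS
      rss_red <- rss_full * exp(dd / n)
      p_full <- 1 + eng$nadj + 4
      stats::pf(((rss_red - rss_full) / k) / (rss_full / (n - p_full)),
                k, n - p_full, lower.tail = FALSE)
    }
  }
  # the grids are nested (null < linear < FP1 < FP2 via repeated powers),
  # so each difference is nonnegative; clamp solver noise at zero
  dd1 <- max(devs$dev_null - dev_fp2, 0)
  dd2 <- max(devs$dev_linear - dev_fp2, 0)
  dd3 <- max(dev_fp1 - dev_fp2, 0)
  out <- list(
    dd = c(fp2_null = dd1, fp2_linear = dd2, fp2_fp1 = dd3),
    deviances = c(null = devs$dev_null, linear = devs$dev_linear,
                  fp1 = dev_fp1, fp2 = dev_fp2),
    best_fp1 = pow1, best_fp2 = pow2,
    p_fp2_null = NA_real_, p_fp2_linear = NA_real_, p_fp2_fp1 = NA_real_
  )
  forced <- alpha_select >= 1
  if (!forced) {
    out$p_fp2_null <- pval(dd1, 4, devs$rss[i2])
    if (out$p_fp2_null > alpha_select) {
      out$decision <- "out"; out$powers <- NULL
      return(out)
    }
  }
  out$p_fp2_linear <- pval(dd2, 3, devs$rss[i2])
  if (out$p_fp2_linear > alpha_function) {
    out$decision <- "linear"; out$powers <- 1
    return(out)
  }
  if (pow1 == 1) {
    # best FP1 is the linear function already rejected: step 3 redundant
    out$decision <- "fp2"; out$powers <- pow2
    return(out)
  }
  out$p_fp2_fp1 <- pval(dd3, 2, devs$rss[i2])
  if (out$p_fp2_fp1 > alpha_function) {
    out$decision <- "fp1"; out$powers <- pow1
  } else {
    out$decision <- "fp2"; out$powers <- pow2
  }
  out
}

#' @export
print.fsp_result <- function(x, ...) {
  cat("Function selection for `", x$variable, "` (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  FP2 vs null:   p = %s\n  FP2 vs linear: p = %s\n  FP2 vs FP1:    p = %s\n",
              fmt_p(x$p_fp2_null), fmt_p(x$p_fp2_linear), fmt_p(x$p_fp2_fp1)))
  cat("  decision:", format_decision(x$decision, x$powers), "\n")
  invisible(x)
}

fmt_p <- function(p) if (is.na(p)) "-" else formatC(p, digits = 3, format = "f")

format_decision <- function(decision, powers) {
  switch(decision,
         out = "out",
         linear = "linear",
         fp1 = paste0("FP1(", powers, ")"),
         fp2 = paste0("FP2(", powers[1], ", ", powers[2], ")"))
}

#' Tidy a function-selection result
#'
#' @param x An `fsp_result`.
#' @param ... Unused.
#' @return A one-row tibble with the variable name, the three closed-test
#'   p-values, the decision, and the selected powers.
#' @export
tidy.fsp_result <- function(x, ...) {
  tibble::tibble(
    variable = x$variable,
    p_fp2_null = x$p_fp2_null,
    p_fp2_linear = x$p_fp2_linear,
    p_fp2_fp1 = x$p_fp2_fp1,
    decision = x$decision,
    powers = list(x$powers),
    label = format_decision(x$decision, x$powers),
    n = x$n
  )
}

#' Univariable function-selection table
#'
#' Runs [fsp()] for each listed continuous variable and stacks the tidied
#' results: one row per variable with the three closed-test p-values and the
#' selected functional form.
#'
#' @inheritParams fsp
#' @param xvars Character vector of continuous covariate names.
#' @return A tibble, one row per variable.
#' @export
fsp_table <- function(data, outcome, xvars, adjust = NULL, alpha = 0.05,
                      alpha_select = alpha, alpha_function = alpha) {
  purrr::map_dfr(xvars, function(v) {
    generics::tidy(fsp(data, outcome, v, adjust = adjust,
                       alpha_select = alpha_select,
                       alpha_function = alpha_function))
  })
}
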