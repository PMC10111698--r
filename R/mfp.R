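# Multivariable model building: backward elimination interleaved with the
# function selection procedure, cycled until no decision changes.

#' Multivariable fractional polynomial model selection
#'
#' Builds a Gaussian regression model by cycling over the candidate
#' variables: each continuous variable is offered the closed-test choice
#' between exclusion, a linear term, the best FP1 and the best FP2 function
#' (adjusting for the current working form of all other retained variables),
#' while each binary or dummy variable gets a 1-df inclusion test.  Visits
#' follow ascending p-values from the initial full linear fit; cycles repeat
#' until a whole cycle leaves every decision unchanged.  `MFP(a1, a2)`
#' selects variables at level `a1` and functional forms at level `a2`.
#'
#' Variables previously dropped remain candidates and are re-tested every
#' cycle.  Dummy columns of a categorical variable are tested individually.
#' Forced variables are never removed (their inclusion step is skipped).
#'
#' @param data A data frame containing the outcome and all covariates.
#' @param outcome Name of the continuous outcome column.
#' @param continuous Character vector of continuous covariate names (offered
#'   FP transforms).
#' @param binary Character vector of binary / dummy covariate names (entered
#'   untransformed).
#' @param forced Character vector of covariates that must stay in the model.
#' @param alpha_select Significance level for variable inclusion.
#' @param alpha_function Significance level for function selection.
#' @param max_cycles Maximum number of full cycles (default 5; the procedure
#'   normally converges in 2-3).
#' @return An object of class `mfp_fit` with the per-variable decisions,
#'   final coefficients, deviance, and convergence status.  See
#'   [tidy.mfp_fit()] and [glance.mfp_fit()].
#' @export
mfp <- function(data, outcome, continuous = NULL, binary = NULL,
                forced = NULL, alpha_select = 0.05,
                alpha_function = alpha_select, max_cycles = 5) {
  stopifnot(is.data.frame(data))
  vars <- c(continuous, binary)
  miss <- setdiff(c(outcome, vars), names(data))
  if (length(miss)) stop("Columns not found: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (!length(vars)) stop("No candidate covariates supplied.", call. = FALSE)
  bad <- setdiff(forced, vars)
  if (length(bad)) stop("`forced` names not among candidates: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  y <- as.numeric(data[[outcome]])

  state <- tibble::tibble(
    variable = vars,
    role = c(rep("continuous", length(continuous)),
             rep("binary", length(binary))),
    forced = vars %in% forced,
    status = ifelse(vars %in% continuous, "linear", "in"),
    p1 = NA_real_, p2 = NA_real_,
    shift = 0, scale = 1,
    p_fp2_null = NA_real_, p_fp2_linear = NA_real_, p_fp2_fp1 = NA_real_,
    p_incl = NA_real_
  )
  for (i in which(state$role == "continuous")) {
    xi <- as.numeric(data[[state$variable[i]]])
    state$shift[i] <- fp_shift(xi)
    state$scale[i] <- fp_scale(xi, state$shift[i])
  }

  # initial visit order: ascending p-value in the full linear model
  X0 <- as.matrix(data[vars])
  fit0 <- stats::lm(y ~ X0)
  p0 <- summary(fit0)$coefficients[-1, 4]
  ord <- vars[order(p0)]

  cycles <- 0L
  converged <- FALSE
  while (cycles < max_cycles) {
    cycles <- cycles + 1L
    changed <- FALSE
    for (v in ord) {
      i <- which(state$variable == v)
      A <- mfp_design(state, data, exclude = v)
      old <- state[i, c("status", "p1", "p2")]
      if (state$role[i] == "continuous") {
        eng <- fp_engine(y, as.numeric(data[[v]]), A,
                         shift = state$shift[i], scale = state$scale[i])
        devs <- fp_grid_deviances(eng)
        a1 <- if (state$forced[i]) 1 else alpha_select
        res <- fsp_decide(eng, devs, a1, alpha_function)
        state$status[i] <- res$decision
        state$p1[i] <- if (res$decision %in% c("fp1", "fp2")) res$powers[1] else
          if (res$decision == "linear") 1 else NA_real_
        state$p2[i] <- if (res$decision == "fp2") res$powers[2] else NA_real_
        state$p_fp2_null[i] <- res$p_fp2_null
        state$p_fp2_linear[i] <- res$p_fp2_linear
        state$p_fp2_fp1[i] <- res$p_fp2_fp1
      } else {
        xv <- matrix(as.numeric(data[[v]]), ncol = 1,
                     dimnames = list(NULL, v))
        f1 <- fit_gaussian(y, cbind(A, xv))
        f0 <- fit_gaussian(y, A)
        p <- stats::pchisq(f0$deviance - f1$deviance, df = 1,
                           lower.tail = FALSE)
        state$p_incl[i] <- p
        state$status[i] <- if (state$forced[i] || p <= alpha_select) "in" else "out"
      }
      if (!identical(unlist(old), unlist(state[i, c("status", "p1", "p2")])))
        changed <- TRUE
    }
    if (!changed) { converged <- TRUE; break }
  }

  if (!converged) {
    warning("MFP did not converge within ", max_cycles,
            " cycles; returning the current (partial) model.",
            call. = FALSE)
  }
  X <- mfp_design(state, data)
  final <- if (is.null(X) || ncol(X) == 0) fit_gaussian(y) else fit_gaussian(y, X)
  structure(
    list(selection = state, coefficients = final$coefficients,
         rss = final$rss, deviance = final$deviance, n = final$n,
         df.residual = final$df.residual,
         r.squared = 1 - final$rss / sum((y - mean(y))^2),
         cycles = cycles, converged = converged, outcome = outcome,
         alpha_select = alpha_select, alpha_function = alpha_function,
         visit_order = ord, fit = final),
    class = "mfp_fit"
  )
}

# design-matrix columns implied by the current selection state; exclude one
# variable to obtain the adjustment model for its own re-test
mfp_design <- function(state, data, exclude = NULL) {
  cols <- list()
  for (i in seq_len(nrow(state))) {
    v <- state$variable[i]
    if (!is.null(exclude) && v %in% exclude) next
    st <- state$status[i]
    if (st == "out") next
    x <- as.numeric(data[[v]])
    if (state$role[i] == "binary" || st == "linear") {
      m <- matrix(x, ncol = 1, dimnames = list(NULL, v))
    } else {
      pw <- if (st == "fp1") state$p1[i] else c(state$p1[i], state$p2[i])
      m <- fp_transform(x, pw, shift = state$shift[i], scale = state$scale[i])
      colnames(m) <- paste0(v, ":", colnames(m))
    }
    cols[[length(cols) + 1]] <- m
  }
  if (!length(cols)) NULL else do.call(cbind, cols)
}

#' Re-estimate a selected MFP model on (new) data
#'
#' Keeps the selected structure frozen - which variables are in, their FP
#' powers, shifts and scales - and re-estimates the regression coefficients
#' by ordinary least squares on the supplied data.
#'
#' @param object An `mfp_fit`.
#' @param data A data frame containing the model's outcome and covariates.
#' @return An `mfp_fit` with updated coefficients and fit statistics; the
#'   selection is untouched.
#' @export
refit <- function(object, data) {
  stopifnot(inherits(object, "mfp_fit"))
  need <- c(object$outcome,
            object$selection$variable[object$selection$status != "out"])
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("Columns not found in `data`: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  y <- as.numeric(data[[object$outcome]])
  X <- mfp_design(object$selection, data)
  final <- if (is.null(X)) fit_gaussian(y) else fit_gaussian(y, X)
  out <- object
  out$coefficients <- final$coefficients
  out$rss <- final$rss
  out$deviance <- final$deviance
  out$n <- final$n
  out$df.residual <- final$df.residual
  out$r.squared <- 1 - final$rss / sum((y - mean(y))^2)
  out$fit <- final
  out
}

#' Predict from a selected MFP model
#'
#' @param object An `mfp_fit`.
#' @param newdata Data frame with the model's covariates (defaults to
#'   refusing; prediction needs data).
#' @param ... Unused.
#' @return Numeric vector of fitted linear predictors.
#' @export
predict.mfp_fit <- function(object, newdata, ...) {
  X <- mfp_design(object$selection, newdata)
  X <- cbind(`(Intercept)` = 1, X)
  drop(X %*% object$coefficients[colnames(X)])
}

#' @export
print.mfp_fit <- function(x, ...) {
  cat("MFP(", x$alpha_select, ", ", x$alpha_function, ") on n = ", x$n,
      " observations; ", x$cycles, " cycle(s), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  s <- x$selection
  for (i in seq_len(nrow(s))) {
    pw <- if (s$status[i] == "fp1") s$p1[i] else
      if (s$status[i] == "fp2") c(s$p1[i], s$p2[i]) else NULL
    lab <- switch(s$status[i], `in` = "in", out = "out",
                  linear = "linear", fp1 = , fp2 = format_decision(s$status[i], pw))
    cat(sprintf("  %-10s %-11s %s\n", s$variable[i], s$role[i], lab))
  }
  cat("deviance =", format(x$deviance, digits = 7),
      " R^2 =", format(x$r.squared, digits = 3), "\n")
  invisible(x)
}

#' Tidy an MFP model
#'
#' @param x An `mfp_fit`.
#' @param type `"selection"` (default) for one row per candidate variable
#'   with its decision and powers, or `"coefficients"` for the final
#'   coefficient vector.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.mfp_fit <- function(x, type = c("selection", "coefficients"), ...) {
  type <- match.arg(type)
  if (type == "coefficients") {
    return(tibble::tibble(term = names(x$coefficients),
                          estimate = unname(x$coefficients)))
  }
  s <- x$selection
  s$label <- vapply(seq_len(nrow(s)), function(i) {
    pw <- if (s$status[i] == "fp1") s$p1[i] else
      if (s$status[i] == "fp2") c(s$p1[i], s$p2[i]) else NULL
    switch(s$status[i], `in` = "in", out = "out", linear = "linear",
           format_decision(s$status[i], pw))
  }, character(1))
  s
}

#' One-row summary of an MFP model
#'
#' @param x An `mfp_fit`.
#' @param ... Unused.
#' @return A tibble with fit statistics and convergence information.
#' @export
glance.mfp_fit <- function(x, ...) {
  tibble::tibble(n = x$n, rss = x$rss, deviance = x$deviance,
                 r.squared = x$r.squared, df.residual = x$df.residual,
                 n_selected = sum(x$selection$status != "out"),
                 cycles = x$cycles, converged = x$converged)
}
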