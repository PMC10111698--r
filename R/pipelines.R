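# Influential-point screening pipelines around MFP: univariable screening
# before model building (IPXu) and diagnostics within the selected
# multivariable model (IPXm).

#' Univariable influential-point screening followed by MFP
#'
#' Screens every continuous covariate univariably with a leave-one-out (and
#' optionally leave-two-out) deviance-difference scan, pools the
#' observations flagged for at least one covariate, removes them, and
#' re-runs the full MFP selection on the reduced data.  The returned object
#' holds both models for side-by-side comparison.
#'
#' @inheritParams mfp
#' @param alpha_ip Flagging level for the influence scans (0.05 or 0.01).
#' @param d Deletion subset sizes to scan: `1` or `c(1, 2)`.
#' @return An object of class `ipx_result` with elements `scope`
#'   (`"univariable"`), `reports` (one [flag_influential()] report per
#'   continuous variable and scan size), `ips` (pooled flagged ids),
#'   `model_all` and `model_reduced` (both `mfp_fit`s).
#' @export
ip_univariable <- function(data, outcome, continuous, binary = NULL,
                           forced = NULL, alpha_select = 0.05,
                           alpha_function = alpha_select, alpha_ip = 0.05,
                           d = 1, max_cycles = 5) {
  stopifnot(all(d %in% c(1, 2)))
  reports <- list()
  for (v in continuous) {
    for (dd in d) {
      scan <- fp_influence(data, outcome, v, d = dd)
      reports[[paste0(v, ".d", dd)]] <- flag_influential(scan, alpha_ip)
    }
  }
  ips <- pool_ips(reports, nrow(data))
  model_all <- mfp(data, outcome, continuous, binary, forced,
                   alpha_select, alpha_function, max_cycles)
  reduced <- if (length(ips)) data[-ips, , drop = FALSE] else data
  model_reduced <- mfp(reduced, outcome, continuous, binary, forced,
                       alpha_select, alpha_function, max_cycles)
  structure(
    list(scope = "univariable", reports = reports, ips = ips,
         model_all = model_all, model_reduced = model_reduced,
         alpha_ip = alpha_ip),
    class = "ipx_result"
  )
}

#' MFP followed by multivariable influential-point diagnostics
#'
#' Fits the MFP model on the full data first, then scans each continuous
#' variable retained by the model, adjusting for the contribution of the
#' other selected variables.  By default the adjustment is entered as a
#' fixed offset - the other variables' selected transforms with their
#' coefficients frozen at the full-data estimates; with
#' `adjustment_mode = "reestimate"` the adjustment columns are kept in the
#' design and their coefficients re-estimated for every deletion.  Variables
#' the model excluded are not checked.  Observations flagged for any checked
#' variable are removed and MFP is re-run on the reduced data.
#'
#' @inheritParams ip_univariable
#' @param adjustment_mode `"fixed"` (default) or `"reestimate"`.
#' @return An `ipx_result` (scope `"multivariable"`) that additionally
#'   carries `adjustment_mode`.
#' @export
ip_multivariable <- function(data, outcome, continuous, binary = NULL,
                             forced = NULL, alpha_select = 0.05,
                             alpha_function = alpha_select, alpha_ip = 0.05,
                             d = 1, max_cycles = 5,
                             adjustment_mode = c("fixed", "reestimate")) {
  stopifnot(all(d %in% c(1, 2)))
  adjustment_mode <- match.arg(adjustment_mode)
  model_all <- mfp(data, outcome, continuous, binary, forced,
                   alpha_select, alpha_function, max_cycles)
  sel <- model_all$selection
  checked <- sel$variable[sel$role == "continuous" & sel$status != "out"]
  y <- as.numeric(data[[outcome]])
  reports <- list()
  for (v in checked) {
    A <- mfp_design(sel, data, exclude = v)
    if (adjustment_mode == "fixed" && !is.null(A)) {
      beta <- model_all$coefficients[colnames(A)]
      off <- drop(A %*% beta)
      A_use <- NULL
    } else {
      off <- NULL
      A_use <- A
    }
    for (dd in d) {
      scan <- fp_influence(data, outcome, v, adjust = A_use, d = dd,
                           offset = off)
      reports[[paste0(v, ".d", dd)]] <- flag_influential(scan, alpha_ip)
    }
  }
  ips <- pool_ips(reports, nrow(data))
  reduced <- if (length(ips)) data[-ips, , drop = FALSE] else data
  model_reduced <- mfp(reduced, outcome, continuous, binary, forced,
                       alpha_select, alpha_function, max_cycles)
  structure(
    list(scope = "multivariable", reports = reports, ips = ips,
         model_all = model_all, model_reduced = model_reduced,
         alpha_ip = alpha_ip, adjustment_mode = adjustment_mode),
    class = "ipx_result"
  )
}

# Pool flagged observations across per-variable reports.  Influential
# points are, by definition, a few unduly influential observations; when
# the pooled set exceeds a quarter of the data the scans are signalling a
# fragile borderline test rather than point influence, so pair-scan
# contributions are dropped (with a warning) and only leave-one-out flags
# are kept.
pool_ips <- function(reports, n, max_frac = 0.25) {
  ips <- sort(unique(unlist(lapply(reports, `[[`, "flagged_ids"))))
  if (length(ips) > max_frac * n) {
    loo <- reports[vapply(reports, function(r) r$d == 1, logical(1))]
    ips_loo <- sort(unique(unlist(lapply(loo, `[[`, "flagged_ids"))))
    warning("Influence scans flagged ", length(ips), " of ", n,
            " observations - treating this as test fragility, not point ",
            "influence; keeping the ", length(ips_loo),
            " leave-one-out flags only.", call. = FALSE)
    ips <- ips_loo
  }
  ips
}

#' @export
print.ipx_result <- function(x, ...) {
  cat("Influential-point pipeline (", x$scope, " screening, alpha = ",
      x$alpha_ip, ")\n", sep = "")
  cat("pooled influential observations:",
      if (length(x$ips)) paste(x$ips, collapse = ", ") else "none", "\n")
  print(generics::tidy(x))
  invisible(x)
}

#' Side-by-side selection table for an influence pipeline
#'
#' @param x An `ipx_result`.
#' @param ... Unused.
#' @return A tibble with one row per candidate variable and the selected
#'   functional form before (`all`) and after (`reduced`) removal of the
#'   flagged observations.
#' @export
tidy.ipx_result <- function(x, ...) {
  a <- generics::tidy(x$model_all)[c("variable", "role", "label")]
  b <- generics::tidy(x$model_reduced)[c("variable", "label")]
  names(a)[3] <- "all"
  names(b)[2] <- "reduced"
  out <- dplyr::left_join(a, b, by = "variable")
  out$agree <- out$all == out$reduced
  out
}
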