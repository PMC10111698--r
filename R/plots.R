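# ggplot2 visualisations: deviance-difference diagnostic plots, grouped
# pair boxplots, and fitted partial functions with pointwise confidence
# bands.

#' Diagnostic plot of a case-deletion scan
#'
#' For a leave-one-out scan, plots the three deviance differences against
#' the observed covariate value, one panel per closed-test comparison, with
#' the 0.05 (solid) and 0.01 (dashed) chi-squared thresholds as horizontal
#' lines and the flagged observations highlighted and labelled.  For a pair
#' scan, draws the grouped boxplots (all pairs G1, pairs under the
#' membership rule G2, complement G3).
#'
#' @param object An `fp_influence` scan.
#' @param alpha Flagging level used to highlight points (`d = 1` only).
#' @param log_x Use a log10 x-axis (useful for heavy-tailed covariates).
#' @param candidates,rule Passed to [group_pairs()] when `d = 2`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_influence <- function(object, alpha = 0.05, log_x = FALSE,
                                  candidates = integer(), rule = "any", ...) {
  thr <- object$thresholds
  test_levels <- c("fp2_null", "fp2_linear", "fp2_fp1")
  test_labels <- c(fp2_null = "FP2 vs null", fp2_linear = "FP2 vs linear",
                   fp2_fp1 = "FP2 vs FP1")
  if (object$d == 1) {
    rep <- flag_influential(object, alpha)
    rec <- object$records
    rec$x <- object$x_values[rec$id1]
    rec$flagged <- rec$id1 %in% rep$flagged$id1
    long <- tidyr::pivot_longer(
      rec[c("id1", "x", "flagged", "dd_fp2_null", "dd_fp2_linear",
            "dd_fp2_fp1")],
      cols = dplyr::starts_with("dd_"), names_to = "test",
      names_prefix = "dd_", values_to = "dd")
    long$test <- factor(long$test, test_levels)
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$dd)) +
      ggplot2::geom_point(ggplot2::aes(colour = .data$flagged), size = 1) +
      ggplot2::geom_text(
        data = long[long$flagged, ],
        ggplot2::aes(label = .data$id1), vjust = -0.6, size = 2.8) +
      ggplot2::geom_hline(data = tidyr::pivot_longer(
        thr, cols = c("crit05", "crit01"), names_to = "level",
        values_to = "crit"),
        ggplot2::aes(yintercept = .data$crit,
                     linetype = .data$level)) +
      ggplot2::scale_linetype_manual(
        values = c(crit05 = "solid", crit01 = "dashed"),
        labels = c(crit05 = "0.05", crit01 = "0.01"), name = "threshold") +
      ggplot2::scale_colour_manual(
        values = c(`TRUE` = "black", `FALSE` = "grey60"), guide = "none") +
      ggplot2::facet_wrap(~test, scales = "free_y",
                          labeller = ggplot2::as_labeller(test_labels)) +
      ggplot2::labs(x = object$variable, y = "deviance difference",
                    title = paste0("Leave-one-out diagnostics for ",
                                   object$variable))
    if (log_x) p <- p + ggplot2::scale_x_log10()
    return(p)
  }
  rec <- object$records[!object$records$failed, ]
  in2 <- if (rule == "any") {
    rec$id1 %in% candidates | rec$id2 %in% candidates
  } else {
    rec$id1 %in% candidates & rec$id2 %in% candidates
  }
  long <- tidyr::pivot_longer(
    dplyr::mutate(rec[c("dd_fp2_null", "dd_fp2_linear", "dd_fp2_fp1")],
                  g2 = in2),
    cols = dplyr::starts_with("dd_"), names_to = "test",
    names_prefix = "dd_", values_to = "dd")
  long$test <- factor(long$test, test_levels)
  groups <- dplyr::bind_rows(
    dplyr::mutate(long, group = "G1"),
    dplyr::mutate(long[long$g2, ], group = "G2"),
    dplyr::mutate(long[!long$g2, ], group = "G3"))
  ggplot2::ggplot(groups, ggplot2::aes(x = .data$group, y = .data$dd)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::geom_hline(data = tidyr::pivot_longer(
      thr, cols = c("crit05", "crit01"), names_to = "level",
      values_to = "crit"),
      ggplot2::aes(yintercept = .data$crit, linetype = .data$level)) +
    ggplot2::scale_linetype_manual(
      values = c(crit05 = "solid", crit01 = "dashed"),
      labels = c(crit05 = "0.05", crit01 = "0.01"), name = "threshold") +
    ggplot2::facet_wrap(~test, scales = "free_y",
                        labeller = ggplot2::as_labeller(test_labels)) +
    ggplot2::labs(x = NULL, y = "deviance difference",
                  title = paste0("Pair-deletion diagnostics for ",
                                 object$variable))
}

#' Fitted partial FP function with pointwise confidence band
#'
#' Plots the selected function of one continuous variable from an MFP model
#' over the observed range, centred at the function value at the variable's
#' median, with a 95% pointwise confidence band conditional on the selected
#' powers (model-selection uncertainty is ignored, so the band understates
#' the true uncertainty).  Optionally overlays a reference (for example
#' true) function, centred the same way.
#'
#' @param object An `mfp_fit` containing the variable.
#' @param data The data the model was fitted to.
#' @param variable Name of a continuous variable retained by the model.
#' @param reference Optional function of the raw covariate returning the
#'   reference curve on the linear-predictor scale.
#' @param level Confidence level for the band.
#' @param log_x Use a log10 x-axis.
#' @param n_grid Number of grid points.
#' @return A ggplot object.
#' @export
plot_fp_function <- function(object, data, variable, reference = NULL,
                             level = 0.95, log_x = FALSE, n_grid = 200) {
  stopifnot(inherits(object, "mfp_fit"))
  sel <- object$selection
  i <- which(sel$variable == variable)
  if (!length(i) || sel$status[i] == "out") {
    stop("`", variable, "` is not in the selected model.", call. = FALSE)
  }
  x <- as.numeric(data[[variable]])
  grid <- seq(min(x), max(x), length.out = n_grid)
  med <- stats::median(x)
  basis_of <- function(v) {
    if (sel$role[i] == "binary" || sel$status[i] == "linear") {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, variable))
    } else {
      pw <- if (sel$status[i] == "fp1") sel$p1[i] else c(sel$p1[i], sel$p2[i])
      m <- fp_transform(v, pw, shift = sel$shift[i], scale = sel$scale[i])
      colnames(m) <- paste0(variable, ":", colnames(m))
    }
    m
  }
  B <- basis_of(grid)
  B0 <- basis_of(med)
  Bc <- sweep(B, 2, B0)                        # centred at the median
  beta <- object$coefficients[colnames(B)]
  est <- drop(Bc %*% beta)
  # covariance of the variable's coefficients from the final fit
  X <- cbind(`(Intercept)` = 1, mfp_design(sel, data))
  sigma2 <- object$rss / object$df.residual
  V <- sigma2 * solve(crossprod(X))
  Vv <- V[colnames(B), colnames(B), drop = FALSE]
  se <- sqrt(pmax(rowSums((Bc %*% Vv) * Bc), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  df <- tibble::tibble(x = grid, estimate = est,
                       lo = est - zq * se, hi = est + zq * se)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::labs(x = variable, y = "partial linear predictor (centred)",
                  title = paste0("Selected function for ", variable))
  if (!is.null(reference)) {
    ref <- reference(grid) - reference(med)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(x = grid, estimate = ref),
      linetype = "longdash", colour = "blue")
  }
  if (log_x) p <- p + ggplot2::scale_x_log10()
  p
}

#' Partial-function panel for an MFP model
#'
#' One [plot_fp_function()] panel per continuous variable retained by the
#' model, combined with facets.
#'
#' @param object An `mfp_fit`.
#' @param data The data the model was fitted to (required).
#' @param ... Passed on to [plot_fp_function()] (e.g. `level`).
#' @return A ggplot object.
#' @export
autoplot.mfp_fit <- function(object, data, ...) {
  sel <- object$selection
  vars <- sel$variable[sel$role == "continuous" & sel$status != "out"]
  if (!length(vars)) stop("No continuous variables in the model.",
                          call. = FALSE)
  dfs <- lapply(vars, function(v) {
    p <- plot_fp_function(object, data, v, ...)
    d <- p$data
    d$variable <- v
    d
  })
  ggplot2::ggplot(dplyr::bind_rows(dfs),
                  ggplot2::aes(x = .data$x, y = .data$estimate)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free") +
    ggplot2::labs(x = NULL, y = "partial linear predictor (centred)")
}
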