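# Experiment runner: one configuration in, a reproducible report bundle out.

#' Run a full analysis experiment from a configuration
#'
#' Orchestrates the package end to end: obtain the data (simulate or load a
#' CSV, optionally subset by a named label or row range), run the
#' univariable function-selection table, the MFP model, and the requested
#' influence pipelines, and collect deletion records, figures and a
#' structured log.  With `output_dir` set, tables are written as CSV and
#' figures as PDF; outputs are deterministic for a given configuration.
#'
#' @param config A named list or the path of a YAML file with fields:
#'   exactly one of `input` (CSV path) or `simulate` (list with `n` and
#'   optional `seed`); optional `subset` (label like `"A250"` or inclusive
#'   1-based `c(from, to)`); `outcome` (default `"y"`); `continuous`,
#'   `binary` (character vectors; default: the generator's layout);
#'   `alpha_select`, `alpha_function`, `alpha_ip` (defaults 0.05);
#'   `diagnostics` (`"loo"`, `"pairs"`, `"both"` or `"none"`, default
#'   `"loo"`); `adjustment_mode` (`"fixed"` or `"reestimate"`);
#'   `max_cycles`; `output_dir` (optional).
#' @return A list of class `mfpdx_experiment`: `data`, `fsp_table`,
#'   `model`, `ipxu`, `ipxm`, `figures`, `log`, and the resolved `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$input) == is.null(config$simulate)) {
    stop("Supply exactly one of `input` or `simulate`.", call. = FALSE)
  }
  cfg <- utils::modifyList(
    list(outcome = "y",
         continuous = c("x1", "x3", "x5", "x6", "x7", "x10"),
         binary = c("x2", "x4a", "x4b", "x8", "x9a", "x9b"),
         alpha_select = 0.05, alpha_function = NULL, alpha_ip = 0.05,
         diagnostics = "loo", adjustment_mode = "fixed", max_cycles = 5,
         subset = NULL, output_dir = NULL),
    config)
  if (is.null(cfg$alpha_function)) cfg$alpha_function <- cfg$alpha_select
  if (!cfg$diagnostics %in% c("loo", "pairs", "both", "none")) {
    stop("`diagnostics` must be one of loo, pairs, both, none.",
         call. = FALSE)
  }
  log <- list()
  note <- function(...) {
    log[[length(log) + 1]] <<- tibble::tibble(
      step = length(log) + 1L, message = paste0(...))
  }

  if (!is.null(cfg$input)) {
    data <- art_load(cfg$input)
    note("loaded ", nrow(data), " rows from ", cfg$input)
  } else {
    sim <- cfg$simulate
    data <- simulate_art(sim$n, seed = sim$seed)
    note("simulated n = ", sim$n, " with seed ",
         if (is.null(sim$seed)) "NULL" else sim$seed)
  }
  if (!is.null(cfg$subset)) {
    data <- art_subset(data, if (is.character(cfg$subset)) cfg$subset
                       else unlist(cfg$subset))
    note("subset to ", nrow(data), " rows")
  }

  fsp_tab <- fsp_table(data, cfg$outcome, cfg$continuous,
                       alpha_select = cfg$alpha_select,
                       alpha_function = cfg$alpha_function)
  note("univariable function selection for ", length(cfg$continuous),
       " variables")

  d <- switch(cfg$diagnostics, loo = 1, pairs = 2, both = c(1, 2),
              none = NULL)
  if (is.null(d)) {
    model <- mfp(data, cfg$outcome, cfg$continuous, cfg$binary,
                 alpha_select = cfg$alpha_select,
                 alpha_function = cfg$alpha_function,
                 max_cycles = cfg$max_cycles)
    ipxu <- NULL
    ipxm <- NULL
    note("MFP(", cfg$alpha_select, ", ", cfg$alpha_function, ") fitted")
  } else {
    ipxu <- ip_univariable(data, cfg$outcome, cfg$continuous, cfg$binary,
                           alpha_select = cfg$alpha_select,
                           alpha_function = cfg$alpha_function,
                           alpha_ip = cfg$alpha_ip, d = d,
                           max_cycles = cfg$max_cycles)
    ipxm <- ip_multivariable(data, cfg$outcome, cfg$continuous, cfg$binary,
                             alpha_select = cfg$alpha_select,
                             alpha_function = cfg$alpha_function,
                             alpha_ip = cfg$alpha_ip, d = d,
                             max_cycles = cfg$max_cycles,
                             adjustment_mode = cfg$adjustment_mode)
    model <- ipxu$model_all
    note("univariable screening flagged: ",
         if (length(ipxu$ips)) paste(ipxu$ips, collapse = ", ") else "none")
    note("multivariable screening flagged: ",
         if (length(ipxm$ips)) paste(ipxm$ips, collapse = ", ") else "none")
  }

  figures <- list()
  if (!is.null(ipxu)) {
    for (nm in names(ipxu$reports)) {
      scan <- ipxu$reports[[nm]]$scan
      if (scan$d == 1) {
        figures[[paste0("loo_", scan$variable)]] <-
          autoplot(scan, alpha = cfg$alpha_ip)
      }
    }
  }
  sel <- model$selection
  for (v in sel$variable[sel$role == "continuous" & sel$status != "out"]) {
    figures[[paste0("fn_", v)]] <- plot_fp_function(model, data, v)
  }

  out <- structure(
    list(data = data, fsp_table = fsp_tab, model = model, ipxu = ipxu,
         ipxm = ipxm, figures = figures, log = dplyr::bind_rows(log),
         config = cfg),
    class = "mfpdx_experiment")

  if (!is.null(cfg$output_dir)) {
    write_experiment(out, cfg$output_dir)
  }
  out
}

# write the bundle: CSV tables, PDF figures, plain-text log
write_experiment <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(x$fsp_table[setdiff(names(x$fsp_table), "powers")],
                   file.path(dir, "fsp_table.csv"), row.names = FALSE)
  sel <- generics::tidy(x$model)
  utils::write.csv(sel, file.path(dir, "mfp_selection.csv"),
                   row.names = FALSE)
  for (obj in list(x$ipxu, x$ipxm)) {
    if (is.null(obj)) next
    utils::write.csv(generics::tidy(obj),
                     file.path(dir, paste0("ipx_", obj$scope, ".csv")),
                     row.names = FALSE)
    for (nm in names(obj$reports)) {
      utils::write.csv(obj$reports[[nm]]$scan$records,
                       file.path(dir, paste0("records_", obj$scope, "_",
                                             nm, ".csv")),
                       row.names = FALSE)
    }
  }
  for (nm in names(x$figures)) {
    ggplot2::ggsave(file.path(dir, paste0(nm, ".pdf")), x$figures[[nm]],
                    width = 8, height = 4)
  }
  writeLines(paste(x$log$step, x$log$message, sep = ": "),
             file.path(dir, "run.log"))
  invisible(x)
}

#' @export
print.mfpdx_experiment <- function(x, ...) {
  cat("mfpdx experiment on", nrow(x$data), "observations\n\n")
  cat("Univariable function selection:\n")
  print(x$fsp_table[c("variable", "p_fp2_null", "p_fp2_linear",
                      "p_fp2_fp1", "label")])
  cat("\nSelected MFP model:\n")
  print(x$model)
  if (!is.null(x$ipxu)) {
    cat("\nUnivariable screening IPs:",
        if (length(x$ipxu$ips)) paste(x$ipxu$ips, collapse = ", ")
        else "none", "\n")
  }
  if (!is.null(x$ipxm)) {
    cat("Multivariable screening IPs:",
        if (length(x$ipxm$ips)) paste(x$ipxm$ips, collapse = ", ")
        else "none", "\n")
  }
  invisible(x)
}
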