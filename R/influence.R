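# Case-deletion influence diagnostics for function selection.
#
# For every deletion (single observation or unordered pair) the FP1/FP2
# grids are re-searched from scratch on the reduced data.  Because each grid
# model's design columns are fixed, the reduced-data RSS follows exactly
# from the full-data fit via the OLS case-deletion identity
#   RSS_{-U} = RSS - r_U' (I - H_UU)^{-1} r_U,
# so the whole scan needs one fit per grid model, not one per deletion.

#' Number of d-subset deletions
#'
#' The size of a leave-d-out scan: the binomial coefficient C(n, d), e.g.
#' 31,125 pairs for n = 250.
#'
#' @param n Number of observations.
#' @param d Number of observations deleted at a time, `0 < d < n`.
#' @return An integer count.
#' @export
pair_count <- function(n, d) {
  if (!is.numeric(n) || !is.numeric(d) || length(n) != 1 || length(d) != 1 ||
      n != round(n) || d != round(d) || d <= 0 || d >= n) {
    stop("Need integers with 0 < d < n.", call. = FALSE)
  }
  choose(n, d)
}

#' Case-deletion deviance-difference scan for one variable
#'
#' Deletes every single observation (`d = 1`) or every unordered pair
#' (`d = 2`) in turn, re-searches the best FP1 and FP2 fits on the reduced
#' data, and records the three closed-test deviance differences (best FP2
#' against the null, the linear, and the best FP1 model) together with their
#' significance at the 0.05 and 0.01 chi-squared thresholds.  An observation
#' whose deletion changes a significance status is a candidate influential
#' point; see [flag_influential()].
#'
#' @inheritParams fsp
#' @param d Deletion subset size: 1 (leave-one-out) or 2 (all pairs).
#' @param min_n Guard: refuse datasets smaller than this (FP2 fits on tiny
#'   data are unstable).  Default 20.
#' @return An object of class `fp_influence` carrying the per-deletion
#'   record table (see [tidy.fp_influence()]), the full-data test results,
#'   and the scan metadata.
#' @export
fp_influence <- function(data, outcome, x, adjust = NULL, d = 1,
                         offset = NULL, min_n = 20) {
  if (!d %in% c(1, 2)) stop("`d` must be 1 or 2.", call. = FALSE)
  v <- fsp_inputs(data, outcome, x, adjust)
  n <- length(v$y)
  if (n < min_n) stop("Need at least ", min_n, " observations.", call. = FALSE)
  y <- v$y
  if (!is.null(offset)) y <- y - offset

  shift <- fp_shift(v$x)
  scale <- fp_scale(v$x, shift)
  eng <- fp_engine(y, v$x, v$A, shift = shift, scale = scale)
  full_devs <- fp_grid_deviances(eng)
  full <- fsp_decide(eng, full_devs, 0.05, 0.05)

  M <- fp_master_basis(v$x, shift, scale)
  base <- cbind(`(Intercept)` = rep(1, n), v$A)
  designs <- c(
    list(null = base,
         linear = cbind(base, M[, match(1, FP_POWER_SET), drop = FALSE])),
    lapply(eng$sets, function(s) cbind(base, M[, s, drop = FALSE]))
  )

  if (d == 1) {
    ids <- cbind(id1 = seq_len(n), id2 = NA_integer_)
  } else {
    pr <- which(upper.tri(diag(n)), arr.ind = TRUE)
    ids <- cbind(id1 = pr[, 1], id2 = pr[, 2])
  }
  nd <- nrow(ids)
  m <- n - d

  # deleted-data deviance for every model x every deletion
  dev <- matrix(NA_real_, nd, length(designs))
  for (k in seq_along(designs)) {
    X <- designs[[k]]
    qx <- qr(X)
    if (qx$rank < ncol(X)) next               # singular model: leave NA
    r <- qr.resid(qx, y)
    rss <- sum(r^2)
    Q <- qr.Q(qx)
    if (d == 1) {
      h <- rowSums(Q^2)
      den <- 1 - h
      rss_d <- rss - r^2 / den
      rss_d[den < 1e-10] <- NA_real_
    } else {
      H <- tcrossprod(Q)
      hii <- diag(H)[ids[, 1]]
      hjj <- diag(H)[ids[, 2]]
      hij <- H[ids]
      ri <- r[ids[, 1]]
      rj <- r[ids[, 2]]
      det <- (1 - hii) * (1 - hjj) - hij^2
      rss_d <- rss - (ri^2 * (1 - hjj) + rj^2 * (1 - hii) + 2 * ri * rj * hij) / det
      rss_d[det < 1e-10] <- NA_real_
    }
    rss_d[rss_d < 0] <- 0
    dev[, k] <- gaussian_deviance(rss_d, m)
  }

  grid <- eng$grid
  fp1_cols <- 2L + which(grid$degree == 1)
  fp2_cols <- 2L + which(grid$degree == 2)
  # preference-ordered argmin so ties resolve as in the full-data search
  pick <- function(cols) {
    rows <- as.integer(cols - 2L)
    pref <- eng$pref[eng$pref %in% rows]
    mm <- dev[, 2L + pref, drop = FALSE]
    mm[is.na(mm)] <- Inf
    j <- max.col(-mm, ties.method = "first")
    best <- mm[cbind(seq_len(nd), j)]
    best[!is.finite(best)] <- NA_real_
    list(dev = best, row = pref[j])
  }
  b1 <- pick(fp1_cols)
  b2 <- pick(fp2_cols)

  # nested grids guarantee nonnegative differences; clamp solver noise
  dd1 <- pmax(dev[, 1] - b2$dev, 0)
  dd2 <- pmax(dev[, 2] - b2$dev, 0)
  dd3 <- pmax(b1$dev - b2$dev, 0)
  failed <- is.na(dd1) | is.na(dd2) | is.na(dd3)

  thr05 <- chi2_critical(c(4, 3, 2), 0.05)
  thr01 <- chi2_critical(c(4, 3, 2), 0.01)
  records <- tibble::tibble(
    id1 = ids[, 1], id2 = ids[, 2],
    dd_fp2_null = dd1, dd_fp2_linear = dd2, dd_fp2_fp1 = dd3,
    sig05_null = dd1 >= thr05[1], sig05_linear = dd2 >= thr05[2],
    sig05_fp1 = dd3 >= thr05[3],
    sig01_null = dd1 >= thr01[1], sig01_linear = dd2 >= thr01[2],
    sig01_fp1 = dd3 >= thr01[3],
    fp1_power = grid$p1[b1$row],
    fp2_p1 = grid$p1[b2$row], fp2_p2 = grid$p2[b2$row],
    failed = failed
  )

  structure(
    list(records = records, variable = x, outcome = outcome, d = d, n = n,
         x_values = v$x, shift = shift, scale = scale,
         full_dd = full$dd,
         full_sig05 = unname(full$dd >= thr05),
         full_sig01 = unname(full$dd >= thr01),
         full_decision = full$decision, full_powers = full$powers,
         thresholds = tibble::tibble(
           test = c("fp2_null", "fp2_linear", "fp2_fp1"), df = c(4, 3, 2),
           crit05 = thr05, crit01 = thr01)),
    class = "fp_influence"
  )
}

#' @export
print.fp_influence <- function(x, ...) {
  cat("Case-deletion scan for `", x$variable, "`: ",
      nrow(x$records), " deletion(s) of size ", x$d, " (n = ", x$n, ")\n",
      sep = "")
  cat("full-data deviance differences:",
      paste(sprintf("%s=%.3f", names(x$full_dd), x$full_dd), collapse = ", "),
      "\n")
  fl <- flag_influential(x)
  cat("flagged at 0.05:",
      if (length(fl$flagged_ids)) paste(fl$flagged_ids, collapse = ", ")
      else "none", "\n")
  invisible(x)
}

#' Tidy a case-deletion scan
#'
#' @param x An `fp_influence` object.
#' @param ... Unused.
#' @return The per-deletion record tibble: deleted ids, the three deviance
#'   differences, six significance flags (0.05 / 0.01), and the re-searched
#'   best FP1/FP2 powers.
#' @export
tidy.fp_influence <- function(x, ...) x$records

#' Flag influential observations
#'
#' An observation (or pair) is flagged when its deletion changes the
#' significance status of at least one of the three closed-test comparisons
#' relative to the full data - in either direction: deletion may collapse a
#' significant test below its threshold (an FP2 that depends on one point)
#' or newly push one above it (a non-linearity masked by one point).
#'
#' For a pair scan the flagged unit is the pair; the observation-level set
#' `flagged_ids` then contains the observations that drive the changes: an
#' observation qualifies when at least `member_threshold` of the pairs
#' containing it are flagged (an observation whose every co-deletion flips a
#' test is influential by itself; a single flipped pair among hundreds is
#' not evidence about either member).
#'
#' @param object An `fp_influence` scan.
#' @param alpha Flagging level, 0.05 or 0.01.
#' @param member_threshold For `d = 2`: minimum fraction of an observation's
#'   pairs that must be flagged before the observation itself is listed in
#'   `flagged_ids` (default 0.5).
#' @return An object of class `ip_report`: the flagged deletions, the ids
#'   involved, and the scan it came from.
#' @export
flag_influential <- function(object, alpha = 0.05, member_threshold = 0.5) {
  stopifnot(inherits(object, "fp_influence"))
  if (!alpha %in% c(0.05, 0.01)) {
    stop("`alpha` must be 0.05 or 0.01 (the tabulated thresholds).",
         call. = FALSE)
  }
  rec <- object$records
  sig <- if (alpha == 0.05) {
    cbind(rec$sig05_null, rec$sig05_linear, rec$sig05_fp1)
  } else {
    cbind(rec$sig01_null, rec$sig01_linear, rec$sig01_fp1)
  }
  ref <- if (alpha == 0.05) object$full_sig05 else object$full_sig01
  change <- sig != matrix(ref, nrow(rec), 3, byrow = TRUE)
  flag <- !rec$failed & rowSums(change) > 0
  flagged <- rec[flag, , drop = FALSE]
  if (object$d == 1) {
    ids <- sort(flagged$id1)
  } else {
    all_ids <- c(rec$id1[!rec$failed], rec$id2[!rec$failed])
    hit_ids <- c(flagged$id1, flagged$id2)
    tot <- table(factor(all_ids, levels = seq_len(object$n)))
    hit <- table(factor(hit_ids, levels = seq_len(object$n)))
    frac <- as.numeric(hit) / pmax(as.numeric(tot), 1)
    ids <- which(as.numeric(tot) > 0 & frac >= member_threshold)
  }
  structure(
    list(variable = object$variable, d = object$d, alpha = alpha,
         flagged = flagged, flagged_ids = ids,
         member_threshold = if (object$d == 2) member_threshold else NA,
         n_flagged = nrow(flagged), scan = object),
    class = "ip_report"
  )
}

#' @export
print.ip_report <- function(x, ...) {
  cat("Influential-point report for `", x$variable, "` (d = ", x$d,
      ", alpha = ", x$alpha, ")\n", sep = "")
  if (!x$n_flagged) {
    cat("  no influential deletions\n")
  } else if (x$d == 1) {
    cat("  flagged observations:", paste(x$flagged$id1, collapse = ", "), "\n")
  } else {
    cat("  flagged pairs:", x$n_flagged, " involving observations: ",
        paste(x$flagged_ids, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
tidy.ip_report <- function(x, ...) x$flagged

#' Grouped summaries of a pair-deletion scan
#'
#' Splits all C(n, 2) pair records into the boxplot groups used to display
#' influential pairs: G1 is every pair, G2 the pairs whose membership rule
#' involves the candidate influential observations, and G3 the complement.
#' The membership rule is configurable because the informative split depends
#' on which points are under suspicion.
#'
#' @param object An `fp_influence` scan with `d = 2`.
#' @param candidates Integer vector of candidate influential observation ids
#'   (may be empty, in which case G2 is empty and G3 equals G1).
#' @param rule `"any"` (default): a pair belongs to G2 when it contains at
#'   least one candidate; `"both"`: only when both members are candidates.
#' @return A tibble with one row per group and test: counts and five-number
#'   summaries of the deviance differences.
#' @export
group_pairs <- function(object, candidates = integer(),
                        rule = c("any", "both")) {
  stopifnot(inherits(object, "fp_influence"))
  if (object$d != 2) stop("`group_pairs()` needs a pair scan (d = 2).",
                          call. = FALSE)
  rule <- match.arg(rule)
  rec <- object$records[!object$records$failed, , drop = FALSE]
  in2 <- if (rule == "any") {
    rec$id1 %in% candidates | rec$id2 %in% candidates
  } else {
    rec$id1 %in% candidates & rec$id2 %in% candidates
  }
  long <- tidyr::pivot_longer(
    rec[c("id1", "id2", "dd_fp2_null", "dd_fp2_linear", "dd_fp2_fp1")],
    cols = dplyr::starts_with("dd_"), names_to = "test",
    names_prefix = "dd_", values_to = "dd")
  long$test <- factor(long$test, levels = c("fp2_null", "fp2_linear", "fp2_fp1"))
  groups <- dplyr::bind_rows(
    dplyr::mutate(long, group = "G1"),
    dplyr::mutate(long[rep(in2, each = 3), ], group = "G2"),
    dplyr::mutate(long[rep(!in2, each = 3), ], group = "G3")
  )
  dplyr::summarise(
    dplyr::group_by(groups, .data$group, .data$test),
    n = dplyr::n(),
    min = suppressWarnings(min(.data$dd)),
    q1 = stats::quantile(.data$dd, 0.25, names = FALSE),
    median = stats::median(.data$dd),
    q3 = stats::quantile(.data$dd, 0.75, names = FALSE),
    max = suppressWarnings(max(.data$dd)),
    .groups = "drop"
  )
}

#' Re-run function selection with named observations deleted
#'
#' The informal targeted check: delete a specific set of observations (for
#' example three suspected influential points at once) and re-run the closed
#' test on what remains.
#'
#' @inheritParams fsp
#' @param ids Integer vector of row indices to delete.
#' @return An `fsp_result` fitted to the reduced data.
#' @export
fsp_drop <- function(data, outcome, x, ids, adjust = NULL, alpha = 0.05,
                     alpha_select = alpha, alpha_function = alpha,
                     offset = NULL) {
  stopifnot(all(ids %in% seq_len(nrow(data))))
  keep <- setdiff(seq_len(nrow(data)), ids)
  fsp(data[keep, , drop = FALSE], outcome, x, adjust = adjust,
      alpha_select = alpha_select, alpha_function = alpha_function,
      offset = if (is.null(offset)) NULL else offset[keep])
}

#' Stepwise elimination of influential observations
#'
#' Removes the single most influential flagged observation, re-runs the
#' leave-one-out scan on the reduced data, and repeats until no observation
#' is flagged or `max_steps` is reached.  "Most influential" means the
#' flagged observation whose deletion moves a deviance difference furthest
#' from its full-data value.
#'
#' @inheritParams fp_influence
#' @param alpha Flagging level.
#' @param max_steps Maximum number of eliminations.
#' @return A list with `removed` (ids in elimination order, in the original
#'   row numbering), `steps` (a tibble log), and `final` (the last scan).
#' @export
sequential_deletion <- function(data, outcome, x, adjust = NULL,
                                alpha = 0.05, max_steps = 5, min_n = 20) {
  rows <- seq_len(nrow(data))
  removed <- integer()
  steps <- list()
  scan <- NULL
  for (s in seq_len(max_steps)) {
    d <- data[rows, , drop = FALSE]
    scan <- fp_influence(d, outcome, x, adjust = adjust, min_n = min_n)
    rep <- flag_influential(scan, alpha)
    if (!rep$n_flagged) break
    dev <- abs(sweep(as.matrix(rep$flagged[c("dd_fp2_null", "dd_fp2_linear",
                                             "dd_fp2_fp1")]),
                     2, scan$full_dd))
    worst_local <- rep$flagged$id1[which.max(apply(dev, 1, max))]
    worst <- rows[worst_local]
    removed <- c(removed, worst)
    steps[[s]] <- tibble::tibble(step = s, removed = worst,
                                 n_flagged = rep$n_flagged)
    rows <- rows[-worst_local]
  }
  list(removed = removed,
       steps = if (length(steps)) dplyr::bind_rows(steps) else
         tibble::tibble(step = integer(), removed = integer(),
                        n_flagged = integer()),
       final = scan)
}
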