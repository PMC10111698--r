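# Fractional polynomial power grid and basis transforms.

# canonical FP power set; 0 denotes the natural logarithm
FP_POWER_SET <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)

#' The fractional polynomial power set
#'
#' The eight exponents from which FP1 and FP2 functions are built.
#' An exponent of 0 denotes the natural logarithm.
#'
#' @return A numeric vector of length 8: `c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)`.
#' @export
fp_power_set <- function() FP_POWER_SET

#' Enumerate fractional polynomial power specifications
#'
#' Lists every FP model specification up to the requested degree: the 8
#' one-power (FP1) functions and, for `max_degree = 2`, the 36 two-power
#' (FP2) functions (28 distinct unordered pairs plus 8 repeated pairs),
#' 44 specifications in total.
#'
#' @param max_degree Maximum FP degree, 1 or 2.
#' @return A tibble with columns `degree`, `p1` and `p2` (`p2` is `NA` for
#'   degree-1 rows; `p1 <= p2` for degree-2 rows).
#' @examples
#' fp_powers(1)     # 8 rows
#' nrow(fp_powers(2))  # 44
#' @export
fp_powers <- function(max_degree = 2) {
  if (!is.numeric(max_degree) || length(max_degree) != 1 ||
      !max_degree %in% c(1, 2)) {
    stop("`max_degree` must be 1 or 2.", call. = FALSE)
  }
  s <- FP_POWER_SET
  fp1 <- tibble::tibble(degree = 1L, p1 = s, p2 = NA_real_)
  if (max_degree == 1) {
    return(fp1)
  }
  pairs <- expand.grid(p1 = s, p2 = s)
  pairs <- pairs[pairs$p1 <= pairs$p2, , drop = FALSE]  # sorted, incl. repeats
  pairs <- pairs[order(pairs$p1, pairs$p2), ]
  fp2 <- tibble::tibble(degree = 2L, p1 = pairs$p1, p2 = pairs$p2)
  dplyr::bind_rows(fp1, fp2)
}

#' Origin shift for non-positive variables
#'
#' FP transforms require a strictly positive argument.  Returns 0 when the
#' variable is already positive, otherwise `1 - min(x)` so that the shifted
#' minimum is exactly 1 (for a variable whose minimum is 0 this is the usual
#' "+1 before taking logs").
#'
#' @param x Numeric vector, non-empty and finite.
#' @return A single number to be added to `x` before transformation.
#' @export
fp_shift <- function(x) {
  if (length(x) == 0 || !is.numeric(x) || any(!is.finite(x))) {
    stop("`x` must be a non-empty finite numeric vector.", call. = FALSE)
  }
  m <- min(x)
  if (m > 0) 0 else 1 - m
}

#' Pre-transformation scale factor
#'
#' A power of ten chosen so that the shifted variable has magnitude of order
#' 1 to 10 before exponentiation.  This prevents overflow for cubic powers of
#' large-valued variables and keeps the basis columns well conditioned; the
#' fitted function is unchanged because rescaling only recombines the basis.
#'
#' @param x Numeric vector.
#' @param shift Origin shift (default [fp_shift()]).
#' @return A positive power of ten.
#' @export
fp_scale <- function(x, shift = fp_shift(x)) {
  z <- x + shift
  if (any(z <= 0)) {
    stop("`x + shift` must be strictly positive.", call. = FALSE)
  }
  10^floor(log10(max(z)))
}

#' Fractional polynomial basis transform
#'
#' Transforms `x` into the basis columns of a single FP specification.  With
#' `z = (x + shift) / scale`, the column for power `p` is `z^p`, with `p = 0`
#' meaning `log(z)`.  For repeated powers `(p, p)` the second column is
#' `z^p * log(z)` (so `(0, 0)` gives `log(z)` and `log(z)^2`).
#'
#' @param x Numeric vector.
#' @param powers Numeric vector of 1 or 2 exponents, each in
#'   [fp_power_set()]; two equal entries request the repeated-power basis.
#' @param shift,scale Origin shift and scale applied before exponentiation;
#'   defaults from [fp_shift()] and [fp_scale()].
#' @return A numeric matrix with one column per basis term and attributes
#'   `shift`, `scale` and `powers`.
#' @examples
#' fp_transform(c(1, exp(1)), powers = 0)      # log column
#' fp_transform(2, powers = c(3, 3))           # c(8, 8 * log(2))
#' @export
fp_transform <- function(x, powers, shift = fp_shift(x),
                         scale = fp_scale(x, shift)) {
  if (!is.numeric(powers) || !length(powers) %in% c(1, 2) ||
      !all(powers %in% FP_POWER_SET)) {
    stop("`powers` must be 1 or 2 exponents from the FP power set.",
         call. = FALSE)
  }
  if (!is.numeric(scale) || length(scale) != 1 || scale <= 0) {
    stop("`scale` must be a positive number.", call. = FALSE)
  }
  z <- (x + shift) / scale
  if (any(z <= 0 | !is.finite(z))) {
    bad <- which(z <= 0 | !is.finite(z))
    stop("Non-positive argument after shift/scale at rows: ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) ", ..." else "", call. = FALSE)
  }
  one <- function(p) if (p == 0) log(z) else z^p
  if (length(powers) == 1) {
    out <- cbind(one(powers))
  } else if (powers[1] == powers[2]) {
    h <- one(powers[1])
    out <- cbind(h, h * log(z))
  } else {
    powers <- sort(powers)
    out <- cbind(one(powers[1]), one(powers[2]))
  }
  colnames(out) <- fp_term_labels(powers)
  structure(out, shift = shift, scale = scale, powers = powers)
}

# labels such as "x^0.5", "log(x)", "x^2*log(x)"
fp_term_labels <- function(powers) {
  lab <- function(p) if (p == 0) "log(x)" else paste0("x^", p)
  if (length(powers) == 1) {
    lab(powers)
  } else if (powers[1] == powers[2]) {
    c(lab(powers[1]), paste0(lab(powers[1]), "*log(x)"))
  } else {
    c(lab(powers[1]), lab(powers[2]))
  }
}

# Master basis: 16 columns, t_p for the 8 powers then t_p * log(z).
# Every FP1/FP2 model is a column subset of this matrix:
#   FP1(p): column p; FP2(p<q): columns p,q; FP2(p,p): columns p and 8+p.
fp_master_basis <- function(x, shift = fp_shift(x),
                            scale = fp_scale(x, shift)) {
  z <- (x + shift) / scale
  if (any(z <= 0 | !is.finite(z))) {
    bad <- which(z <= 0 | !is.finite(z))
    stop("Non-positive argument after shift/scale at rows: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  lz <- log(z)
  tp <- vapply(FP_POWER_SET, function(p) if (p == 0) lz else z^p,
               numeric(length(z)))
  out <- cbind(tp, tp * lz)
  colnames(out) <- c(paste0("t", seq_len(8)), paste0("lt", seq_len(8)))
  structure(out, shift = shift, scale = scale)
}

# Column index sets (within the 16 master columns) for the 44 grid models,
# in the row order of fp_powers(2).
fp_model_columns <- function(grid = fp_powers(2)) {
  idx <- function(p) match(p, FP_POWER_SET)
  lapply(seq_len(nrow(grid)), function(i) {
    p1 <- grid$p1[i]; p2 <- grid$p2[i]
    if (grid$degree[i] == 1) {
      idx(p1)
    } else if (p1 == p2) {
      c(idx(p1), 8L + idx(p1))
    } else {
      c(idx(p1), idx(p2))
    }
  })
}

# Preference order for tie-breaking: powers closest to 1, then
# lexicographically smaller; degree-1 preferred over degree-2 at equal fit
# is enforced by the closed test itself, not here.
fp_preference_order <- function(grid) {
  dist <- ifelse(is.na(grid$p2), abs(grid$p1 - 1),
                 abs(grid$p1 - 1) + abs(grid$p2 - 1))
  order(dist, grid$p1, ifelse(is.na(grid$p2), -Inf, grid$p2))
}
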