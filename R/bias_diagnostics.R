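## bias_diagnostics: calibration slope, Bland-Altman agreement, binned bias.

.paired_numeric <- function(dnam_ages, chronological_ages) {
  if (is.data.frame(dnam_ages)) dnam_ages <-
      setNames(dnam_ages$dnam_age, dnam_ages$sample_id)
  if (is.data.frame(chronological_ages)) chronological_ages <-
      setNames(chronological_ages$chronological_age,
               chronological_ages$sample_id)
  if (!is.null(names(dnam_ages)) && !is.null(names(chronological_ages))) {
    p <- .match_pairs(dnam_ages, chronological_ages)
    dnam_ages <- p$dnam; chronological_ages <- p$chron
  }
  stopifnot(length(dnam_ages) == length(chronological_ages))
  ok <- !is.na(dnam_ages) & !is.na(chronological_ages)
  list(dnam = as.numeric(dnam_ages[ok]),
       chron = as.numeric(chronological_ages[ok]))
}

#' Calibration fit of DNAm age on chronological age
#'
#' OLS regression of predicted on actual age.  An unbiased clock tracks
#' the identity line (slope 1, intercept 0); the audit's headline symptom
#' is a slope clearly below 1.  A two-sided t-test of H0: slope = 1 is
#' reported.
#'
#' @inheritParams delta_age
#' @return A list of class `calibration_fit`: `slope`, `intercept`,
#'   `slope_se`, `p_slope_ne_1`, `r_squared`, `n`.
#' @export
calibration_fit <- function(dnam_ages, chronological_ages) {
  p <- .paired_numeric(dnam_ages, chronological_ages)
  n <- length(p$dnam)
  if (n < 3) stop("calibration fit needs >= 3 pairs", call. = FALSE)
  if (var(p$chron) == 0) {
    stop("chronological age is constant; slope undefined", call. = FALSE)
  }
  fit <- stats::lm(p$dnam ~ p$chron)
  sm <- suppressWarnings(summary(fit))  # exact fits trip summary.lm
  slope <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  # H0: slope = 1 (not the default slope = 0)
  tstat <- (slope - 1) / se
  pval <- if (is.finite(tstat)) 2 * pt(-abs(tstat), df = n - 2) else NA_real_
  if (se == 0) pval <- as.numeric(slope == 1)  # exact fits: 1 iff identity
  structure(list(slope = slope, intercept = unname(coef(fit)[1]),
                 slope_se = se, p_slope_ne_1 = pval,
                 r_squared = sm$r.squared, n = n),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> n = %d: slope %.4f (se %.4f), intercept %.3f, R2 %.3f\n",
    x$n, x$slope, x$slope_se, x$intercept, x$r_squared))
  cat(sprintf("  H0 slope = 1: p = %.4g%s\n", x$p_slope_ne_1,
              if (x$slope < 1) "  [underestimation: slope < 1]" else ""))
  invisible(x)
}

#' Bland-Altman agreement summary
#'
#' Mean-difference analysis of DNAm vs chronological age: the bias (mean
#' difference), the sample (n-1) SD of the differences, limits of
#' agreement at bias +/- 1.96 * SD (the normal-theory 95% band — for
#' purely random error about 5% of points fall outside), the fraction of
#' points outside the limits, and two trend slopes of the difference:
#' against chronological age (`trend_vs_age`, the headline age-dependence
#' diagnostic) and against the pairwise mean (`trend_vs_mean`, the
#' classical Bland-Altman abscissa).
#'
#' `trend_vs_age` equals the calibration slope minus 1 exactly (both are
#' OLS against the same predictor).
#'
#' @inheritParams delta_age
#' @return A list of class `bland_altman_summary`: `bias`, `sd_diff`,
#'   `lower_limit`, `upper_limit`, `prop_outside`, `trend_vs_age`,
#'   `trend_vs_mean`, `n`.
#' @export
bland_altman <- function(dnam_ages, chronological_ages) {
  p <- .paired_numeric(dnam_ages, chronological_ages)
  n <- length(p$dnam)
  if (n < 2) stop("Bland-Altman needs >= 2 pairs", call. = FALSE)
  d <- p$dnam - p$chron
  bias <- mean(d)
  s <- sd(d)
  lo <- bias - 1.96 * s
  hi <- bias + 1.96 * s
  trend <- function(x) {
    if (var(x) == 0) return(NA_real_)
    unname(coef(stats::lm(d ~ x))[2])
  }
  structure(list(bias = bias, sd_diff = s,
                 lower_limit = lo, upper_limit = hi,
                 prop_outside = mean(d < lo | d > hi),
                 trend_vs_age = trend(p$chron),
                 trend_vs_mean = trend((p$dnam + p$chron) / 2),
                 n = n),
            class = "bland_altman_summary")
}

#' @export
print.bland_altman_summary <- function(x, ...) {
  cat(sprintf("<bland_altman> n = %d: bias %.3f y, sd %.3f, limits [%.3f, %.3f]\n",
              x$n, x$bias, x$sd_diff, x$lower_limit, x$upper_limit))
  cat(sprintf("  outside limits: %.1f%%; trend vs age %.4f y/y, vs mean %.4f y/y\n",
              100 * x$prop_outside, x$trend_vs_age, x$trend_vs_mean))
  invisible(x)
}

#' Age-binned prediction bias
#'
#' Mean and SD of (DNAm age - chronological age) within half-open age bins
#' `[lo, hi)`.  A clock with age-dependent underestimation shows a
#' monotonically decreasing mean difference across bins.
#'
#' @inheritParams delta_age
#' @param bin_edges Strictly increasing numeric vector of bin edges in
#'   years; samples outside `[min, max)` are excluded and counted.
#' @return A `data.frame` with columns `bin`, `lo`, `hi`, `n`,
#'   `mean_diff`, `sd_diff`; attribute `n_excluded` counts out-of-range
#'   samples.
#' @export
age_binned_bias <- function(dnam_ages, chronological_ages, bin_edges) {
  p <- .paired_numeric(dnam_ages, chronological_ages)
  if (is.unsorted(bin_edges, strictly = TRUE) || length(bin_edges) < 2) {
    stop("bin_edges must be strictly increasing with >= 2 values",
         call. = FALSE)
  }
  d <- p$dnam - p$chron
  k <- length(bin_edges) - 1
  idx <- findInterval(p$chron, bin_edges, rightmost.closed = FALSE)
  in_range <- idx >= 1 & idx <= k & p$chron < bin_edges[k + 1]
  out <- data.frame(
    bin = sprintf("[%g,%g)", bin_edges[-(k + 1)], bin_edges[-1]),
    lo = bin_edges[-(k + 1)], hi = bin_edges[-1],
    n = 0L, mean_diff = NA_real_, sd_diff = NA_real_,
    stringsAsFactors = FALSE)
  for (b in seq_len(k)) {
    sel <- in_range & idx == b
    out$n[b] <- sum(sel)
    if (out$n[b] > 0) out$mean_diff[b] <- mean(d[sel])
    if (out$n[b] > 1) out$sd_diff[b] <- sd(d[sel])
  }
  attr(out, "n_excluded") <- sum(!in_range)
  out
}
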