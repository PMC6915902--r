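## locus_analytics: per-clock-probe influence, age slopes, saturation.

#' Per-locus clock probe summary
#'
#' For every probe of the clock, summarises its beta distribution across
#' samples (mean, SD, coefficient of variation), the influence score
#' |coefficient| / CV (a probe drives the age estimate strongly when its
#' clock weight is large relative to its dispersion in the data), the OLS
#' slope of beta on chronological age with its p-value, whether that slope
#' is concordant in sign with the clock coefficient, and whether the probe
#' is a saturation candidate (see [flag_saturation()]).
#'
#' CV uses the sample (n-1) SD over the arithmetic mean of the raw betas;
#' probes with mean beta below `1e-6` get CV and influence flagged
#' undefined (`NA`) rather than infinite.  Clock probes absent from the
#' beta matrix are kept as rows with `present = FALSE`, never silently
#' dropped.
#'
#' @param betas Beta matrix (probes in rows, samples in columns).
#' @param clock A [clock_definition()].
#' @param ages Chronological ages, named by sample id or aligned to the
#'   columns of `betas`.
#' @param high_threshold,low_threshold Saturation thresholds passed to
#'   [flag_saturation()].
#' @return A `data.frame`, one row per clock probe: `probe_id`,
#'   `coefficient`, `present`, `n`, `mean_beta`, `sd_beta`, `cv`,
#'   `influence`, `age_slope`, `slope_p`, `concordant`,
#'   `saturation_candidate`.
#' @export
locus_summary <- function(betas, clock, ages,
                          high_threshold = 0.8, low_threshold = 0.2) {
  stopifnot(inherits(clock, "clock_definition"))
  betas <- beta_matrix(betas)
  if (!is.null(names(ages))) {
    stopifnot(all(colnames(betas) %in% names(ages)))
    ages <- ages[colnames(betas)]
  }
  stopifnot(length(ages) == ncol(betas))
  ages <- as.numeric(ages)
  probes <- names(clock$coefficients)
  present <- probes %in% rownames(betas)
  if (!any(present)) stop("no clock probes present in beta matrix",
                          call. = FALSE)
  if (sum(!is.na(ages)) < 3) {
    stop("locus slopes need >= 3 samples with known age", call. = FALSE)
  }

  out <- data.frame(probe_id = probes,
                    coefficient = unname(clock$coefficients),
                    present = present,
                    n = NA_integer_, mean_beta = NA_real_,
                    sd_beta = NA_real_, cv = NA_real_,
                    influence = NA_real_, age_slope = NA_real_,
                    slope_p = NA_real_, concordant = NA,
                    saturation_candidate = NA,
                    stringsAsFactors = FALSE)
  for (i in which(present)) {
    x <- betas[probes[i], ]
    ok <- !is.na(x) & !is.na(ages)
    out$n[i] <- sum(ok)
    if (out$n[i] == 0) next
    out$mean_beta[i] <- mean(x[ok])
    out$sd_beta[i] <- if (out$n[i] > 1) sd(x[ok]) else NA_real_
    if (!is.na(out$sd_beta[i]) && out$mean_beta[i] >= 1e-6) {
      out$cv[i] <- out$sd_beta[i] / out$mean_beta[i]
      out$influence[i] <- if (out$coefficient[i] == 0) 0 else
        if (out$cv[i] > 0) abs(out$coefficient[i]) / out$cv[i] else NA_real_
    } else if (out$coefficient[i] == 0) {
      out$influence[i] <- 0
    }
    if (out$n[i] >= 3 && var(ages[ok]) > 0 && !is.na(out$sd_beta[i])) {
      fit <- suppressWarnings(summary(stats::lm(x[ok] ~ ages[ok])))
      out$age_slope[i] <- fit$coefficients[2, 1]
      out$slope_p[i] <- if (nrow(fit$coefficients) > 1 &&
                            fit$coefficients[2, 2] > 0) {
        fit$coefficients[2, 4]
      } else {
        as.numeric(out$age_slope[i] == 0)
      }
      out$concordant[i] <- sign(out$age_slope[i]) ==
        sign(out$coefficient[i])
    }
    out$saturation_candidate[i] <- flag_saturation(
      out$mean_beta[i], out$coefficient[i], high_threshold, low_threshold)
  }
  out
}

#' Top influential clock probes
#'
#' The `k` probes with the largest influence score, ties broken by
#' lexicographic probe id.  Probes with undefined influence rank last.
#'
#' @param stats A [locus_summary()] table.
#' @param k Number of probes to return (`>= 1`).
#' @return The top `k` rows, sorted by decreasing influence.
#' @export
top_influential <- function(stats, k = 10) {
  stopifnot(is.data.frame(stats), k >= 1)
  if (k > nrow(stats)) {
    warning(sprintf("k = %d exceeds table size %d; returning all rows",
                    k, nrow(stats)), call. = FALSE)
    k <- nrow(stats)
  }
  key <- stats$influence
  key[is.na(key)] <- -Inf
  ord <- order(-key, stats$probe_id)
  stats[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
}

#' Flag a probe as a saturation candidate
#'
#' A clock locus is a saturation candidate when its methylation is already
#' near a boundary and the clock expects it to keep moving toward that
#' boundary with age: highly methylated (mean beta at or above
#' `high_threshold`) with a positive coefficient, or lowly methylated (at
#' or below `low_threshold`) with a negative coefficient.  Near the
#' boundary the beta response flattens, so such loci stop contributing
#' age signal — compressing predicted age in the elderly.
#'
#' @param mean_beta Mean beta of the probe across samples.
#' @param coefficient Clock coefficient of the probe.
#' @param high_threshold,low_threshold Boundary thresholds (defaults 0.8
#'   and 0.2).
#' @return Logical (vectorized).
#' @export
flag_saturation <- function(mean_beta, coefficient,
                            high_threshold = 0.8, low_threshold = 0.2) {
  (mean_beta >= high_threshold & coefficient > 0) |
    (mean_beta <= low_threshold & coefficient < 0)
}

#' Overlap between two probe sets
#'
#' Exact, symmetric set intersection of probe ids (clock definitions or
#' plain character vectors).
#'
#' @param set_a,set_b Character vectors of probe ids, or
#'   [clock_definition()] objects.
#' @return A list: `count` and `shared` (sorted shared ids).
#' @export
probe_overlap <- function(set_a, set_b) {
  ids <- function(s) {
    if (inherits(s, "clock_definition")) names(s$coefficients)
    else as.character(s)
  }
  shared <- sort(intersect(unique(ids(set_a)), unique(ids(set_b))))
  list(count = length(shared), shared = shared)
}
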