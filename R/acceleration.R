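## acceleration: the catalogue of age-acceleration definitions.
##
## Three definitions circulate in the literature and they are NOT
## interchangeable when the clock is biased:
##   delta     — DNAm age minus chronological age; inherits any
##               age-dependent clock bias, so it correlates with age.
##   residual  — residuals of DNAm age regressed on chronological age
##               (plus optional covariates); orthogonal to age by
##               construction on the fitted set.
##   ageaccel  — deviation from the regression line fitted on controls
##               only, evaluated for all samples.

.new_acceleration <- function(sample_id, acceleration, method,
                              reference_fit = NULL) {
  res <- data.frame(sample_id = as.character(sample_id),
                    acceleration = unname(acceleration),
                    stringsAsFactors = FALSE)
  attr(res, "method") <- method
  attr(res, "reference_fit") <- reference_fit
  class(res) <- c("acceleration_result", "data.frame")
  res
}

#' @export
print.acceleration_result <- function(x, ...) {
  cat(sprintf("<acceleration_result> method '%s', %d samples\n",
              attr(x, "method"), nrow(x)))
  rf <- attr(x, "reference_fit")
  if (!is.null(rf)) {
    cat(sprintf("  reference fit: intercept %.4g, slope(age) %.4g, n = %d\n",
                rf$intercept, rf$slope, rf$n))
  }
  print.data.frame(head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat(sprintf("  ... %d more rows\n", nrow(x) - 6))
  invisible(x)
}

.match_pairs <- function(dnam, chron) {
  # both are either named vectors or data.frames carrying sample_id
  as_named <- function(v, what) {
    if (is.data.frame(v)) {
      col <- intersect(c("dnam_age", "acceleration", "chronological_age"),
                       names(v))[1]
      setNames(v[[col]], v$sample_id)
    } else if (!is.null(names(v))) {
      v
    } else {
      stop(sprintf("%s must be named by sample id (or a data.frame)", what),
           call. = FALSE)
    }
  }
  d <- as_named(dnam, "dnam_ages")
  c_ <- as_named(chron, "chronological_ages")
  only_d <- setdiff(names(d), names(c_))
  only_c <- setdiff(names(c_), names(d))
  if (length(only_d) > 0 || length(only_c) > 0) {
    stop(sprintf("unmatched sample ids: %s",
                 paste(head(c(only_d, only_c), 10), collapse = ", ")),
         call. = FALSE)
  }
  list(dnam = d, chron = c_[names(d)])
}

#' Delta age acceleration
#'
#' The plain difference DNAm age minus chronological age.  When the clock
#' underestimates old ages this quantity trends negative with age, which
#' is exactly what makes it a confounded measure of "acceleration".
#'
#' @param dnam_ages Named numeric vector of DNAm ages (names = sample
#'   ids), or the data.frame from [predict_dnam_age()].
#' @param chronological_ages Named numeric vector of chronological ages,
#'   paired by sample id.
#' @return An `acceleration_result` data frame (method `"delta"`).
#' @export
delta_age <- function(dnam_ages, chronological_ages) {
  p <- .match_pairs(dnam_ages, chronological_ages)
  .new_acceleration(names(p$dnam), p$dnam - p$chron, "delta")
}

.ols_accel_fit <- function(dnam, chron, covariates = NULL) {
  df <- data.frame(.dnam = dnam, .age = chron)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == length(dnam))
    df <- cbind(df, covariates)
  }
  fit <- stats::lm(.dnam ~ ., data = df)
  if (anyNA(coef(fit))) {
    stop("rank-deficient design in acceleration regression (collinear covariates?)",
         call. = FALSE)
  }
  fit
}

#' Residual age acceleration
#'
#' Residuals of OLS regression of DNAm age on chronological age (plus any
#' extra covariates, e.g. sex or cell proportions).  By OLS orthogonality
#' these residuals are uncorrelated with age over the fitted set, which is
#' why this definition — unlike [delta_age()] — does not inherit the
#' clock's age-dependent bias.
#'
#' @inheritParams delta_age
#' @param extra_covariates Optional data.frame of additional regressors,
#'   rows aligned to the order of `dnam_ages`.
#' @return An `acceleration_result` (method `"residual"`) whose
#'   `reference_fit` attribute records intercept, age slope and any
#'   covariate coefficients.
#' @export
residual_acceleration <- function(dnam_ages, chronological_ages,
                                  extra_covariates = NULL) {
  p <- .match_pairs(dnam_ages, chronological_ages)
  n <- length(p$dnam)
  if (n < 3) stop("residual acceleration needs >= 3 samples", call. = FALSE)
  fit <- .ols_accel_fit(p$dnam, p$chron, extra_covariates)
  cf <- coef(fit)
  rf <- list(intercept = unname(cf[1]), slope = unname(cf[".age"]),
             covariate_coefficients = cf[setdiff(names(cf),
                                                 c("(Intercept)", ".age"))],
             n = n)
  .new_acceleration(names(p$dnam), stats::residuals(fit), "residual", rf)
}

#' Control-referenced age acceleration (AgeAccel)
#'
#' Fits the DNAm-age-on-age regression on control samples only and
#' returns, for every sample (case and control), its deviation from that
#' control line.  Case samples never influence the reference fit.
#'
#' @inheritParams delta_age
#' @param control_mask Logical vector (named by sample id, or aligned to
#'   the paired samples) marking controls.
#' @return An `acceleration_result` (method `"ageaccel_control"`).
#' @export
ageaccel_control <- function(dnam_ages, chronological_ages, control_mask) {
  p <- .match_pairs(dnam_ages, chronological_ages)
  if (!is.null(names(control_mask))) {
    control_mask <- control_mask[names(p$dnam)]
  }
  stopifnot(length(control_mask) == length(p$dnam))
  control_mask <- as.logical(control_mask)
  if (sum(control_mask, na.rm = TRUE) < 3) {
    stop("AgeAccel needs >= 3 control samples", call. = FALSE)
  }
  ctrl <- which(!is.na(control_mask) & control_mask)
  fit <- .ols_accel_fit(p$dnam[ctrl], p$chron[ctrl])
  cf <- coef(fit)
  pred <- cf[1] + cf[2] * p$chron
  rf <- list(intercept = unname(cf[1]), slope = unname(cf[2]),
             covariate_coefficients = numeric(0), n = length(ctrl))
  .new_acceleration(names(p$dnam), p$dnam - pred, "ageaccel_control", rf)
}
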