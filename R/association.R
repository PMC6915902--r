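## association: age-acceleration vs phenotype regression, with/without age.

#' Regress age acceleration on a phenotype, with or without age
#'
#' OLS with acceleration (years) as the response and the phenotype as a
#' numeric predictor (ordinal stages such as Braak 0-6 are coded
#' numerically), optionally adding chronological age as a covariate.
#' Because delta-style acceleration is itself age-dependent under a
#' biased clock, any age-correlated phenotype shows a "significant"
#' association in the age-free model that attenuates or disappears once
#' age is covaried — the motivating contrast of this package.
#'
#' @param accel An `acceleration_result` (from [delta_age()],
#'   [residual_acceleration()] or [ageaccel_control()]) or a named numeric
#'   vector of accelerations.
#' @param phenotype Named numeric vector (or vector aligned to `accel`).
#' @param chronological_ages Named numeric vector of ages; required when
#'   `include_age = TRUE`.
#' @param include_age Add chronological age as a covariate?
#' @param extra_covariates Optional data.frame of further covariates,
#'   rows aligned to the samples used.
#' @param phenotype_name Label stored in the result.
#' @return A list of class `association_fit`: `phenotype_name`,
#'   `coefficient` (years of acceleration per phenotype unit), `se`,
#'   `p_value`, `age_covaried`, `n`, `covariate_coefficients`.
#' @export
accel_phenotype_regression <- function(accel, phenotype,
                                       chronological_ages = NULL,
                                       include_age = FALSE,
                                       extra_covariates = NULL,
                                       phenotype_name = "phenotype") {
  if (inherits(accel, "acceleration_result") || is.data.frame(accel)) {
    accel <- setNames(accel$acceleration, accel$sample_id)
  }
  align <- function(v) {
    if (!is.null(names(v)) && !is.null(names(accel))) {
      missing <- setdiff(names(accel), names(v))
      if (length(missing) > 0) {
        stop(sprintf("no value for sample(s): %s",
                     paste(head(missing, 10), collapse = ", ")),
             call. = FALSE)
      }
      v[names(accel)]
    } else {
      stopifnot(length(v) == length(accel))
      v
    }
  }
  phenotype <- as.numeric(align(phenotype))
  n <- length(accel)
  if (n < 4) stop("association needs >= 4 samples", call. = FALSE)
  if (var(phenotype, na.rm = TRUE) == 0) {
    stop("phenotype is constant; association undefined", call. = FALSE)
  }
  df <- data.frame(.accel = as.numeric(accel), .pheno = phenotype)
  if (include_age) {
    if (is.null(chronological_ages)) {
      stop("include_age = TRUE requires chronological_ages", call. = FALSE)
    }
    df$.age <- as.numeric(align(chronological_ages))
  }
  if (!is.null(extra_covariates)) {
    extra_covariates <- as.data.frame(extra_covariates)
    stopifnot(nrow(extra_covariates) == n)
    df <- cbind(df, extra_covariates)
  }
  fit <- stats::lm(.accel ~ ., data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    dropped <- names(cf)[is.na(cf)]
    stop(sprintf("collinear design: could not estimate %s",
                 paste(dropped, collapse = ", ")), call. = FALSE)
  }
  sm <- summary(fit)$coefficients
  other <- setdiff(rownames(sm), c("(Intercept)", ".pheno"))
  structure(list(
    phenotype_name = phenotype_name,
    coefficient = unname(sm[".pheno", 1]),
    se = unname(sm[".pheno", 2]),
    p_value = unname(sm[".pheno", 4]),
    age_covaried = include_age,
    n = nrow(df) - length(stats::na.action(fit) %||% integer(0)),
    covariate_coefficients = setNames(sm[other, 1], other)),
    class = "association_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.association_fit <- function(x, ...) {
  cat(sprintf(
    "<association_fit> acceleration ~ %s%s (n = %d)\n  coefficient %.4f (se %.4f), p = %.4g\n",
    x$phenotype_name, if (x$age_covaried) " + age" else "", x$n,
    x$coefficient, x$se, x$p_value))
  invisible(x)
}

#' Tabulate an association fit
#'
#' One-row data.frame form of [accel_phenotype_regression()] output, for
#' CSV export.
#'
#' @param fit An `association_fit`.
#' @return One-row `data.frame`.
#' @export
association_as_row <- function(fit) {
  stopifnot(inherits(fit, "association_fit"))
  data.frame(phenotype = fit$phenotype_name,
             coefficient = fit$coefficient, se = fit$se,
             p_value = fit$p_value, age_covaried = fit$age_covaried,
             n = fit$n, stringsAsFactors = FALSE)
}
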