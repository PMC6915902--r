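## clock_engine: calibrated linear age prediction from beta values.

#' Anchored log-linear age transform
#'
#' The calibration used by the multi-tissue clock: ages below the anchor
#' (the end of development, conventionally 20 years) are mapped
#' logarithmically, ages above linearly, with a continuous join at the
#' anchor where the transform is 0:
#' \deqn{F(a) = \log(a + 1) - \log(A + 1) \quad (a \le A);\qquad
#'       F(a) = (a - A)/(A + 1) \quad (a > A).}
#'
#' @param age Age(s) in years, `>= 0`.  Vectorized.
#' @param anchor_years Anchor age A in years, `> 0` (default 20).
#' @return Transformed age(s); strictly increasing in `age`, 0 at the
#'   anchor.
#' @examples
#' transform_age(c(0, 20, 41), anchor_years = 20)  # -log(21), 0, 1
#' @export
transform_age <- function(age, anchor_years = 20) {
  stopifnot(is.numeric(age), is.numeric(anchor_years),
            length(anchor_years) == 1, anchor_years > 0)
  if (any(!is.na(age) & age < 0)) {
    stop("age must be >= 0", call. = FALSE)
  }
  ifelse(age <= anchor_years,
         log(age + 1) - log(anchor_years + 1),
         (age - anchor_years) / (anchor_years + 1))
}

#' Inverse of the anchored log-linear age transform
#'
#' Total on the real line; values below `-log(anchor_years + 1)` invert to
#' negative ages, which are returned as-is (with a warning) rather than
#' clipped — a predicted negative age is a symptom of clock pathology that
#' the audit should surface, not hide.
#'
#' @param y Transformed age(s).  Vectorized.
#' @param anchor_years Anchor age A in years, `> 0` (default 20).
#' @param warn Warn when any output age is negative (default TRUE).
#' @return Age(s) in years with `inverse_transform_age(transform_age(a)) == a`.
#' @export
inverse_transform_age <- function(y, anchor_years = 20, warn = TRUE) {
  stopifnot(is.numeric(y), is.numeric(anchor_years),
            length(anchor_years) == 1, anchor_years > 0)
  age <- ifelse(y <= 0,
                (anchor_years + 1) * exp(y) - 1,
                (anchor_years + 1) * y + anchor_years)
  if (warn && any(!is.na(age) & age < 0)) {
    warning("inverse calibration produced negative age(s); returned unclipped",
            call. = FALSE)
  }
  age
}

#' Predict DNAm age from a beta matrix
#'
#' Computes the per-sample linear score
#' \deqn{m_i = \beta_0 + \sum_j \beta_j x_{ij}}
#' over the clock's probes and maps it to years through the clock's
#' calibration (identity clocks return the score unchanged; anchored
#' clocks apply [inverse_transform_age()]).
#'
#' Missing clock probes are handled by `missing_policy`:
#' \describe{
#'   \item{`"impute_mean"`}{(default) a missing cell is replaced by the
#'     probe's across-sample mean; probes absent from the matrix entirely
#'     are dropped from the score.}
#'   \item{`"drop"`}{missing cells contribute nothing to the score.}
#'   \item{`"error"`}{any clock probe absent from the matrix is an error.}
#' }
#' The applied policy and per-sample missing-probe counts are recorded in
#' the result; predicted negative ages are flagged, never clipped.
#'
#' @param betas Beta matrix (probes in rows).
#' @param clock A [clock_definition()].
#' @param missing_policy One of `"impute_mean"`, `"drop"`, `"error"`.
#' @return A `data.frame` with columns `sample_id`, `dnam_age`,
#'   `linear_score`, `n_probes_used`, `n_probes_missing`, `negative_age`,
#'   and attributes `missing_policy` and `clock_name`.
#' @examples
#' b <- beta_matrix(matrix(c(0.8, 0.3), 2, 1,
#'        dimnames = list(c("cgA", "cgB"), "s1")))
#' clk <- clock_definition("toy", 0, c(cgA = 1, cgB = -1),
#'        calibration = list(kind = "anchored_log_linear", anchor_years = 20))
#' predict_dnam_age(b, clk)  # score 0.5 -> 30.5 years
#' @export
predict_dnam_age <- function(betas, clock,
                             missing_policy = c("impute_mean", "drop",
                                                "error")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(clock, "clock_definition"))
  betas <- beta_matrix(betas)
  probes <- names(clock$coefficients)
  n_clock <- length(probes)
  present <- intersect(probes, rownames(betas))
  absent <- setdiff(probes, rownames(betas))

  if (missing_policy == "error" && length(absent) > 0) {
    stop(sprintf("clock probes absent from beta matrix: %s%s",
                 paste(head(absent, 10), collapse = ", "),
                 if (length(absent) > 10) ", ..." else ""), call. = FALSE)
  }
  if (n_clock > 0 && length(present) == 0) {
    stop("no clock probes present in beta matrix", call. = FALSE)
  }

  x <- betas[present, , drop = FALSE]
  miss <- is.na(x)
  if (missing_policy == "impute_mean" && any(miss)) {
    pm <- rowMeans(x, na.rm = TRUE)  # NaN if a probe is all-missing
    idx <- which(miss, arr.ind = TRUE)
    x[miss] <- pm[idx[, 1]]
  }
  w <- clock$coefficients[present]
  contrib <- x * w                     # NA where still missing
  score <- clock$intercept + colSums(contrib, na.rm = TRUE)
  # a sample contributing no probe at all has no meaningful score
  n_avail <- length(present) - colSums(is.na(contrib))
  all_missing <- n_clock > 0 & n_avail == 0
  score[all_missing] <- NA_real_

  dnam_age <- if (clock$calibration$kind == "identity") {
    score
  } else {
    inverse_transform_age(score, clock$calibration$anchor_years, warn = FALSE)
  }
  res <- data.frame(
    sample_id = colnames(betas),
    dnam_age = unname(dnam_age),
    linear_score = unname(score),
    n_probes_used = unname(n_avail),
    n_probes_missing = unname(n_clock - n_avail),
    negative_age = unname(!is.na(dnam_age) & dnam_age < 0),
    stringsAsFactors = FALSE)
  if (any(res$negative_age)) {
    warning(sprintf("%d sample(s) predicted a negative DNAm age",
                    sum(res$negative_age)), call. = FALSE)
  }
  attr(res, "missing_policy") <- missing_policy
  attr(res, "clock_name") <- clock$name
  res
}
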