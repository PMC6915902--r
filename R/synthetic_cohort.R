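## synthetic_cohort: seeded generator of methylation cohorts with the
## statistical structure under audit — bounded logistic (hence saturating)
## age trajectories per locus, logit-scale noise, and an age-correlated
## ordinal phenotype that has NO direct methylation link (conditional
## independence given age: exactly the confounding structure that makes
## age-free acceleration associations spurious).

.logistic <- function(x) 1 / (1 + exp(-x))

#' Configuration for the synthetic methylation cohort
#'
#' Per-locus beta values follow
#' \deqn{\beta_{ij} = \mathrm{logistic}(\alpha_j + \gamma_j a_i +
#'   \epsilon_{ij}),\quad \epsilon_{ij} \sim N(0, \sigma_j^2),}
#' so trajectories are monotone in age, strictly inside (0, 1), and
#' compress (saturate) as they approach the boundaries.  Informative loci
#' draw a sign at random, a logit-scale slope `gamma` from
#' `gamma_range` per year and a value at the young edge of the training
#' range from `young_logit_range` (mirrored for decreasing loci), which
#' places the training years in the quasi-linear band and the old years in
#' the saturating band.  The remaining loci are flat (`gamma = 0`) with
#' baseline logits from `flat_logit_range`.
#'
#' The ordinal phenotype (Braak-like, levels `0 .. ordinal_levels - 1`)
#' discretizes a latent `kappa * age + eta`, `eta ~ N(0,
#' phenotype_noise_sd^2)`, by equal-width bins over the realized latent
#' range.  It depends on methylation only through age.
#'
#' Samples are drawn in two strata: `n_train` ages uniform on
#' `train_age_range` and `n_test` on `test_age_range`, labelled in the
#' metadata `split` column, so a clock can be trained on the young stratum
#' and audited on the old one.
#'
#' @param n_train,n_test Samples per stratum.
#' @param train_age_range,test_age_range Age ranges in years
#'   (`c(lo, hi)`, `lo < hi`).
#' @param n_loci Total loci.
#' @param n_informative Loci with a nonzero age trend (`<= n_loci`).
#' @param gamma_range Magnitude range of the logit-scale age slope, per
#'   year.
#' @param young_logit_range Logit of an increasing informative locus at
#'   the young edge of the training range (negated for decreasing loci).
#' @param flat_logit_range Baseline logit range of uninformative loci.
#' @param noise_sd_range Per-locus logit-scale noise SD range.
#' @param kappa Phenotype latent slope, phenotype units per year of age
#'   (0 gives a pure-noise phenotype).
#' @param phenotype_noise_sd SD of the latent phenotype noise.
#' @param ordinal_levels Number of ordinal phenotype levels (`>= 2`).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_train = 150, n_test = 150,
                              train_age_range = c(20, 60),
                              test_age_range = c(60, 100),
                              n_loci = 100, n_informative = 60,
                              gamma_range = c(0.04, 0.08),
                              young_logit_range = c(-1.5, -0.5),
                              flat_logit_range = c(-3, 3),
                              noise_sd_range = c(0.15, 0.35),
                              kappa = 0.08, phenotype_noise_sd = 1,
                              ordinal_levels = 7, seed = 1) {
  cfg <- list(n_train = n_train, n_test = n_test,
              train_age_range = train_age_range,
              test_age_range = test_age_range,
              n_loci = n_loci, n_informative = n_informative,
              gamma_range = gamma_range,
              young_logit_range = young_logit_range,
              flat_logit_range = flat_logit_range,
              noise_sd_range = noise_sd_range,
              kappa = kappa, phenotype_noise_sd = phenotype_noise_sd,
              ordinal_levels = ordinal_levels, seed = as.integer(seed))
  stopifnot(cfg$n_train + cfg$n_test >= 1,
            cfg$n_informative <= cfg$n_loci, cfg$n_loci >= 1,
            cfg$ordinal_levels >= 2,
            all(cfg$noise_sd_range >= 0))
  for (r in list(cfg$train_age_range, cfg$test_age_range)) {
    if (length(r) != 2 || r[1] < 0 || r[2] <= r[1]) {
      stop("age ranges must be c(lo, hi) with 0 <= lo < hi", call. = FALSE)
    }
  }
  class(cfg) <- "cohort_sim_config"
  cfg
}

.sim_locus_params <- function(config) {
  # own RNG stream so the truth table is reproducible independently of
  # the sample draw
  set.seed(config$seed)
  n <- config$n_loci
  k <- config$n_informative
  probe_id <- sprintf("cgS%06d", seq_len(n))
  informative <- seq_len(n) <= k
  sgn <- ifelse(runif(n) < 0.5, 1, -1)
  gamma <- ifelse(informative,
                  sgn * runif(n, config$gamma_range[1],
                              config$gamma_range[2]),
                  0)
  a0 <- config$train_age_range[1]
  young_logit <- runif(n, config$young_logit_range[1],
                       config$young_logit_range[2])
  flat_logit <- runif(n, config$flat_logit_range[1],
                      config$flat_logit_range[2])
  alpha <- ifelse(informative, sgn * young_logit - gamma * a0, flat_logit)
  sigma <- runif(n, config$noise_sd_range[1], config$noise_sd_range[2])
  data.frame(probe_id = probe_id, alpha = alpha, gamma = gamma,
             sigma = sigma, informative = informative,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic methylation cohort
#'
#' Draws the cohort described by a [cohort_sim_config()]: a beta matrix
#' (all values strictly in (0, 1) by construction of the logistic link),
#' sample metadata with chronological age, train/test `split` and the
#' ordinal `braak_stage` phenotype, and the true per-locus generative
#' parameters.
#'
#' @param config A [cohort_sim_config()].
#' @return A list: `betas` (beta matrix), `metadata` (data.frame),
#'   `truth` (per-locus parameter data.frame), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  loci <- .sim_locus_params(config)
  set.seed(config$seed + 1L)
  n <- config$n_train + config$n_test
  ages <- c(runif(config$n_train, config$train_age_range[1],
                  config$train_age_range[2]),
            runif(config$n_test, config$test_age_range[1],
                  config$test_age_range[2]))
  split <- rep(c("train", "test"), c(config$n_train, config$n_test))
  sample_id <- sprintf("S%04d", seq_len(n))

  eps <- matrix(rnorm(config$n_loci * n, sd = rep(loci$sigma, n)),
                nrow = config$n_loci)
  logits <- outer(loci$alpha, rep(1, n)) +
    outer(loci$gamma, ages) + eps
  betas <- .logistic(logits)
  dimnames(betas) <- list(loci$probe_id, sample_id)

  latent <- config$kappa * ages +
    rnorm(n, sd = config$phenotype_noise_sd)
  rng <- range(latent)
  if (rng[2] > rng[1]) {
    edges <- seq(rng[1], rng[2], length.out = config$ordinal_levels + 1)
    stage <- findInterval(latent, edges, rightmost.closed = TRUE) - 1L
  } else {
    stage <- rep(0L, n)
  }
  metadata <- data.frame(sample_id = sample_id,
                         chronological_age = ages, split = split,
                         braak_stage = stage, stringsAsFactors = FALSE)
  list(betas = beta_matrix(betas), metadata = metadata, truth = loci,
       config = config)
}

#' Train a demonstration clock by ridge regression
#'
#' Regresses the anchored-transformed age on the selected beta values:
#' the coefficient vector solves
#' \deqn{(X_c^T X_c + \lambda I)\, b = X_c^T y_c}
#' with column-centred predictors and response (the intercept is not
#' penalized).  `lambda = 0` gives ordinary least squares (and errors on
#' a rank-deficient design, advising `lambda > 0`).  The result is an
#' anchored [clock_definition()] directly usable by
#' [predict_dnam_age()].  This is a deliberately simple stand-in for the
#' published elastic-net clocks: enough to reproduce the saturation-driven
#' underestimation mechanism end to end, with no claim of replicating any
#' published training protocol.
#'
#' @param betas Training beta matrix (probes in rows).
#' @param ages Chronological ages of the training samples (named by
#'   sample id or aligned to columns).
#' @param probes Probe subset to use (default: all rows of `betas`).
#' @param lambda Ridge penalty, `>= 0` (default 0.01).
#' @param anchor_years Calibration anchor in years (default 20).
#' @param name Clock label.
#' @return A [clock_definition()] with anchored log-linear calibration.
#' @export
train_demo_clock <- function(betas, ages, probes = rownames(betas),
                             lambda = 0.01, anchor_years = 20,
                             name = "demo_ridge") {
  stopifnot(lambda >= 0, anchor_years > 0)
  betas <- beta_matrix(betas)
  if (!is.null(names(ages))) ages <- ages[colnames(betas)]
  stopifnot(length(ages) == ncol(betas))
  if (ncol(betas) <= 2) stop("training needs more than 2 samples",
                             call. = FALSE)
  X <- t(betas[probes, , drop = FALSE])
  y <- transform_age(as.numeric(ages), anchor_years)
  xm <- colMeans(X)
  Xc <- sweep(X, 2, xm)
  ym <- mean(y)
  G <- crossprod(Xc) + diag(lambda, ncol(Xc))
  b <- tryCatch(solve(G, crossprod(Xc, y - ym)),
                error = function(e) {
                  stop("design is rank-deficient with lambda = 0; use lambda > 0",
                       call. = FALSE)
                })
  b <- drop(b)
  clock_definition(
    name = name,
    intercept = ym - sum(xm * b),
    coefficients = setNames(b, probes),
    calibration = list(kind = "anchored_log_linear",
                       anchor_years = anchor_years))
}

#' Spurious-association experiment
#'
#' The end-to-end demonstration: repeatedly (i) simulate a cohort whose
#' ordinal phenotype depends on age only, (ii) train the demo clock on
#' the young stratum, (iii) predict DNAm age for the full cohort, (iv)
#' compute delta-age acceleration, and (v) regress it on the phenotype
#' both without and with chronological age as covariate.
#' Because the trained clock saturates on the old stratum, delta-age
#' trends with age; the age-free regression therefore "finds" an
#' association with the (age-correlated, methylation-free) phenotype in
#' most repeats, while the age-covaried regression does not.
#'
#' @param config A [cohort_sim_config()]; its `seed` is re-derived per
#'   repeat from `seed`.
#' @param n_repeats Number of repeats (default 50).
#' @param seed Base seed; repeat r uses `seed + r`.
#' @param lambda Ridge penalty for the demo clock.
#' @return A `data.frame` with one row per repeat (`seed`,
#'   `coef_without_age`, `p_without`, `coef_with_age`, `p_with`) and
#'   attribute `summary`: `frac_sig_without`, `frac_sig_with` (fraction
#'   of repeats with p < 0.05), `n_repeats`.
#' @export
spurious_association_experiment <- function(config = cohort_sim_config(),
                                            n_repeats = 50, seed = 1,
                                            lambda = 0.01) {
  stopifnot(inherits(config, "cohort_sim_config"), n_repeats >= 1)
  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    sim <- simulate_cohort(cfg)
    tr <- sim$metadata$split == "train"
    clock <- train_demo_clock(sim$betas[, tr, drop = FALSE],
                              setNames(sim$metadata$chronological_age[tr],
                                       sim$metadata$sample_id[tr]),
                              lambda = lambda)
    pred <- predict_dnam_age(sim$betas, clock)
    chron <- setNames(sim$metadata$chronological_age,
                      sim$metadata$sample_id)
    accel <- delta_age(pred, chron)
    pheno <- setNames(sim$metadata$braak_stage,
                      sim$metadata$sample_id)
    f0 <- accel_phenotype_regression(accel, pheno, include_age = FALSE,
                                     phenotype_name = "braak_stage")
    f1 <- accel_phenotype_regression(accel, pheno,
                                     chronological_ages = chron,
                                     include_age = TRUE,
                                     phenotype_name = "braak_stage")
    rows[[r]] <- data.frame(seed = cfg$seed,
                            coef_without_age = f0$coefficient,
                            p_without = f0$p_value,
                            coef_with_age = f1$coefficient,
                            p_with = f1$p_value)
  }
  out <- do.call(rbind, rows)
  attr(out, "summary") <- list(
    frac_sig_without = mean(out$p_without < 0.05),
    frac_sig_with = mean(out$p_with < 0.05),
    n_repeats = n_repeats)
  out
}
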