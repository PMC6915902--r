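logistic <- function(x) 1 / (1 + exp(-x))

test_that("degenerate generator settings give the closed-form betas", {
  # gamma = 0, sigma = 0: every locus constant at logistic(alpha)
  cfg <- cohort_sim_config(n_train = 5, n_test = 5, n_loci = 8,
                           n_informative = 0, noise_sd_range = c(0, 0),
                           seed = 61)
  sim <- simulate_cohort(cfg)
  expect_equal(unname(sim$betas),
               matrix(rep(logistic(sim$truth$alpha), 10), nrow = 8),
               tolerance = 1e-12)
})

test_that("a single noiseless locus follows logistic(alpha + gamma * age)", {
  cfg <- cohort_sim_config(n_train = 3, n_test = 3,
                           train_age_range = c(0, 1e-9),
                           test_age_range = c(40, 40 + 1e-9),
                           n_loci = 1, n_informative = 1,
                           gamma_range = c(0.05, 0.05),
                           young_logit_range = c(0, 0),
                           noise_sd_range = c(0, 0), seed = 62)
  sim <- simulate_cohort(cfg)
  # informative locus: sign may be +/-; force interpretation via truth
  g <- sim$truth$gamma
  a <- sim$truth$alpha
  expect_equal(abs(g), 0.05, tolerance = 1e-12)
  young <- sim$metadata$split == "train"
  expect_equal(unname(sim$betas[1, young]),
               rep(logistic(a + g * 0), 3) , tolerance = 1e-6)
  expect_equal(unname(sim$betas[1, !young]),
               rep(logistic(a + g * 40), 3), tolerance = 1e-6)
  # and with alpha = 0, gamma = +0.05: beta(0) = 0.5, beta(40) = 0.8808
  if (g > 0) {
    expect_equal(unname(sim$betas[1, young][1]), 0.5, tolerance = 1e-6)
    expect_equal(unname(sim$betas[1, !young][1]), logistic(2),
                 tolerance = 1e-6)
  }
})

test_that("the seeding contract gives bit-identical and distinct cohorts", {
  cfg <- cohort_sim_config(seed = 63)
  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1$betas, s2$betas)
  expect_identical(s1$metadata, s2$metadata)
  s3 <- simulate_cohort(cohort_sim_config(seed = 64))
  expect_false(identical(s1$betas, s3$betas))
})

test_that("simulated betas are strictly inside (0, 1) across random configs", {
  set.seed(65)
  for (rep in 1:5) {
    cfg <- cohort_sim_config(
      n_train = sample(10:40, 1), n_test = sample(10:40, 1),
      n_loci = sample(10:50, 1), n_informative = sample(0:10, 1),
      noise_sd_range = sort(runif(2, 0, 1)),
      flat_logit_range = c(-6, 6), seed = 650 + rep)
    sim <- simulate_cohort(cfg)
    expect_true(all(sim$betas > 0 & sim$betas < 1))
  }
})

test_that("mean trajectories are monotone in age in the direction of gamma", {
  cfg <- cohort_sim_config(n_train = 300, n_test = 300,
                           noise_sd_range = c(0.05, 0.1), seed = 66)
  sim <- simulate_cohort(cfg)
  ages <- sim$metadata$chronological_age
  ord <- order(ages)
  thirds <- split(ord, cut(seq_along(ord), 3, labels = FALSE))
  for (j in which(sim$truth$informative)) {
    m <- vapply(thirds, function(ix) mean(sim$betas[j, ix]), numeric(1))
    expect_true(all(sign(diff(m)) == sign(sim$truth$gamma[j])))
  }
})

test_that("the phenotype is ordinal, age-linked for kappa > 0 and null for kappa = 0", {
  cfg <- cohort_sim_config(seed = 67)
  sim <- simulate_cohort(cfg)
  st <- sim$metadata$braak_stage
  expect_true(all(st %in% 0:6))
  expect_gt(cor(st, sim$metadata$chronological_age), 0.5)
  sim0 <- simulate_cohort(cohort_sim_config(kappa = 0, seed = 67))
  expect_lt(abs(cor(sim0$metadata$braak_stage,
                    sim0$metadata$chronological_age)), 0.2)
})

test_that("OLS demo clock recovers ages on noiseless quasi-linear data", {
  cfg <- cohort_sim_config(n_train = 80, n_test = 0,
                           train_age_range = c(25, 55),
                           n_loci = 5, n_informative = 5,
                           gamma_range = c(0.03, 0.09),
                           young_logit_range = c(-2, 0.5),
                           noise_sd_range = c(0, 0), seed = 68)
  sim <- simulate_cohort(cfg)
  ages <- setNames(sim$metadata$chronological_age, sim$metadata$sample_id)
  clk <- train_demo_clock(sim$betas, ages, lambda = 0)
  pred <- predict_dnam_age(sim$betas, clk)
  expect_lt(sqrt(mean((pred$dnam_age - ages)^2)), 0.1)
})

test_that("ridge matches an independent closed-form solution and shrinks correctly", {
  cfg <- cohort_sim_config(n_train = 60, n_test = 0, n_loci = 15,
                           n_informative = 10, seed = 69)
  sim <- simulate_cohort(cfg)
  ages <- setNames(sim$metadata$chronological_age, sim$metadata$sample_id)
  lambda <- 0.5
  clk <- train_demo_clock(sim$betas, ages, lambda = lambda)
  o <- ridge_normal_eq(t(sim$betas), transform_age(ages, 20), lambda)
  expect_equal(unname(clk$coefficients), unname(o$coef),
               tolerance = 1e-8)
  expect_equal(clk$intercept, o$intercept, tolerance = 1e-8)
  # lambda -> Inf: coefficients vanish, predictions collapse to the
  # inverse-transformed mean of the transformed training ages
  big <- train_demo_clock(sim$betas, ages, lambda = 1e9)
  expect_lt(max(abs(big$coefficients)), 1e-6)
  pred <- predict_dnam_age(sim$betas, big)
  expect_equal(pred$dnam_age,
               rep(inverse_transform_age(mean(transform_age(ages, 20)), 20),
                   60),
               tolerance = 1e-3)
})

test_that("rank-deficient OLS training advises a positive penalty", {
  cfg <- cohort_sim_config(n_train = 80, n_test = 0,
                           train_age_range = c(25, 55),
                           n_loci = 20, n_informative = 20,
                           noise_sd_range = c(0, 0), seed = 70)
  sim <- simulate_cohort(cfg)
  ages <- setNames(sim$metadata$chronological_age, sim$metadata$sample_id)
  expect_error(train_demo_clock(sim$betas, ages, lambda = 0),
               "lambda > 0")
})

test_that("delta-age trends with age on the elderly stratum but residuals do not", {
  cfg <- cohort_sim_config(n_train = 500, n_test = 2000, seed = 71)
  sim <- simulate_cohort(cfg)
  tr <- sim$metadata$split == "train"
  ages <- setNames(sim$metadata$chronological_age, sim$metadata$sample_id)
  clk <- train_demo_clock(sim$betas[, tr], ages[tr])
  pred <- predict_dnam_age(sim$betas[, !tr], clk)
  chron <- ages[!tr]
  d <- delta_age(pred, chron)
  r <- residual_acceleration(pred, chron)
  expect_lt(cor(d$acceleration, chron[d$sample_id]), -0.5)
  expect_lt(abs(cor(r$acceleration, chron[r$sample_id])), 0.05)
})

test_that("one-repeat experiment returns a finite one-row table", {
  res <- spurious_association_experiment(n_repeats = 1, seed = 72)
  expect_equal(nrow(res), 1)
  expect_true(all(is.finite(unlist(res))))
  sm <- attr(res, "summary")
  expect_true(sm$frac_sig_without %in% c(0, 1))
})
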