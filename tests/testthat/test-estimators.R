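test_that("individual effects recover the worked example and degenerate cases", {
  eff <- individual_effects(worked_example_trial(), period_adjust = FALSE)
  expect_equal(eff$d_hat, -0.5)  # 0.5 kg lost due to treatment
  expect_equal(eff$n_treat, 2L)
  expect_equal(eff$n_control, 2L)

  flat <- trial_from(rep(1L, 4), 1:4, c("T", "C", "T", "C"), rep(-1, 4))
  expect_equal(individual_effects(flat, period_adjust = FALSE)$d_hat, 0)
})

test_that("parallel-groups data make individual effects impossible", {
  po <- simulate_potential_outcomes(
    trial_params(tau = -0.5, sigma2_trh = 1, sigma2_resid = 1), 10, 4,
    seed = 31)
  pgd <- observe(po, build_schedule("pgd", 10, 4, seed = 32))
  expect_error(individual_effects(pgd), class = "rrd_identifiability_error")
})

test_that("subjects with one condition are skipped and counted", {
  tr <- trial_from(c(1, 1, 2, 2), c(1, 2, 1, 2), c("T", "C", "T", "T"),
                   c(0, 0.5, 1, 2))
  eff <- individual_effects(tr, period_adjust = FALSE)
  expect_equal(nrow(eff), 1L)
  expect_equal(attr(eff, "n_skipped"), 1L)
})

test_that("pooled residual variance matches hand computation and fails without replication", {
  one <- trial_from(c(1, 1, 1), 1:3, c("T", "T", "C"), c(1, 3, 0))
  expect_equal(as.numeric(pooled_residual_variance(one, period_adjust = FALSE)),
               2)  # var(c(1, 3))

  noise_free <- sim_rrd_trial(trial_params(tau = -0.5), 5, 4, seed = 41)
  expect_equal(as.numeric(pooled_residual_variance(noise_free,
                                                   period_adjust = FALSE)),
               0)

  po <- simulate_potential_outcomes(
    trial_params(sigma2_trh = 1, sigma2_resid = 1), 20, 2, seed = 42)
  balaam <- observe(po, build_schedule("balaam", 20, 2, seed = 43))
  expect_error(pooled_residual_variance(balaam),
               class = "rrd_identifiability_error")
  crossover <- observe(po, build_schedule("crossover2", 20, 2, seed = 44))
  expect_error(trh_moment(crossover), class = "rrd_identifiability_error")
})

test_that("moment estimator: zero-heterogeneity data give zero TRH, pure noise truncates", {
  # all d_hat_i identical, no noise
  flat <- sim_rrd_trial(trial_params(tau = -0.5), 10, 4, seed = 51)
  est <- trh_moment(flat, period_adjust = FALSE)
  expect_equal(est$sigma2_trh_hat, 0)
  expect_equal(est$mu_d_hat, -0.5)
  expect_equal(est$sigma2_resid_hat, 0)

  # pure noise, no TRH: raw estimate may be negative, truncated to 0
  noisy <- sim_rrd_trial(trial_params(sigma2_resid = 1), 8, 4, seed = 52)
  est2 <- trh_moment(noisy, period_adjust = FALSE)
  expect_gte(est2$sigma2_trh_hat, 0)
  expect_equal(est2$sigma2_trh_hat, max(0, est2$sigma2_trh_raw))
})

test_that("mixed model handles the noise-free degenerate fit", {
  flat <- sim_rrd_trial(trial_params(tau = -0.5), 6, 4, seed = 61)
  est <- trh_mixed(flat, period_adjust = FALSE)
  expect_equal(est$mu_d_hat, -0.5, tolerance = 1e-6)
  expect_lt(est$sigma2_trh_hat, 1e-8)
})

test_that("moment and mixed mu_D coincide on balanced data without period effects", {
  tr <- sim_rrd_trial(
    trial_params(tau = -0.5, sigma2_subject = 1, sigma2_trh = 1,
                 sigma2_resid = 1), 30, 8, seed = 62)
  m1 <- trh_moment(tr, period_adjust = FALSE)
  m2 <- trh_mixed(tr, period_adjust = FALSE)
  expect_equal(m1$mu_d_hat, m2$mu_d_hat, tolerance = 1e-6)
})

test_that("moment TRH estimates are unbiased before truncation", {
  # modest replicate count; the acceptance suite runs the full recovery
  raw <- sapply(1:60, function(r) {
    tr <- sim_rrd_trial(
      trial_params(tau = -0.5, sigma2_trh = 4, sigma2_resid = 1),
      200, 8, seed = 7000 + r)
    trh_moment(tr, period_adjust = FALSE)$sigma2_trh_raw
  })
  mc_se <- sd(raw) / sqrt(length(raw))
  expect_lt(abs(mean(raw) - 4), 3 * mc_se)
})

test_that("mean effect: zero when both arms show the same average change", {
  tr <- trial_from(subject_id = 1:10, period = rep(1L, 10),
                   arm = rep(c("T", "C"), each = 5),
                   outcome = rep(-1.57, 10))
  me <- mean_effect(tr)
  expect_equal(me$estimate, 0)
  expect_equal(me$method, "between_arm")

  # constant D_i = -0.5 everywhere
  flat <- sim_rrd_trial(trial_params(mu = -1.07, tau = -0.5), 10, 4, seed = 71)
  expect_equal(mean_effect(flat, period_adjust = FALSE)$estimate, -0.5)

  single_arm <- trial_from(1:4, rep(1L, 4), rep("C", 4), rnorm(4))
  expect_error(mean_effect(single_arm), class = "rrd_data_error")
})

test_that("mean effect on balanced RRD ignores subject-level intercept shifts", {
  tr <- sim_rrd_trial(
    trial_params(tau = -0.5, sigma2_trh = 1, sigma2_resid = 1), 20, 4,
    seed = 81)
  shifted <- tr
  shifted$outcome <- shifted$outcome + 100
  expect_equal(mean_effect(tr, period_adjust = FALSE)$estimate,
               mean_effect(as_rrd_trial(shifted), period_adjust = FALSE)$estimate)
})

test_that("responder proportions follow the normal model and its point-mass limit", {
  # symmetry at mu = 0
  r0 <- responder_proportions(list(mu_d_hat = 0, sigma2_trh_hat = 1), delta = 0)
  expect_equal(r0$prop_control_better, 0.5)

  # mu = -1, sigma = 1: P(D > 0) = 1 - pnorm(1); cross-checked by simulation
  r1 <- responder_proportions(list(mu_d_hat = -1, sigma2_trh_hat = 1),
                              delta = 0)
  expect_equal(r1$prop_control_better, 1 - pnorm(1))
  set.seed(1); draws <- rnorm(2e5, -1, 1)
  expect_lt(abs(r1$prop_control_better - mean(draws > 0)), 0.005)

  # point mass at -0.5
  rp <- responder_proportions(list(mu_d_hat = -0.5, sigma2_trh_hat = 0),
                              delta = 0.1)
  expect_equal(rp$prop_control_better, 0)
  expect_equal(rp$prop_treat_better, 1)
  expect_equal(rp$prop_nonresponder, 0)

  expect_error(responder_proportions(list(mu_d_hat = 0, sigma2_trh_hat = 1),
                                     delta = -1),
               class = "rrd_config_error")
})

test_that("responder probability masses account for the whole distribution", {
  for (mu in c(-1, 0, 0.3)) {
    r <- responder_proportions(list(mu_d_hat = mu, sigma2_trh_hat = 2),
                               delta = 0.4)
    below <- pnorm((-0.4 - mu) / sqrt(2))
    above <- 1 - pnorm((0.4 - mu) / sqrt(2))
    expect_equal(below + r$prop_nonresponder + above, 1, tolerance = 1e-12)
    expect_equal(r$prop_treat_better + r$prop_control_better, 1,
                 tolerance = 1e-12)
  }
})

test_that("empirical responder proportions are the d_hat plug-in", {
  eff <- tibble::tibble(d_hat = c(-2, -0.3, 0, 0.2, 1.5))
  re <- responder_proportions_empirical(eff, delta = 0.3)
  expect_equal(re$prop_nonresponder, 3 / 5)
  expect_equal(re$prop_treat_better, 2 / 5)
  expect_equal(re$prop_control_better, 2 / 5)
})
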