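test_that("simple-mean information calculus matches the closed forms", {
  i1 <- info_simple_mean(100, 20, 1, 1)
  expect_equal(i1$I_full, 100)
  expect_equal(i1$I_obs, 80)
  expect_equal(i1$I_sens, 100)    # homogeneous variance: nothing lost
  i2 <- info_simple_mean(100, 20, 1, 2.25)
  expect_equal(i2$I_sens, 80)     # the crossover with I_obs
  # strictly decreasing in the unobserved-population variance, -> 0
  grid <- seq(0.1, 50, by = 0.1)
  is <- vapply(grid, function(s) info_simple_mean(100, 20, 1, s)$I_sens,
               numeric(1))
  expect_true(all(diff(is) < 0))
  expect_lt(info_simple_mean(100, 20, 1, 1e8)$I_sens, 1e-3)
  expect_error(info_simple_mean(100, 20, -1, 1), "positive")
})

test_that("information classification compares retained proportions", {
  expect_equal(classify_information(80, 100, 40, 50)$classification,
               "anchored")
  expect_equal(classify_information(80, 100, 20, 50)$classification,
               "negative")
  expect_equal(classify_information(80, 100, 60, 50)$classification,
               "positive")
  r <- classify_information(80, 100, 40, 50)
  expect_equal(r$ratio_primary, 0.8)
  expect_equal(r$ratio_sensitivity, 0.8)
})

test_that("expected full-data variances follow the design formulas", {
  expect_equal(expected_full_variance_primary(fev_sigma, 250,
                                              baseline_adjusted = FALSE),
               2 * 0.6 / 250)     # 0.0048
  expect_equal(expected_full_variance_primary(fev_sigma, 250,
                                              baseline_adjusted = TRUE),
               2 * (0.6 - 0.04 / 0.4) / 250)   # 0.004

  pat <- list(n = 250, n_complete = 175, n_dev = c(visit2 = 38, visit3 = 37))
  # all deviation-pattern means equal to the on-treatment mean: MAR-like
  tv0 <- expected_full_variance_sensitivity(fev_sigma, 250, pat,
                                            mu_dev_final = c(2.2, 2.2),
                                            mu_a_final = 2.2,
                                            baseline_adjusted = FALSE)
  expect_equal(tv0$v_full_sensitivity, tv0$v_full_primary)
  # no deviators at all
  pat0 <- list(n = 250, n_complete = 250, n_dev = c(visit2 = 0, visit3 = 0))
  tvn <- expected_full_variance_sensitivity(fev_sigma, 250, pat0,
                                            mu_dev_final = c(1.9, 1.9),
                                            mu_a_final = 2.2,
                                            baseline_adjusted = FALSE)
  expect_equal(tvn$v_full_sensitivity, 0.0048)
  # heterogeneous pattern means can only inflate the variance
  for (s in 1:25) {
    set.seed(500 + s)
    nd <- c(visit2 = sample(0:60, 1), visit3 = sample(0:60, 1))
    pat_s <- list(n = 250, n_complete = 250 - sum(nd), n_dev = nd)
    tv <- expected_full_variance_sensitivity(
      fev_sigma, 250, pat_s, mu_dev_final = rnorm(2, 2, 0.5),
      mu_a_final = 2.2, baseline_adjusted = sample(c(TRUE, FALSE), 1))
    expect_gte(tv$v_full_sensitivity, tv$v_full_primary)
  }
})

test_that("the scenario-variance formula matches simulated fully observed
           sensitivity data", {
  # jump to reference at 30% dropout: deviators' final-visit mean is the
  # reference mean 1.9
  cfg <- sim_config(n_reps = 1)
  spec <- imputation_spec("J2R", "reference")
  pat <- list(n = 250, n_complete = 175, n_dev = c(visit2 = 38, visit3 = 37))
  tv <- expected_full_variance_sensitivity(fev_sigma, 250, pat,
                                           mu_dev_final = c(1.9, 1.9),
                                           mu_a_final = 2.2,
                                           baseline_adjusted = FALSE)
  vs <- vapply(1:300, function(r) {
    d <- generate_complete_trial(cfg, derive_seed(901, r))
    obs <- impose_mcar_monotone_dropout(d, 0.3, derive_seed(902, r))
    sens <- generate_full_sensitivity_data(obs, cfg, spec,
                                           seed = derive_seed(903, r))
    fit_diff_means(sens)$variance
  }, numeric(1))
  mcse <- sd(vs) / sqrt(length(vs))
  expect_lt(abs(mean(vs) - tv$v_full_sensitivity), 3 * mcse)
})

test_that("the delta Q term evaluates the cumulative-shift inflation", {
  pat <- list(n = 250, n_complete = 200, n_dev = c(visit2 = 25, visit3 = 25))
  expect_equal(delta_Q_term(pat, 0), 0)
  # single pattern: only the completer-deviator sum survives
  pat1 <- list(n = 100, n_complete = 80, n_dev = c(visit2 = 20, visit3 = 0))
  expect_equal(delta_Q_term(pat1, -0.5, J = 3),
               80 * 20 * (3 - 1)^2 * 0.25 / 100^3)
  # hand-evaluated three-term sum: J = 3, delta = -1
  q <- delta_Q_term(pat, -1, J = 3)
  hand <- (200 * 25 * 4 + 200 * 25 * 1 + 2 * 25 * 25 * 1) / 250^3
  expect_equal(q, hand)
})

test_that("the anchored variance scales the scenario variance by the
           primary information loss", {
  expect_equal(anchored_variance(0.004, 0.004, 0.005), 0.005)
  expect_equal(anchored_variance(0.006, 0.004, 0.005), 0.0075)
  expect_gte(anchored_variance(0.006, 0.004, 0.005), 0.005)
  expect_warning(anchored_variance(0.003, 0.004, 0.005), "gain")
  expect_error(anchored_variance(0, 0.004, 0.005), "positive")
})

test_that("the leading discrepancy term behaves per method", {
  pat <- list(n = 250, n_complete = 175, n_dev = c(visit2 = 38, visit3 = 37))
  # fixed delta: exactly zero
  dd <- theorem1_first_term(fev_sigma, pat, mu = fev_mu_act, scale = "delta")
  expect_identical(dd$first_term, 0)
  # subsampled reference: exactly zero
  ds <- theorem1_first_term(fev_sigma, pat, mu = fev_mu_act,
                            scale = "reference_subsampled")
  expect_identical(ds$first_term, 0)
  # no deviators: zero
  pat0 <- list(n = 250, n_complete = 250, n_dev = c(visit2 = 0, visit3 = 0))
  d0 <- theorem1_first_term(fev_sigma, pat0, mu = fev_mu_act,
                            scale = "reference_full")
  expect_equal(d0$first_term, 0)
  # full reference: positive, small relative to the full-data variance
  dr <- theorem1_first_term(fev_sigma, pat, mu = fev_mu_act,
                            scale = "reference_full")
  expect_gt(dr$first_term, 0)
  expect_equal(sum(dr$per_pattern), dr$first_term)
  v_full <- expected_full_variance_primary(fev_sigma, 250)
  expect_lt(dr$first_term / v_full, 0.05)
  # with the deviation proportions fixed, the term shrinks like 1/n:
  # ten times more patients, ten times smaller discrepancy
  pat10 <- list(n = 2500, n_complete = 1750,
                n_dev = c(visit2 = 380, visit3 = 370))
  dr10 <- theorem1_first_term(fev_sigma, pat10, mu = fev_mu_act,
                              scale = "reference_full")
  expect_equal(dr$first_term / dr10$first_term, 10, tolerance = 0.05)
  # random delta: total is -pi_d^2 sigma_delta^2 (information negative)
  drand <- theorem1_first_term(fev_sigma, pat, scale = "delta_random",
                               sigma_delta = 0.46)
  expect_equal(drand$first_term, -0.3^2 * 0.46^2)
})

test_that("information loss percentages match the worked values", {
  expect_equal(info_loss_percent(0.1, 0.1), 0)
  expect_equal(info_loss_percent(1, sqrt(2)), 50)
  expect_equal(info_loss_percent(0.072, 0.132), 70.2479, tolerance = 1e-4)
  expect_equal(round(info_loss_percent(0.072, 0.132)), 70)
  expect_error(info_loss_percent(0.2, 0.1), "gains")
})

test_that("variance inflation to the anchored level is achieved in the
           long run", {
  expect_equal(inflate_to_anchored(0.3, 0.004, 0.004), 0.3)
  expect_identical(inflate_to_anchored(0.3, 1, 2, seed = 5),
                   inflate_to_anchored(0.3, 1, 2, seed = 5))
  expect_error(inflate_to_anchored(0.3, 2, 1), "at least")
  set.seed(77)
  adj <- vapply(1:10000, function(i) inflate_to_anchored(0, 1, 2.5),
                numeric(1))
  # adjusted estimator variance = v_ml-part (0 here) + (v_anchored - v_ml)
  expect_equal(var(adj), 1.5, tolerance = 0.05)
})

test_that("the sample-size formula reproduces the design calculation", {
  expect_equal(sample_size_per_arm(0.23, 0.5, 0.05, 0.80), 75L)
  # doubling sigma quadruples n (before rounding)
  n1 <- 2 * (qnorm(0.975) + qnorm(0.8))^2 * 0.5^2 / 0.23^2
  expect_equal(sample_size_per_arm(0.23, 1.0, 0.05, 0.80), ceiling(4 * n1))
  expect_error(sample_size_per_arm(0, 0.5), "non-zero")
  # Monte-Carlo check: the returned n achieves the nominal power
  n <- sample_size_per_arm(0.23, 0.5, 0.05, 0.80)
  set.seed(88)
  rej <- vapply(1:600, function(r) {
    a <- rnorm(n, 0.23, 0.5)
    b <- rnorm(n, 0, 0.5)
    t.test(a, b, var.equal = TRUE)$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.75)   # nominal 0.80, MC se ~ 0.016
})

test_that("the heterogeneity threshold where sensitivity and observed
           information cross is recovered by root finding", {
  expect_equal(info_crossover_sigma_m2(100, 20, 1), 2.25, tolerance = 1e-8)
  # algebraic check at another design point
  n <- 60; nm <- 15; s2 <- 2
  root <- info_crossover_sigma_m2(n, nm, s2)
  expect_equal(root, s2 * (n^2 - (n - nm)^2) / (nm * (n - nm)),
               tolerance = 1e-8)
})
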