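trial_draw <- function() fixed_draw(fev_mu_act, fev_mu_ref, fev_sigma)

test_that("the controlled joint mean follows each method's rule", {
  dr <- trial_draw()
  j2r <- function(j) build_joint_mean(
    imputation_spec("J2R", "reference"), dr, "active", j)
  expect_equal(j2r(2), c(2.0, 1.95, 1.9))
  expect_equal(j2r(3), c(2.0, 2.21, 1.9))
  cir3 <- build_joint_mean(imputation_spec("CIR", "reference"), dr,
                           "active", 3)
  expect_equal(cir3, c(2.0, 2.21, 2.21 + (1.9 - 1.95)))   # 2.16
  lmcf3 <- build_joint_mean(imputation_spec("LMCF", "reference"), dr,
                            "active", 3)
  expect_equal(lmcf3, c(2.0, 2.21, 2.21))
  cr <- build_joint_mean(imputation_spec("CR", "reference"), dr,
                         "active", 2)
  expect_equal(cr, c(2.0, 1.95, 1.9))
  mar <- build_joint_mean(imputation_spec("MAR", "reference"), dr,
                          "active", 3)
  expect_equal(mar, c(2.0, 2.21, 2.2))

  # deviators in the reference arm itself are imputed under within-arm MAR
  ref_j2r <- build_joint_mean(imputation_spec("J2R", "reference"), dr,
                              "reference", 2)
  expect_equal(ref_j2r, fev_mu_ref)

  expect_error(build_joint_mean(imputation_spec("J2R", "reference"), dr,
                                "active", 1), "2..J")
  sep <- fixed_draw(fev_mu_act, fev_mu_ref, fev_sigma, pooling = "separate")
  expect_error(build_joint_mean(imputation_spec("CR", "reference"), sep,
                                "active", 2), "common")
})

test_that("imputation leaves complete datasets and observed cells
           untouched", {
  set.seed(11)
  full <- trial_dataset(paste0("p", 1:12),
                        rep(c("active", "reference"), 6),
                        matrix(rnorm(36, 2, 0.5), 12, 3))
  for (m in c("MAR", "J2R", "CIR", "CR", "LMCF")) {
    comp <- impute_once(full, trial_draw(), imputation_spec(m, "reference"),
                        seed = 1)
    expect_identical(comp$y, full$y)
  }
  # observed cells bit-identical across methods on incomplete data
  d <- random_monotone_dataset(77, n = 40)
  obs_mask <- !is.na(d$y)
  for (m in c("MAR", "J2R", "CIR", "CR", "LMCF")) {
    comp <- impute_once(d, trial_draw(), imputation_spec(m, "reference"),
                        seed = 2)
    expect_identical(comp$y[obs_mask], d$y[obs_mask])
    expect_false(anyNA(comp$y))
    expect_identical(attr(comp, "imputed"), !obs_mask)
  }
})

test_that("J2R imputations are centred on the reference means when the
           covariance is diagonal", {
  dr <- fixed_draw(c(5, 5, 5), c(1, 2, 3), diag(c(1, 1, 1)))
  d <- trial_dataset(c("p1", "r1", "r2"), c("active", "reference", "reference"),
                     rbind(c(5, NA, NA), c(1, 2, 3), c(1, 2, 3)))
  spec <- imputation_spec("J2R", "reference")
  set.seed(314)
  imp <- replicate(5000, impute_once(d, dr, spec)$y[1, 2:3])
  se <- 1 / sqrt(5000)
  expect_lt(abs(mean(imp[1, ]) - 2), 3 * se)
  expect_lt(abs(mean(imp[2, ]) - 3), 3 * se)
})

test_that("delta adjustment shifts imputed cells by the documented
           pattern", {
  d <- trial_dataset(c("p1", "p2", "r1"), c("active", "active", "reference"),
                     rbind(c(2.0, NA, NA), c(2.1, 2.2, NA), c(1.9, 2.0, 2.1)))
  dr <- trial_draw()
  base <- impute_once(d, dr, imputation_spec("DELTA", "reference",
                                             delta = -0.5), seed = 4)
  # delta = 0 is the identity
  zero <- apply_delta(base, imputation_spec("DELTA", "reference", delta = 0))
  expect_identical(zero$y, base$y)
  # cumulative: deviation at 2 -> shifts (-0.5, -1.0); at 3 -> (-0.5)
  shifted <- apply_delta(base, imputation_spec("DELTA", "reference",
                                               delta = -0.5))
  expect_equal(shifted$y[1, 2:3] - base$y[1, 2:3], c(-0.5, -1.0),
               ignore_attr = TRUE)
  expect_equal(shifted$y[2, 3] - base$y[2, 3], -0.5, ignore_attr = TRUE)
  expect_identical(shifted$y[3, ], base$y[3, ])   # no imputed cells
  # per-visit mode: every post-deviation visit gets delta
  pv <- apply_delta(base, imputation_spec("DELTA", "reference",
                                          delta = -0.5,
                                          delta_mode = "per_visit"))
  expect_equal(pv$y[1, 2:3] - base$y[1, 2:3], c(-0.5, -0.5),
               ignore_attr = TRUE)
  # random delta: one draw per imputation, centred on delta
  spec_r <- imputation_spec("DELTA", "reference", delta = -0.21,
                            delta_sd = 0.46)
  dks <- vapply(1:4000, function(k)
    attr(apply_delta(base, spec_r, seed = derive_seed(9, "dk", k)),
         "delta_k"), numeric(1))
  expect_lt(abs(mean(dks) + 0.21), 3 * 0.46 / sqrt(4000))
  expect_equal(sd(dks), 0.46, tolerance = 0.05)

  expect_error(apply_delta(base, imputation_spec("MAR", "reference")),
               "DELTA")
})

test_that("impute_all is seed-reproducible and composes the delta edit", {
  d <- random_monotone_dataset(55, n = 60)
  spec <- imputation_spec("J2R", "reference", K = 5)
  a <- impute_all(d, spec, seed = 123)
  b <- impute_all(d, spec, seed = 123)
  expect_identical(lapply(a, `[[`, "y"), lapply(b, `[[`, "y"))
  # distinct completed datasets when data have missing cells
  expect_false(identical(a[[1]]$y, a[[2]]$y))

  # fixed-delta imputations are an exact shift of the MAR imputations
  # sharing the same seed: the imputation-model draws coincide
  mar <- impute_all(d, imputation_spec("MAR", "reference", K = 4),
                    seed = 321)
  del <- impute_all(d, imputation_spec("DELTA", "reference", K = 4,
                                       delta = -0.3), seed = 321)
  fm <- ifelse(rowSums(!is.na(d$y)) == 3, NA, rowSums(!is.na(d$y)) + 1)
  for (k in 1:4) {
    diff <- del[[k]]$y - mar[[k]]$y
    for (i in seq_len(nrow(d$y))) {
      if (is.na(fm[i])) {
        expect_equal(diff[i, ], c(0, 0, 0), ignore_attr = TRUE)
      } else {
        ks <- fm[i]:3
        expect_equal(diff[i, ks], (ks - fm[i] + 1) * -0.3,
                     ignore_attr = TRUE)
      }
    }
  }
})

test_that("jump to reference and copy reference coincide for deviation at
           visit 2 when arm baselines share a mean", {
  mu_a <- c(2.0, 2.3, 2.4)   # same baseline mean as the reference arm
  dr <- fixed_draw(mu_a, fev_mu_ref, fev_sigma)
  m_j2r <- build_joint_mean(imputation_spec("J2R", "reference"), dr,
                            "active", 2)
  m_cr <- build_joint_mean(imputation_spec("CR", "reference"), dr,
                           "active", 2)
  expect_equal(m_j2r, m_cr)
  d <- trial_dataset(c("p1", "r1"), c("active", "reference"),
                     rbind(c(2.2, NA, NA), c(1.9, 2.0, 2.1)))
  y1 <- impute_once(d, dr, imputation_spec("J2R", "reference"), seed = 6)$y
  y2 <- impute_once(d, dr, imputation_spec("CR", "reference"), seed = 6)$y
  expect_identical(y1, y2)
})

test_that("stacked imputation export has one block per imputation", {
  d <- random_monotone_dataset(3, n = 20)
  imps <- impute_all(d, imputation_spec("MAR", "reference", K = 3),
                     seed = 5)
  path <- file.path(tempdir(), "stack.csv")
  write_imputations_csv(imps, path)
  stacked <- read.csv(path)
  expect_equal(nrow(stacked), 3 * 20)
  expect_equal(sort(unique(stacked$imputation)), 1:3)
  expect_true(all(c("imputed_y1", "imputed_y3") %in% names(stacked)))
})
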