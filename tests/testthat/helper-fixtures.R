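# Shared fixtures and independent oracles, built in code at test time.

# trial-like covariance/means used across tests (3 visits, FEV1-like scale)
fev_sigma <- matrix(c(0.4, 0.2, 0.2,
                      0.2, 0.5, 0.2,
                      0.2, 0.2, 0.6), 3, 3)
fev_mu_ref <- c(2.0, 1.95, 1.9)
fev_mu_act <- c(2.0, 2.21, 2.2)

# random monotone two-arm dataset for property tests
random_monotone_dataset <- function(seed, n = 30, J = 3,
                                    arms = c("active", "reference"),
                                    p_dev = 0.4) {
  set.seed(seed)
  arm <- sample(arms, n, replace = TRUE)
  y <- matrix(rnorm(n * J, 2, 0.5), n, J)
  for (i in seq_len(n)) {
    if (runif(1) < p_dev) {
      j <- 1L + sample.int(J - 1L, 1)   # deviation visit in 2..J
      y[i, j:J] <- NA_real_
    }
  }
  trial_dataset(sprintf("p%03d", seq_len(n)), arm, y)
}

# the 10-patient pattern fixture: 3 completers, 4 first-missing-at-2,
# 3 first-missing-at-3
patients10 <- function() {
  y <- rbind(
    c(2.0, 2.1, 2.2), c(1.9, 2.0, 2.1), c(2.2, 2.0, 1.9),   # completers
    c(2.1,  NA,  NA), c(1.8,  NA,  NA), c(2.0,  NA,  NA), c(2.3, NA, NA),
    c(1.7, 1.9,  NA), c(2.4, 2.2,  NA), c(2.0, 2.1,  NA))
  trial_dataset(sprintf("p%02d", 1:10), rep("active", 10), y)
}

# a parameter object usable where an mvn_draw is expected, at chosen values
fixed_draw <- function(mu_active, mu_reference, sigma,
                       pooling = "common") {
  structure(list(mu = list(active = mu_active, reference = mu_reference),
                 sigma = list(active = sigma, reference = sigma),
                 pooling = pooling, J = length(mu_active),
                 draw_index = 1L),
            class = "mvn_draw")
}

# Independent EM oracle for the bivariate-normal MLE with missing second
# coordinate (monotone). Used to check the sequential-regression MLE.
em_mle_bivariate <- function(y, tol = 1e-10, max_iter = 10000) {
  obs <- !is.na(y[, 2])
  mu <- c(mean(y[, 1]), mean(y[obs, 2]))
  S <- matrix(c(stats::var(y[, 1]), 0, 0, stats::var(y[obs, 2])), 2, 2)
  n <- nrow(y)
  for (it in seq_len(max_iter)) {
    b <- S[1, 2] / S[1, 1]
    cv <- S[2, 2] - S[1, 2]^2 / S[1, 1]
    ey2 <- ifelse(obs, y[, 2], mu[2] + b * (y[, 1] - mu[1]))
    ey22 <- ifelse(obs, y[, 2]^2, ey2^2 + cv)
    mu_new <- c(mean(y[, 1]), mean(ey2))
    s11 <- mean(y[, 1]^2) - mu_new[1]^2
    s12 <- mean(y[, 1] * ey2) - mu_new[1] * mu_new[2]
    s22 <- mean(ey22) - mu_new[2]^2
    S_new <- matrix(c(s11, s12, s12, s22), 2, 2)
    done <- max(abs(mu_new - mu), abs(S_new - S)) < tol
    mu <- mu_new
    S <- S_new
    if (done) break
  }
  list(mu = mu, sigma = S)
}
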