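#' Derive a reproducible sub-seed from a root seed
#'
#' All randomness in the package flows from a single root seed. Independent
#' random tasks (posterior draw k, imputation k, replicate r, ...) use
#' sub-seeds derived from the root seed and a sequence of integer or string
#' tokens through a fixed multiplicative hash, so the K imputations and the
#' simulation replicates are order-independent and individually
#' reproducible.
#'
#' @param seed integer root seed.
#' @param ... integer or character tokens identifying the task.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' derive_seed(1, "draw", 3)
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647
  h <- abs(as.numeric(seed)) %% m
  for (tok in list(...)) {
    ks <- if (is.character(tok)) utf8ToInt(paste(tok, collapse = "|"))
          else as.numeric(tok)
    for (k in ks) h <- (h * 69069 + abs(k) + 1) %% m
  }
  as.integer(h)
}

# ---------------------------------------------------------------------------
# Sequential-regression sufficient statistics for the monotone factorization.
#
# Under monotone missingness the per-arm multivariate-normal likelihood
# factorizes into J normal linear regressions: Y1 (on arm means only), then
# Yj on Y1..Y(j-1) for j = 2..J, each fitted to the patients observed at
# visit j. With pooling = "common" the covariance matrix is shared across
# arms, so slopes and residual variances are common and only the intercepts
# are arm specific; with pooling = "separate" each arm gets its own chain.
# ---------------------------------------------------------------------------
monotone_suffstats <- function(data, pooling = c("common", "separate")) {
  pooling <- match.arg(pooling)
  arms <- sort(unique(data$arm))
  J <- ncol(data$y)
  obs <- !is.na(data$y)

  fit_one <- function(rows, j, with_arms) {
    yj <- data$y[rows, j]
    hist <- if (j > 1L) data$y[rows, seq_len(j - 1L), drop = FALSE] else NULL
    X <- if (with_arms) {
      D <- matrix(0, length(rows), length(arms))
      D[cbind(seq_along(rows), match(data$arm[rows], arms))] <- 1
      D
    } else {
      matrix(1, length(yj), 1L)
    }
    if (!is.null(hist)) X <- cbind(X, hist)
    n_j <- nrow(X)
    p_j <- ncol(X)
    qr_x <- qr(X)
    if (qr_x$rank < p_j || n_j <= p_j)
      stop("singular (or under-determined) sequential regression at visit ", j)
    beta <- qr.coef(qr_x, yj)
    rss <- sum(qr.resid(qr_x, yj)^2)
    R <- qr.R(qr_x)[seq_len(p_j), seq_len(p_j), drop = FALSE]
    # reorder R columns to the original column order (qr may pivot)
    piv <- qr_x$pivot[seq_len(p_j)]
    Rinv <- backsolve(R, diag(p_j))[order(piv), , drop = FALSE]
    list(j = j, n = n_j, p = p_j, beta = beta, rss = rss, Rinv = Rinv,
         n_intercepts = if (with_arms) length(arms) else 1L)
  }

  regs <- list()
  if (pooling == "common") {
    for (j in seq_len(J)) {
      rows <- which(obs[, j])
      regs[[paste0("v", j)]] <- fit_one(rows, j, with_arms = TRUE)
    }
  } else {
    for (a in arms) for (j in seq_len(J)) {
      rows <- which(obs[, j] & data$arm == a)
      regs[[paste0(a, ".v", j)]] <- fit_one(rows, j, with_arms = FALSE)
    }
  }
  list(pooling = pooling, arms = arms, J = J, regs = regs,
       n_by_arm = table(factor(data$arm, levels = arms)))
}

# Recompose (mu_by_arm, sigma_by_arm) from sequential-regression parameters.
# `coefs` is a list parallel to ss$regs with elements beta, s2.
recompose_mvn <- function(ss, coefs) {
  arms <- ss$arms
  J <- ss$J
  mu <- stats::setNames(lapply(arms, function(a) numeric(J)), arms)
  if (ss$pooling == "common") {
    sigma <- matrix(0, J, J)
    for (j in seq_len(J)) {
      cf <- coefs[[paste0("v", j)]]
      alpha <- cf$beta[seq_along(arms)]
      b <- if (j > 1L) cf$beta[-seq_along(arms)] else numeric(0)
      for (ai in seq_along(arms)) {
        a <- arms[ai]
        mu[[a]][j] <- alpha[ai] +
          if (j > 1L) sum(b * mu[[a]][seq_len(j - 1L)]) else 0
      }
      if (j == 1L) {
        sigma[1L, 1L] <- cf$s2
      } else {
        Sh <- sigma[seq_len(j - 1L), seq_len(j - 1L), drop = FALSE]
        cross <- as.numeric(Sh %*% b)
        sigma[seq_len(j - 1L), j] <- cross
        sigma[j, seq_len(j - 1L)] <- cross
        sigma[j, j] <- cf$s2 + sum(b * cross)
      }
    }
    sigma_by_arm <- stats::setNames(rep(list(sigma), length(arms)), arms)
  } else {
    sigma_by_arm <- stats::setNames(vector("list", length(arms)), arms)
    for (a in arms) {
      sigma <- matrix(0, J, J)
      for (j in seq_len(J)) {
        cf <- coefs[[paste0(a, ".v", j)]]
        alpha <- cf$beta[1L]
        b <- if (j > 1L) cf$beta[-1L] else numeric(0)
        mu[[a]][j] <- alpha +
          if (j > 1L) sum(b * mu[[a]][seq_len(j - 1L)]) else 0
        if (j == 1L) {
          sigma[1L, 1L] <- cf$s2
        } else {
          Sh <- sigma[seq_len(j - 1L), seq_len(j - 1L), drop = FALSE]
          cross <- as.numeric(Sh %*% b)
          sigma[seq_len(j - 1L), j] <- cross
          sigma[j, seq_len(j - 1L)] <- cross
          sigma[j, j] <- cf$s2 + sum(b * cross)
        }
      }
      sigma_by_arm[[a]] <- sigma
    }
  }
  list(mu = mu, sigma = sigma_by_arm)
}

#' Maximum-likelihood multivariate-normal fit under monotone missingness
#'
#' Fits per-arm mean vectors and the covariance matrix of the `J` repeated
#' outcomes by maximum likelihood, using the exact factorization of the
#' monotone likelihood into sequential normal linear regressions (visit `j`
#' regressed on visits `1..j-1`, fitted to the patients observed at visit
#' `j`). Residual variances use the maximum-likelihood divisor `n` (not
#' `n - 1`).
#'
#' With `pooling = "common"` (the default) the covariance matrix is pooled
#' across arms: slopes and residual variances are shared and only the visit
#' intercepts are arm specific. With `pooling = "separate"` each arm gets
#' its own mean vector and covariance matrix.
#'
#' @param data a `trial_data` object (monotone, validated).
#' @param pooling `"common"` or `"separate"` covariance across arms.
#' @return An object of class `mvn_params`: list with `mu` (named list of
#'   `J`-vectors per arm), `sigma` (named list of `JxJ` matrices per arm;
#'   identical entries when pooled), `pooling`, `J` and `n_by_arm`.
#' @export
fit_mle_monotone <- function(data, pooling = c("common", "separate")) {
  pooling <- match.arg(pooling)
  ss <- monotone_suffstats(data, pooling)
  coefs <- lapply(ss$regs, function(r)
    list(beta = r$beta, s2 = r$rss / r$n))  # ML divisor n
  out <- recompose_mvn(ss, coefs)
  structure(list(mu = out$mu, sigma = out$sigma, pooling = pooling,
                 J = ss$J, n_by_arm = ss$n_by_arm),
            class = "mvn_params")
}

#' @export
print.mvn_params <- function(x, ...) {
  cat("mvn_params (pooling = ", x$pooling, ")\n", sep = "")
  for (a in names(x$mu))
    cat("  mu[", a, "] = (", paste(signif(x$mu[[a]], 4), collapse = ", "),
        ")\n", sep = "")
  cat("  sigma diag = (",
      paste(signif(diag(x$sigma[[1L]]), 4), collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Proper-imputation posterior draws of the imputation-model parameters
#'
#' Draws `K` independent samples of the per-arm means and covariance matrix
#' from their exact Bayesian posterior under the monotone factorization
#' with the Jeffreys prior on each sequential regression: for visit `j`
#' with `n_j` cases and `p_j` coefficients, the residual variance is drawn
#' as `RSS_j / chi^2(n_j - p_j)` and the coefficients from their
#' conditional normal `N(beta_hat_j, s2 (X'X)^{-1})`; the joint
#' `(mu, sigma)` is then recomposed from the drawn chain. This is the
#' standard "proper" multiple-imputation posterior for monotone normal
#' data: no MCMC is needed.
#'
#' Draw `k` uses the sub-seed `derive_seed(seed, "draw", k)`, so draws are
#' order-independent and individually reproducible.
#'
#' @param data a `trial_data` object.
#' @param K number of draws (at least 2; Rubin's between-imputation
#'   variance is undefined otherwise).
#' @param pooling covariance pooling, as in [fit_mle_monotone()].
#' @param seed integer root seed.
#' @return list of `K` objects of class `mvn_draw`, each with `mu`,
#'   `sigma` (per-arm lists), `pooling` and `draw_index`.
#' @export
draw_posterior <- function(data, K, pooling = c("common", "separate"),
                           seed) {
  pooling <- match.arg(pooling)
  if (K < 2L) stop("K must be at least 2 (between-imputation variance undefined)")
  ss <- monotone_suffstats(data, pooling)
  lapply(seq_len(K), function(k) {
    set.seed(derive_seed(seed, "draw", k))
    coefs <- lapply(ss$regs, function(r) {
      s2 <- r$rss / stats::rchisq(1L, df = r$n - r$p)
      beta <- r$beta + sqrt(s2) * as.numeric(r$Rinv %*% stats::rnorm(r$p))
      list(beta = beta, s2 = s2)
    })
    out <- recompose_mvn(ss, coefs)
    structure(list(mu = out$mu, sigma = out$sigma, pooling = pooling,
                   J = ss$J, draw_index = k,
                   rng_state = c(seed = seed, draw = k)),
              class = "mvn_draw")
  })
}

#' Conditional distribution of a Gaussian sub-vector
#'
#' Standard multivariate-normal conditioning: for `Y ~ N(mu, sigma)` with
#' observed coordinates `observed_idx` equal to `observed_values`, the
#' missing block is normal with mean
#' `mu_m + S_mo S_oo^{-1} (y_o - mu_o)` and covariance
#' `S_mm - S_mo S_oo^{-1} S_om`.
#'
#' @param mu mean vector.
#' @param sigma positive-definite covariance matrix.
#' @param observed_idx indices of the observed coordinates (non-empty
#'   proper subset).
#' @param observed_values observed values, same length as `observed_idx`.
#' @return list with `mean` (vector over the missing coordinates, in
#'   increasing index order), `cov` (their conditional covariance) and
#'   `missing_idx`.
#' @examples
#' sigma <- matrix(c(0.4, 0.2, 0.2, 0.6), 2, 2)
#' conditional_normal(c(2.0, 1.9), sigma, 1, 2.0)
#' @export
conditional_normal <- function(mu, sigma, observed_idx, observed_values) {
  J <- length(mu)
  observed_idx <- as.integer(observed_idx)
  if (length(observed_idx) == 0L || length(observed_idx) >= J)
    stop("'observed_idx' must be a non-empty proper subset of coordinates")
  if (length(observed_values) != length(observed_idx))
    stop("'observed_values' must match 'observed_idx' in length")
  miss_idx <- setdiff(seq_len(J), observed_idx)
  cc <- cond_coef(sigma, observed_idx, miss_idx)
  mean_m <- mu[miss_idx] + as.numeric(cc$C %*% (observed_values - mu[observed_idx]))
  list(mean = mean_m, cov = cc$cov, missing_idx = miss_idx)
}

# regression coefficients C = S_mo S_oo^{-1} and conditional covariance,
# shared by conditional_normal() and the vectorized imputation path
cond_coef <- function(sigma, observed_idx, miss_idx) {
  S_oo <- sigma[observed_idx, observed_idx, drop = FALSE]
  S_mo <- sigma[miss_idx, observed_idx, drop = FALSE]
  ok <- tryCatch(chol(S_oo), error = function(e) NULL)
  if (is.null(ok)) stop("observed block of 'sigma' is singular")
  C <- S_mo %*% chol2inv(ok)
  cov <- sigma[miss_idx, miss_idx, drop = FALSE] - C %*% t(S_mo)
  cov <- (cov + t(cov)) / 2
  list(C = C, cov = cov)
}
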