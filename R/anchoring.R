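#' Statistical information about a sample mean in a simple sensitivity
#' analysis
#'
#' For a study intending `n` observations with known variance `sigma2`, of
#' which `n_m` are missing and are assumed (in the sensitivity analysis) to
#' come from a population with the same mean but variance `sigma_m2`:
#' the full-data information about the mean is `n / sigma2`, the
#' observed-data information `(n - n_m) / sigma2`, and the information
#' under the sensitivity analysis (missing values multiply imputed under
#' the heterogeneous-variance assumption, estimator still the mean) is
#' approximately `n^2 / ((n - n_m) sigma2 + n_m sigma_m2)`.
#'
#' @param n intended number of observations.
#' @param n_m number missing, `0 <= n_m < n`.
#' @param sigma2 variance of the observed population (> 0).
#' @param sigma_m2 assumed variance of the unobserved population (> 0).
#' @return list with `I_full`, `I_obs`, `I_sens`.
#' @examples
#' info_simple_mean(100, 20, 1, 2.25)  # I_sens equals I_obs here
#' @export
info_simple_mean <- function(n, n_m, sigma2, sigma_m2) {
  if (sigma2 <= 0 || sigma_m2 <= 0) stop("variances must be positive")
  if (n_m < 0 || n_m >= n) stop("'n_m' must satisfy 0 <= n_m < n")
  list(I_full = n / sigma2,
       I_obs = (n - n_m) / sigma2,
       I_sens = n^2 / ((n - n_m) * sigma2 + n_m * sigma_m2))
}

#' Heterogeneous-variance threshold where sensitivity information equals
#' observed-data information
#'
#' Solves `I_sens(sigma_m2) = I_obs` for `sigma_m2` by root finding on the
#' information function of [info_simple_mean()]. Below the threshold the
#' sensitivity analysis carries more information than the observed data;
#' above it, less.
#'
#' @inheritParams info_simple_mean
#' @return the crossover value of `sigma_m2`.
#' @examples
#' info_crossover_sigma_m2(100, 20, 1)  # 2.25
#' @export
info_crossover_sigma_m2 <- function(n, n_m, sigma2) {
  if (n_m <= 0) stop("'n_m' must be positive for a crossover to exist")
  f <- function(s2m) {
    inf <- info_simple_mean(n, n_m, sigma2, s2m)
    inf$I_sens - inf$I_obs
  }
  upper <- sigma2 * max(10, 4 * n / n_m)
  stats::uniroot(f, c(sigma2 * 1e-6, upper), tol = 1e-12)$root
}

#' Classify a sensitivity analysis as information negative / anchored /
#' positive
#'
#' Compares the proportion of information retained under the primary
#' analysis, `I_obs_primary / I_full_primary`, with the proportion
#' retained under the sensitivity analysis,
#' `I_obs_sensitivity / I_full_sensitivity` (information = inverse
#' variance of the treatment-effect estimator). The analysis is *anchored*
#' when the two ratios agree within relative tolerance `rel_tol`,
#' *negative* when the sensitivity analysis retains proportionally less
#' information, and *positive* when it retains more. The anchoring theory
#' is an approximation, hence the tolerance.
#'
#' @param I_obs_primary,I_full_primary,I_obs_sensitivity,I_full_sensitivity
#'   the four (positive) information values.
#' @param rel_tol relative tolerance for calling the ratios equal
#'   (default 0.05).
#' @return An object of class `information_report`: the four inputs,
#'   `ratio_primary`, `ratio_sensitivity` and `classification` (one of
#'   `"negative"`, `"anchored"`, `"positive"`).
#' @examples
#' classify_information(200, 250, 160, 200)  # equal ratios: anchored
#' @export
classify_information <- function(I_obs_primary, I_full_primary,
                                 I_obs_sensitivity, I_full_sensitivity,
                                 rel_tol = 0.05) {
  vals <- c(I_obs_primary, I_full_primary, I_obs_sensitivity,
            I_full_sensitivity)
  if (any(vals <= 0)) stop("all information values must be positive")
  ratio_p <- I_obs_primary / I_full_primary
  ratio_s <- I_obs_sensitivity / I_full_sensitivity
  rel <- ratio_s / ratio_p - 1
  classification <- if (abs(rel) <= rel_tol) "anchored"
                    else if (rel < 0) "negative" else "positive"
  structure(list(I_obs_primary = I_obs_primary,
                 I_full_primary = I_full_primary,
                 I_obs_sensitivity = I_obs_sensitivity,
                 I_full_sensitivity = I_full_sensitivity,
                 ratio_primary = ratio_p, ratio_sensitivity = ratio_s,
                 rel_tol = rel_tol, classification = classification),
            class = "information_report")
}

#' @export
print.information_report <- function(x, ...) {
  cat("information_report: ", x$classification, "\n", sep = "")
  cat("  primary retains     ", signif(100 * x$ratio_primary, 4),
      "% of full-data information\n", sep = "")
  cat("  sensitivity retains ", signif(100 * x$ratio_sensitivity, 4),
      "% of full-data information (rel_tol ", x$rel_tol, ")\n", sep = "")
  invisible(x)
}

#' Expected full-data variance of the primary treatment-effect estimator
#'
#' For `n` patients per arm with outcome covariance `sigma`, the expected
#' design-based variance of the final-visit treatment effect with complete
#' data is `2 sigma_JJ / n` for the unadjusted difference in means, and
#' `2 sigma_J.1 / n` for the baseline-adjusted (ANCOVA) estimator, where
#' `sigma_J.1 = sigma_JJ - sigma_1J^2 / sigma_11` is the final-visit
#' variance conditional on baseline. The `n - 1 -> n` large-sample
#' convention is used throughout.
#'
#' @param sigma `JxJ` outcome covariance matrix.
#' @param n patients per arm.
#' @param baseline_adjusted `TRUE` for the ANCOVA estimator.
#' @return the expected variance (outcome units squared).
#' @export
expected_full_variance_primary <- function(sigma, n,
                                           baseline_adjusted = TRUE) {
  J <- ncol(sigma)
  s2 <- if (baseline_adjusted)
    sigma[J, J] - sigma[1L, J]^2 / sigma[1L, 1L]
  else sigma[J, J]
  2 * s2 / n
}

#' Expected full-data variance under a controlled deviation scenario
#'
#' If the `n_d,j` deviators at each visit `j` could be observed following
#' the controlled model (post-deviation final-visit mean
#' `mu_dev_final[j]` instead of the on-treatment mean `mu_a_final`), the
#' expected sample variance of the treatment-effect estimator picks up
#' between-pattern mean-heterogeneity terms:
#' \deqn{E[V_{full,sens}] = \frac{2\sigma^2}{n}
#'   + \sum_j \frac{n_o n_{d,j} \Delta_{d,j}^2}{n^3}
#'   + \sum_{p \ne q} \frac{n_{d,p} n_{d,q} \Delta_{d,p,q}^2}{n^3},}
#' with \eqn{\Delta_{d,j} = \mu_{a,J} - \mu_{d,j,J}} and
#' \eqn{\Delta_{d,p,q} = \mu_{d,p,J} - \mu_{d,q,J}}. Both extra terms are
#' sums of squares, so the scenario variance can never fall below the
#' primary full-data variance.
#'
#' @param sigma `JxJ` outcome covariance matrix.
#' @param n patients per arm.
#' @param pattern a [summarize_patterns()] result for the deviating arm
#'   (or a list with `n_complete` and `n_dev`).
#' @param mu_dev_final numeric vector of final-visit means under the
#'   controlled model, one per deviation visit `2..J` (in the order of
#'   `pattern$n_dev`).
#' @param mu_a_final on-treatment final-visit mean.
#' @param baseline_adjusted `TRUE` for the ANCOVA estimator.
#' @return An object of class `theoretical_variances`: list with
#'   `v_full_primary`, `v_full_sensitivity`, the two deviation terms and
#'   the inputs.
#' @export
expected_full_variance_sensitivity <- function(sigma, n, pattern,
                                               mu_dev_final, mu_a_final,
                                               baseline_adjusted = TRUE) {
  n_dev <- pattern$n_dev
  n_o <- pattern$n_complete
  if (length(mu_dev_final) != length(n_dev))
    stop("'mu_dev_final' needs one entry per deviation visit (",
         length(n_dev), ")")
  if (n_o + sum(n_dev) > n)
    stop("pattern counts exceed n")
  base <- expected_full_variance_primary(sigma, n, baseline_adjusted)
  delta_dj <- unname(mu_a_final - mu_dev_final)
  n_dev <- unname(n_dev)
  term_onoff <- sum(n_o * n_dev * delta_dj^2) / n^3
  term_cross <- 0
  m <- length(n_dev)
  if (m > 1L) {
    for (p in seq_len(m)) for (q in seq_len(m)) if (p != q)
      term_cross <- term_cross +
        n_dev[p] * n_dev[q] * (mu_dev_final[p] - mu_dev_final[q])^2
    term_cross <- term_cross / n^3
  }
  structure(list(v_full_primary = base,
                 v_full_sensitivity = base + term_onoff + term_cross,
                 term_completer_deviator = unname(term_onoff),
                 term_between_patterns = unname(term_cross),
                 baseline_adjusted = baseline_adjusted, n = n),
            class = "theoretical_variances")
}

#' @export
print.theoretical_variances <- function(x, ...) {
  cat("theoretical_variances (",
      if (x$baseline_adjusted) "baseline-adjusted" else "unadjusted",
      ", n = ", x$n, " per arm)\n", sep = "")
  cat("  E[V_full,primary]     = ", signif(x$v_full_primary, 5), "\n",
      sep = "")
  cat("  E[V_full,sensitivity] = ", signif(x$v_full_sensitivity, 5), "\n",
      sep = "")
  invisible(x)
}

#' The Q term: full-data variance increase under delta adjustment
#'
#' Under the cumulative delta method (final-visit shift `(J + 1 - j) delta`
#' for deviation at visit `j`) the expected full-data scenario variance is
#' the primary one plus
#' \deqn{Q = \sum_j \frac{n_o n_{d,j} (J+1-j)^2 \delta^2}{n^3}
#'   + \sum_{p \ne q} \frac{n_{d,p} n_{d,q}
#'     \{(J+1-p)\delta - (J+1-q)\delta\}^2}{n^3}.}
#' All terms carry `n^{-2}`-order factors, so `Q` vanishes asymptotically
#' unless `delta` is very large.
#'
#' @param pattern a [summarize_patterns()] result for the deviating arm.
#' @param delta the (fixed) delta adjustment per post-deviation visit.
#' @param J number of visits; defaults to the number implied by `pattern`.
#' @param n patients per arm; defaults to `pattern$n`.
#' @return the value of `Q` (>= 0).
#' @export
delta_Q_term <- function(pattern, delta, J = NULL, n = NULL) {
  if (!is.finite(delta)) stop("'delta' must be finite")
  n_dev <- unname(pattern$n_dev)
  n_o <- pattern$n_complete
  if (is.null(J)) J <- length(n_dev) + 1L
  if (is.null(n)) n <- pattern$n
  js <- 2:J
  shift <- (J + 1 - js) * delta
  q1 <- sum(n_o * n_dev * shift^2) / n^3
  q2 <- 0
  m <- length(js)
  for (p in seq_len(m)) for (q in seq_len(m)) if (p != q)
    q2 <- q2 + n_dev[p] * n_dev[q] * (shift[p] - shift[q])^2
  q1 + q2 / n^3
}

#' The information-anchored variance
#'
#' By definition the anchored variance scales the full-data sensitivity
#' variance by the proportion of information lost in the primary analysis:
#' `(V_obs,primary / V_full,primary) * V_full,sensitivity`. Because the
#' ratio is at least 1, the anchored variance is always at least the
#' variance that would be obtained if the post-deviation data could be
#' observed under the sensitivity scenario.
#'
#' @param v_obs_primary primary-analysis variance on the observed data.
#' @param v_full_primary primary-analysis variance with full data.
#' @param v_full_sensitivity full-data variance under the sensitivity
#'   scenario.
#' @return the anchored variance.
#' @examples
#' anchored_variance(0.006, 0.004, 0.005)  # 0.0075
#' @export
anchored_variance <- function(v_obs_primary, v_full_primary,
                              v_full_sensitivity) {
  if (any(c(v_obs_primary, v_full_primary, v_full_sensitivity) <= 0))
    stop("all variances must be positive")
  if (v_obs_primary < v_full_primary)
    warning("v_obs_primary < v_full_primary: the primary analysis appears ",
            "to gain information from missing data")
  (v_obs_primary / v_full_primary) * v_full_sensitivity
}

#' Leading discrepancy between the anchored variance and Rubin's variance
#'
#' The difference between the information-anchored variance and the
#' expected Rubin's-rules variance is, to leading order, a sum over
#' deviation patterns of
#' `pi_dj^2 * P_j' (V_primary,j - V_sensitivity,j) P_j`, where `P_j` is
#' the pattern's mean history vector (a leading 1 for the imputation-model
#' intercept, then the mean responses at visits `1..j-1`) and
#' `V_primary,j`, `V_sensitivity,j` are the covariance matrices of the
#' imputation-model coefficients under the primary (MAR, fitted to the
#' `n_o` on-treatment completers) and sensitivity assumptions. The
#' coefficient covariance is evaluated as
#' `sigma^2_{J.hist} M_j^{-1} / n_fit`, with `M_j` the moment matrix of
#' `(1, Y_1, ..., Y_{j-1})` and `sigma^2_{J.hist}` the conditional
#' final-visit variance given the history.
#'
#' The scale of the sensitivity fit depends on the method:
#' \describe{
#'   \item{reference_full}{the sensitivity imputation model borrows the
#'     fully observed reference arm, so `n_fit = n` and the contribution is
#'     `pi_dj^2 P_j' sigma^2 M_j^{-1} P_j (1/n_o - 1/n)`, positive and of
#'     order `n^{-2}`.}
#'   \item{reference_subsampled}{the reference arm is subsampled to `n_o`
#'     patients, so the term is exactly 0.}
#'   \item{delta}{a fixed delta shift adds a constant to MAR imputations:
#'     the coefficient covariances are identical and the term is exactly
#'     0.}
#'   \item{delta_random}{drawing `delta_k ~ N(delta, sigma_delta^2)` per
#'     imputation inflates the between-imputation variance, giving a total
#'     of `-pi_d^2 sigma_delta^2`: the analysis is information negative.}
#' }
#'
#' @param sigma `JxJ` outcome covariance matrix.
#' @param pattern a [summarize_patterns()] result for the deviating arm.
#' @param history_means named list mapping each deviation visit `j` (with
#'   `n_dev > 0`) to the vector `c(1, mean(Y_1), ..., mean(Y_{j-1}))`; if
#'   `NULL`, built from `mu`.
#' @param mu mean vector used to build default history means (and the
#'   moment matrices).
#' @param n patients per arm; defaults to `pattern$n`.
#' @param n_o on-treatment completers; defaults to `pattern$n_complete`.
#' @param scale one of `"reference_full"`, `"reference_subsampled"`,
#'   `"delta"`, `"delta_random"`.
#' @param sigma_delta standard deviation of the per-imputation delta draw
#'   (used by `"delta_random"`).
#' @return An object of class `discrepancy_report`: `first_term` (the
#'   total), `per_pattern` contributions, `scale` and a `notes` string
#'   recording that higher-order terms are not evaluated.
#' @export
theorem1_first_term <- function(sigma, pattern, history_means = NULL,
                                mu = NULL, n = NULL, n_o = NULL,
                                scale = c("reference_full",
                                          "reference_subsampled",
                                          "delta", "delta_random"),
                                sigma_delta = 0) {
  scale <- match.arg(scale)
  if (is.null(n)) n <- pattern$n
  if (is.null(n_o)) n_o <- pattern$n_complete
  J <- length(pattern$n_dev) + 1L
  pi_dj <- pattern$n_dev / n
  pi_d <- sum(pi_dj)
  dev_js <- which(pattern$n_dev > 0) + 1L   # deviation visits with mass
  if (length(dev_js) == 0L)
    return(structure(list(first_term = 0, per_pattern = numeric(0),
                          scale = scale, notes = "no deviators"),
                     class = "discrepancy_report"))
  per <- stats::setNames(numeric(length(dev_js)), paste0("visit", dev_js))

  if (scale == "delta_random") {
    if (sigma_delta <= 0)
      stop("'delta_random' requires sigma_delta > 0")
    # total -pi_d^2 sigma_delta^2, split across patterns in proportion pi_dj
    for (i in seq_along(dev_js)) {
      j <- dev_js[i]
      per[i] <- -pi_dj[j - 1L] * pi_d * sigma_delta^2
    }
  } else if (scale %in% c("delta", "reference_subsampled")) {
    per[] <- 0
  } else {
    if (is.null(history_means)) {
      if (is.null(mu))
        stop("supply 'history_means' or 'mu' to build them")
      history_means <- lapply(dev_js, function(j) c(1, mu[seq_len(j - 1L)]))
      names(history_means) <- paste0("visit", dev_js)
    }
    if (is.null(mu)) {
      # recover history means from the P vectors for the moment matrices
      mu <- rep(NA_real_, J)
    }
    for (i in seq_along(dev_js)) {
      j <- dev_js[i]
      P <- history_means[[paste0("visit", dev_js[i])]]
      if (is.null(P)) P <- history_means[[i]]
      if (length(P) != j)
        stop("history mean vector for deviation visit ", j,
             " must have length ", j, " (leading 1 + ", j - 1L,
             " history means)")
      h <- seq_len(j - 1L)
      mu_h <- if (all(is.finite(mu[h]))) mu[h] else P[-1L]
      S_h <- sigma[h, h, drop = FALSE]
      M <- rbind(c(1, mu_h), cbind(mu_h, S_h + tcrossprod(mu_h)))
      s2_cond <- sigma[J, J] -
        sigma[J, h, drop = FALSE] %*% solve(S_h, sigma[h, J])
      quad <- drop(t(P) %*% solve(M, P)) * drop(s2_cond)
      per[i] <- pi_dj[j - 1L]^2 * quad * (1 / n_o - 1 / n)
    }
  }
  structure(list(first_term = sum(per), per_pattern = per, scale = scale,
                 notes = paste("Leading term only; the higher-order",
                               "remainder of the anchored-vs-Rubin",
                               "difference is asymptotically negligible",
                               "and is not evaluated.")),
            class = "discrepancy_report")
}

#' @export
print.discrepancy_report <- function(x, ...) {
  cat("discrepancy_report (", x$scale, "): first term = ",
      signif(x$first_term, 4), "\n", sep = "")
  invisible(x)
}

#' Percentage of information lost beyond the primary analysis
#'
#' Given the standard error of an information-anchored analysis (`se_a`)
#' and of a less precise sensitivity analysis (`se_b`), returns the
#' percentage of the anchored information lost by the second analysis:
#' `(1/se_a^2 - 1/se_b^2) / (1/se_a^2) * 100`.
#'
#' @param se_a anchored (smaller) standard error, > 0.
#' @param se_b comparison (larger) standard error, `se_b >= se_a`.
#' @return the information loss in percent.
#' @examples
#' info_loss_percent(0.072, 0.132)  # about 70
#' @export
info_loss_percent <- function(se_a, se_b) {
  if (se_a <= 0) stop("'se_a' must be positive")
  if (se_b < se_a)
    stop("'se_b' < 'se_a': the comparison analysis gains information")
  (1 / se_a^2 - 1 / se_b^2) / (1 / se_a^2) * 100
}

#' Inflate a treatment estimate to the information-anchored variance
#'
#' The reference-based multiple-imputation point estimator has a long-run
#' (maximum-likelihood) variance `v_ml` smaller than the anchored variance
#' `v_anchored`. Adding one draw from `N(0, v_anchored - v_ml)` to the
#' estimate yields an estimator whose long-run variance is the anchored
#' variance.
#'
#' @param estimate the treatment-effect estimate.
#' @param v_ml its long-run (ML) variance.
#' @param v_anchored the information-anchored variance, `>= v_ml`.
#' @param seed optional seed for the inflation draw.
#' @return the adjusted estimate.
#' @export
inflate_to_anchored <- function(estimate, v_ml, v_anchored, seed = NULL) {
  if (v_anchored < v_ml)
    stop("'v_anchored' must be at least 'v_ml'")
  if (v_anchored == v_ml) return(estimate)
  if (!is.null(seed)) set.seed(seed)
  estimate + stats::rnorm(1L, 0, sqrt(v_anchored - v_ml))
}

#' Per-arm sample size for a two-arm comparison of means
#'
#' The standard formula `n = 2 (z_{1-alpha/2} + z_{power})^2 sigma^2 /
#' Delta^2`, rounded up.
#'
#' @param delta targeted difference in means (non-zero).
#' @param sigma outcome standard deviation.
#' @param alpha two-sided significance level.
#' @param power required power.
#' @return integer patients per arm.
#' @examples
#' sample_size_per_arm(0.23, 0.5, 0.05, 0.80)  # 75
#' @export
sample_size_per_arm <- function(delta, sigma, alpha = 0.05, power = 0.80) {
  if (delta == 0) stop("'delta' must be non-zero")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("'alpha' and 'power' must lie in (0, 1)")
  f <- (stats::qnorm(1 - alpha / 2) + stats::qnorm(power))^2
  as.integer(ceiling(2 * f * sigma^2 / delta^2))
}
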