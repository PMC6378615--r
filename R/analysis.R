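#' Baseline-adjusted treatment-effect analysis (ANCOVA)
#'
#' Ordinary least squares of the outcome at `outcome_visit` on an
#' intercept, the baseline outcome and the treatment indicator (reference
#' arm coded 0, active arm 1, so positive estimates favor the active arm).
#' The variance is the classical homoskedastic OLS estimate and the
#' two-sided p-value comes from the t distribution with `n - 3` degrees of
#' freedom, matching the design-based primary analysis of a longitudinal
#' trial.
#'
#' @param data a complete `trial_data` (e.g. a `completed_trial`).
#' @param outcome_visit visit index analysed (default: the final visit).
#' @param baseline_visit baseline visit index (default 1).
#' @param active_arm,reference_arm arm labels; by default `"active"` /
#'   `"reference"` when present, otherwise they must be supplied.
#' @return An object of class `trial_fit`: list with `estimate`,
#'   `variance`, `se`, `df`, `p_value`, `model`, `n` and the full
#'   coefficient vector.
#' @examples
#' y <- cbind(rnorm(40, 2, 0.5), rnorm(40, 2, 0.5))
#' td <- trial_dataset(paste0("p", 1:40), rep(c("active", "reference"), 20), y)
#' fit_ancova(td)
#' @export
fit_ancova <- function(data, outcome_visit = NULL, baseline_visit = 1L,
                       active_arm = NULL, reference_arm = NULL) {
  roles <- resolve_arms(data, active_arm, reference_arm)
  J <- ncol(data$y)
  if (is.null(outcome_visit)) outcome_visit <- J
  yJ <- data$y[, outcome_visit]
  y1 <- data$y[, baseline_visit]
  if (anyNA(yJ) || anyNA(y1))
    stop("analysis requires complete data at the baseline and outcome visits")
  g <- as.numeric(data$arm == roles$active)
  n <- length(yJ)
  if (n < 4L) stop("too few patients for ANCOVA (need at least 4)")
  if (stats::var(y1) == 0)
    stop("baseline outcome is constant: ANCOVA design is collinear")
  X <- cbind(1, y1, g)
  XtX <- crossprod(X)
  Xty <- crossprod(X, yJ)
  coefs <- tryCatch(drop(solve(XtX, Xty)),
                    error = function(e) stop("collinear ANCOVA design"))
  resid <- yJ - drop(X %*% coefs)
  df <- n - 3L
  s2 <- sum(resid^2) / df
  v <- unname(s2 * solve(XtX)[3L, 3L])
  est <- unname(coefs[3L])
  se <- sqrt(v)
  p <- 2 * stats::pt(-abs(est / se), df)
  structure(list(estimate = est, variance = v, se = se,
                 df = df, p_value = p, model = "ancova", n = n,
                 coefficients = stats::setNames(coefs,
                   c("(Intercept)", "baseline", "treatment"))),
            class = "trial_fit")
}

#' Unadjusted difference in arm means at one visit
#'
#' Difference of arm means (active minus reference) with the pooled
#' two-sample variance estimate
#' `s2_pooled * (1/n_a + 1/n_r)` and `n_a + n_r - 2` degrees of freedom.
#'
#' @inheritParams fit_ancova
#' @return a `trial_fit` with `model = "diff_means"`.
#' @export
fit_diff_means <- function(data, outcome_visit = NULL, active_arm = NULL,
                           reference_arm = NULL) {
  roles <- resolve_arms(data, active_arm, reference_arm)
  if (is.null(outcome_visit)) outcome_visit <- ncol(data$y)
  yJ <- data$y[, outcome_visit]
  if (anyNA(yJ)) stop("analysis requires complete data at the outcome visit")
  ya <- yJ[data$arm == roles$active]
  yr <- yJ[data$arm == roles$reference]
  if (length(ya) < 2L || length(yr) < 2L)
    stop("each arm needs at least 2 patients")
  na <- length(ya); nr <- length(yr)
  s2 <- ((na - 1) * stats::var(ya) + (nr - 1) * stats::var(yr)) / (na + nr - 2)
  est <- mean(ya) - mean(yr)
  v <- s2 * (1 / na + 1 / nr)
  df <- na + nr - 2L
  se <- sqrt(v)
  p <- 2 * stats::pt(-abs(est / se), df)
  structure(list(estimate = est, variance = v, se = se, df = df,
                 p_value = p, model = "diff_means", n = na + nr),
            class = "trial_fit")
}

resolve_arms <- function(data, active_arm, reference_arm) {
  arms <- unique(data$arm)
  if (length(arms) != 2L)
    stop("analysis requires exactly two arms; found: ",
         paste(arms, collapse = ", "))
  if (is.null(active_arm))
    active_arm <- if ("active" %in% arms) "active" else
      stop("specify 'active_arm' (no arm is labelled \"active\")")
  if (!active_arm %in% arms) stop("unknown active arm '", active_arm, "'")
  if (is.null(reference_arm)) reference_arm <- setdiff(arms, active_arm)
  if (!reference_arm %in% arms)
    stop("unknown reference arm '", reference_arm, "'")
  list(active = active_arm, reference = reference_arm)
}

#' @export
print.trial_fit <- function(x, ...) {
  cat("trial_fit (", x$model, "): estimate = ", signif(x$estimate, 4),
      ", se = ", signif(x$se, 4), ", df = ", x$df,
      ", p = ", signif(x$p_value, 3), "\n", sep = "")
  invisible(x)
}
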