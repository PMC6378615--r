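#' Pool per-imputation analyses by Rubin's rules
#'
#' Combines `K` analyses of multiply imputed datasets: the pooled estimate
#' is the mean of the per-imputation estimates, the within-imputation
#' variance `W` the mean of the per-imputation variances, the
#' between-imputation variance `B` the sample variance (divisor `K - 1`)
#' of the estimates, and the total variance `V = W + (1 + 1/K) B`.
#' Degrees of freedom use the Barnard-Rubin small-sample adjustment with
#' the analysis model's complete-data degrees of freedom; when `B = 0`
#' (identical analyses, no missing information) the complete-data degrees
#' of freedom are returned unchanged.
#'
#' @param results list of `K >= 2` [fit_ancova()] / [fit_diff_means()]
#'   results from the same model.
#' @param df_complete complete-data degrees of freedom; defaults to the
#'   per-imputation `df`.
#' @return An object of class `pooled_result`: list with `estimate`, `W`,
#'   `B`, `V`, `se`, `df`, `p_value`, `lambda` (fraction of missing
#'   information, `(1 + 1/K) B / V`) and `K`.
#' @examples
#' f <- list(
#'   structure(list(estimate = 0.1, variance = 0.004, df = 97,
#'                  model = "ancova"), class = "trial_fit"),
#'   structure(list(estimate = 0.3, variance = 0.004, df = 97,
#'                  model = "ancova"), class = "trial_fit"))
#' pool(f)
#' @export
pool <- function(results, df_complete = NULL) {
  K <- length(results)
  if (K < 2L) stop("Rubin's rules require K >= 2 analyses")
  models <- vapply(results, function(r) r$model, character(1))
  if (length(unique(models)) != 1L)
    stop("all results must come from the same analysis model")
  ests <- vapply(results, function(r) r$estimate, numeric(1))
  vars <- vapply(results, function(r) r$variance, numeric(1))
  if (is.null(df_complete)) df_complete <- results[[1L]]$df
  est <- mean(ests)
  W <- mean(vars)
  B <- stats::var(ests)
  V <- W + (1 + 1 / K) * B
  lambda <- if (V > 0) (1 + 1 / K) * B / V else 0
  if (B <= 0 || lambda <= 0) {
    df <- df_complete
    lambda <- 0
  } else {
    nu_old <- (K - 1) / lambda^2
    nu_obs <- (df_complete + 1) / (df_complete + 3) * df_complete *
      (1 - lambda)
    df <- 1 / (1 / nu_old + 1 / nu_obs)
  }
  se <- sqrt(V)
  p <- 2 * stats::pt(-abs(est / se), df)
  structure(list(estimate = est, W = W, B = B, V = V, se = se, df = df,
                 p_value = p, lambda = lambda, K = K,
                 model = models[[1L]]),
            class = "pooled_result")
}

#' @export
print.pooled_result <- function(x, ...) {
  cat("pooled_result (", x$model, ", K = ", x$K, ")\n", sep = "")
  cat("  estimate = ", signif(x$estimate, 4), ", se = ", signif(x$se, 4),
      ", df = ", signif(x$df, 4), ", p = ", signif(x$p_value, 3), "\n",
      sep = "")
  cat("  W = ", signif(x$W, 4), ", B = ", signif(x$B, 4), ", V = ",
      signif(x$V, 4), ", lambda = ", signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}

#' Relative efficiency of K imputations
#'
#' The variance of a pooled estimate based on `K` imputations relative to
#' one based on infinitely many is approximately `1 + lambda / K`, where
#' `lambda` is the fraction of missing information.
#'
#' @param lambda fraction of missing information, in `[0, 1)`.
#' @param K number of imputations, `K >= 1`.
#' @return the relative efficiency `1 + lambda / K`.
#' @examples
#' relative_efficiency(0.3, 50)
#' @export
relative_efficiency <- function(lambda, K) {
  if (lambda < 0 || lambda >= 1) stop("'lambda' must lie in [0, 1)")
  if (K < 1L) stop("'K' must be at least 1")
  1 + lambda / K
}
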