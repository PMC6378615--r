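#' Configuration for the simulation engine
#'
#' Defaults emulate a chronic-asthma trial with FEV1 (litres) recorded at
#' baseline and two follow-up visits: per-arm multivariate-normal outcomes
#' with means `mu_reference = (2.0, 1.95, 1.9)` and
#' `mu_active = (2.0, 2.21, 2.2)` (final-visit treatment effect 0.3),
#' common covariance with diagonal `(0.4, 0.5, 0.6)`, `n = 250` patients
#' per arm, monotone completely-at-random dropout confined to the active
#' arm and split across the deviation visits, `K = 50` imputations and
#' 1000 replicates. Tests and desk-scale runs reduce `n_reps` and `K`.
#'
#' @param n_per_arm patients per arm.
#' @param mu_reference,mu_active per-arm mean vectors (equal length `J`).
#' @param sigma `JxJ` positive-definite covariance matrix, common to both
#'   arms.
#' @param dropout overall proportion of active-arm patients deviating.
#' @param K imputations per analysis.
#' @param n_reps simulation replicates.
#' @param methods default method list for [run_study()]; method names or
#'   [imputation_spec()] objects.
#' @param seed root seed.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_per_arm = 250L,
                       mu_reference = c(2.0, 1.95, 1.9),
                       mu_active = c(2.0, 2.21, 2.2),
                       sigma = matrix(c(0.4, 0.2, 0.2,
                                        0.2, 0.5, 0.2,
                                        0.2, 0.2, 0.6), 3L, 3L),
                       dropout = 0.3,
                       K = 50L,
                       n_reps = 1000L,
                       methods = c("MAR", "J2R", "CIR", "CR", "LMCF"),
                       seed = 1L) {
  if (length(mu_reference) != length(mu_active))
    stop("'mu_reference' and 'mu_active' must have equal length")
  J <- length(mu_reference)
  if (!all(dim(sigma) == c(J, J))) stop("'sigma' must be ", J, "x", J)
  if (max(abs(sigma - t(sigma))) > 1e-10) stop("'sigma' must be symmetric")
  ok <- tryCatch({ chol(sigma); TRUE }, error = function(e) FALSE)
  if (!ok) stop("'sigma' must be positive definite")
  if (dropout < 0 || dropout >= 1) stop("'dropout' must lie in [0, 1)")
  if (dropout > 0.5)
    warning("dropout above 50%: the information-anchoring approximation ",
            "degrades at such extreme deviation proportions")
  structure(list(n_per_arm = as.integer(n_per_arm),
                 mu_reference = mu_reference, mu_active = mu_active,
                 sigma = sigma, J = J, dropout = dropout,
                 K = as.integer(K), n_reps = as.integer(n_reps),
                 methods = methods, seed = as.integer(seed)),
            class = "sim_config")
}

# true parameters wrapped as a parameter object usable wherever an
# mvn_draw is expected (imputation at known parameters)
true_params <- function(config) {
  structure(list(mu = list(active = config$mu_active,
                           reference = config$mu_reference),
                 sigma = list(active = config$sigma,
                              reference = config$sigma),
                 pooling = "common", J = config$J, draw_index = NA_integer_),
            class = "mvn_draw")
}

#' Generate one complete trial
#'
#' Draws `n_per_arm` patients per arm from the arm's multivariate-normal
#' outcome distribution; no missing cells. Arms are labelled `"active"`
#' and `"reference"`.
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return a complete `trial_data`.
#' @export
generate_complete_trial <- function(config, seed) {
  set.seed(seed)
  n <- config$n_per_arm
  ya <- MASS::mvrnorm(n, config$mu_active, config$sigma)
  yr <- MASS::mvrnorm(n, config$mu_reference, config$sigma)
  trial_dataset(id = c(sprintf("a%04d", seq_len(n)),
                       sprintf("r%04d", seq_len(n))),
                arm = rep(c("active", "reference"), each = n),
                y = rbind(ya, yr))
}

#' Impose monotone completely-at-random dropout
#'
#' Deletes post-deviation data for a fraction `pi_total` of the patients
#' in `arm` (default the active arm; the reference arm stays fully
#' observed). Deviators are chosen uniformly without replacement and split
#' as evenly as possible across the deviation visits `2..J`, with earlier
#' visits taking the remainder: for `J = 3`, `ceiling(pi n / 2)` patients
#' lose visits 2 and 3 and `floor(pi n / 2)` lose visit 3 only. The exact
#' deterministic split (rather than a binomial draw) keeps the pattern
#' counts reproducible.
#'
#' @param data a complete `trial_data`.
#' @param pi_total overall deviation proportion in `[0, 1)`.
#' @param seed integer seed for the deviator selection.
#' @param arm the arm subject to dropout.
#' @return a `trial_data` with monotone missingness.
#' @export
impose_mcar_monotone_dropout <- function(data, pi_total, seed,
                                         arm = "active") {
  stopifnot(inherits(data, "trial_data"))
  if (pi_total < 0 || pi_total >= 1) stop("'pi_total' must lie in [0, 1)")
  if (pi_total == 0) return(data)
  J <- ncol(data$y)
  idx <- which(data$arm == arm)
  n <- length(idx)
  if (n == 0L) stop("no patients in arm '", arm, "'")
  m <- J - 1L                       # number of deviation visits
  total <- round(pi_total * n)
  base <- floor(pi_total * n / m)
  counts <- rep(base, m)
  rem <- total - base * m
  if (rem > 0L) counts[seq_len(rem)] <- counts[seq_len(rem)] + 1L
  if (total >= n)
    stop("dropout proportion leaves no completers in arm '", arm, "'")
  set.seed(seed)
  chosen <- sample(idx, total)
  y <- data$y
  pos <- 0L
  for (k in seq_len(m)) {
    j <- k + 1L                     # deviation visit
    if (counts[k] == 0L) next
    rows <- chosen[pos + seq_len(counts[k])]
    y[rows, j:J] <- NA_real_
    pos <- pos + counts[k]
  }
  trial_dataset(data$id, data$arm, y, data$visit_labels)
}

#' Draw the post-deviation data under the controlled scenario
#'
#' Given an incomplete dataset (deviation = first missing visit), fills
#' the post-deviation cells with draws from the conditional distribution
#' of the controlled model evaluated at the *true* generating parameters:
#' joint mean from [build_joint_mean()] under the scenario, covariance
#' `sigma`, conditioned on the patient's observed pre-deviation history.
#' This produces the "complete scenario-specific dataset" whose analysis
#' variance is the full-data sensitivity variance. For the `DELTA`
#' scenario the fixed shift `spec$delta` is added to the drawn
#' post-deviation values.
#'
#' @param data a `trial_data` with monotone missingness.
#' @param config the [sim_config()] holding the true parameters.
#' @param spec an [imputation_spec()] naming the scenario.
#' @param seed integer seed.
#' @return a complete `trial_data`.
#' @export
generate_full_sensitivity_data <- function(data, config, spec, seed) {
  tp <- true_params(config)
  comp <- impute_once(data, tp, spec, seed = seed)
  if (spec$method == "DELTA")
    comp <- apply_delta(comp, spec, delta_k = spec$delta)
  comp
}

# normalize a methods entry (name or spec) to an imputation_spec + label
as_method_spec <- function(x, K) {
  if (inherits(x, "imputation_spec")) {
    spec <- x
    spec$K <- as.integer(K)
    label <- if (spec$method == "DELTA") {
      if (spec$delta_sd > 0)
        sprintf("delta%g~sd%g", spec$delta, spec$delta_sd)
      else sprintf("delta%g", spec$delta)
    } else spec$method
  } else {
    spec <- imputation_spec(as.character(x), reference_arm = "reference",
                            K = K)
    label <- spec$method
  }
  list(spec = spec, label = label)
}

#' Run one simulation replicate
#'
#' Generates a complete trial, imposes dropout, and for each requested
#' method computes the four variance summaries that characterize
#' information anchoring:
#' \describe{
#'   \item{v_rubin}{Rubin's-rules total variance of the controlled
#'     multiple-imputation analysis (K imputations).}
#'   \item{v_anchored}{`(V_obs,primary / V_full,primary) *
#'     V_full,sensitivity`, using the replicate's own complete dataset for
#'     the full-data primary fit and its scenario-complete dataset for the
#'     sensitivity fit.}
#'   \item{v_primary_est}{the primary analysis-model (classical ANCOVA)
#'     variance estimator averaged over the K imputed datasets.}
#'   \item{v_full_sensitivity}{the ANCOVA variance on the
#'     scenario-complete dataset.}
#' }
#' `V_obs,primary` is the Rubin variance of the MAR analysis of the
#' observed data. All methods share the same generated data, deviation
#' pattern and MAR posterior draws, which mirrors pairing the scenarios on
#' common datasets to reduce Monte-Carlo noise.
#'
#' @param config a [sim_config()].
#' @param methods method names or [imputation_spec()] objects.
#' @param seed integer replicate seed.
#' @param dropout deviation proportion (defaults to `config$dropout`).
#' @return a data.frame with one row per method.
#' @export
run_replicate <- function(config, methods = config$methods, seed,
                          dropout = config$dropout) {
  K <- config$K
  specs <- lapply(methods, as_method_spec, K = K)
  complete <- generate_complete_trial(config, derive_seed(seed, "gen"))
  observed <- impose_mcar_monotone_dropout(complete, dropout,
                                           derive_seed(seed, "drop"))
  full_fit <- fit_ancova(complete)
  v_full_primary <- full_fit$variance
  has_missing <- anyNA(observed$y)

  mar_spec <- imputation_spec("MAR", reference_arm = "reference", K = K)
  if (has_missing) {
    draws <- draw_posterior(observed, K, "common", derive_seed(seed, "post"))
    mar_sets <- lapply(seq_len(K), function(k)
      impute_once(observed, draws[[k]], mar_spec,
                  seed = derive_seed(seed, "imp", "MAR", k)))
    mar_fits <- lapply(mar_sets, fit_ancova)
    mar_pool <- pool(mar_fits)
    v_obs_primary <- mar_pool$V
  } else {
    draws <- NULL
    mar_sets <- NULL
    mar_fits <- list(full_fit)
    v_obs_primary <- v_full_primary
  }

  rows <- lapply(specs, function(ms) {
    spec <- ms$spec
    if (!has_missing) {
      v <- v_full_primary
      return(data.frame(method = ms$label, dropout = dropout,
                        estimate = full_fit$estimate, v_rubin = v,
                        v_anchored = v, v_primary_est = v,
                        v_full_sensitivity = v,
                        v_full_primary = v, v_obs_primary = v,
                        stringsAsFactors = FALSE))
    }
    fits <- if (spec$method == "MAR") {
      mar_fits
    } else if (spec$method == "DELTA") {
      lapply(seq_len(K), function(k) {
        shifted <- apply_delta(mar_sets[[k]], spec,
                               seed = derive_seed(seed, "delta", ms$label, k))
        fit_ancova(shifted)
      })
    } else {
      lapply(seq_len(K), function(k) {
        comp <- impute_once(observed, draws[[k]], spec,
                            seed = derive_seed(seed, "imp", ms$label, k))
        fit_ancova(comp)
      })
    }
    pooled <- pool(fits)
    sens_full <- generate_full_sensitivity_data(
      observed, config, spec, seed = derive_seed(seed, "sens", ms$label))
    fs_fit <- fit_ancova(sens_full)
    data.frame(method = ms$label, dropout = dropout,
               estimate = pooled$estimate, v_rubin = pooled$V,
               v_anchored = anchored_variance(v_obs_primary, v_full_primary,
                                              fs_fit$variance),
               v_primary_est = pooled$W,
               v_full_sensitivity = fs_fit$variance,
               v_full_primary = v_full_primary,
               v_obs_primary = v_obs_primary,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Run the full simulation study
#'
#' Loops [run_replicate()] over a grid of deviation proportions, sharing
#' data generation within a replicate across methods, and aggregates the
#' four variance summaries per (dropout, method) cell with their
#' Monte-Carlo standard errors.
#'
#' @param config a [sim_config()].
#' @param dropout_grid vector of deviation proportions.
#' @param methods method names or [imputation_spec()] objects.
#' @param n_reps replicates per grid point.
#' @param out optional path; when given, the per-replicate table is
#'   written there as CSV and the summary next to it (`*_summary.csv`).
#' @return An object of class `sim_study`: list with `replicates` (tidy
#'   per-replicate data.frame) and `summary` (per-cell means and MC
#'   standard errors).
#' @export
run_study <- function(config, dropout_grid = config$dropout,
                      methods = config$methods,
                      n_reps = config$n_reps, out = NULL) {
  reps <- vector("list", length(dropout_grid) * n_reps)
  pos <- 0L
  for (gi in seq_along(dropout_grid)) {
    pi_d <- dropout_grid[gi]
    for (r in seq_len(n_reps)) {
      pos <- pos + 1L
      reps[[pos]] <- run_replicate(
        config, methods,
        seed = derive_seed(config$seed, "rep", gi, r),
        dropout = pi_d)
      reps[[pos]]$rep <- r
    }
  }
  replicates <- do.call(rbind, reps)
  agg_cols <- c("estimate", "v_rubin", "v_anchored", "v_primary_est",
                "v_full_sensitivity", "v_full_primary", "v_obs_primary")
  key <- interaction(replicates$dropout, replicates$method, drop = TRUE)
  summ <- do.call(rbind, lapply(split(replicates, key), function(d) {
    row <- data.frame(dropout = d$dropout[1L], method = d$method[1L],
                      n_reps = nrow(d), stringsAsFactors = FALSE)
    for (cn in agg_cols) {
      row[[paste0("mean_", cn)]] <- mean(d[[cn]])
      row[[paste0("mcse_", cn)]] <- stats::sd(d[[cn]]) / sqrt(nrow(d))
    }
    # empirical sampling variance of the pooled point estimate: the
    # long-run variance an ML/delta-method analysis would target, which
    # shrinks with the deviation proportion under reference-based methods
    row$var_estimate <- stats::var(d$estimate)
    row
  }))
  rownames(summ) <- NULL
  summ <- summ[order(summ$method, summ$dropout), ]
  if (!is.null(out)) {
    utils::write.csv(replicates, out, row.names = FALSE)
    utils::write.csv(summ, sub("(\\.csv)?$", "_summary.csv", out),
                     row.names = FALSE)
  }
  structure(list(replicates = replicates, summary = summ, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", nrow(x$replicates), "replicate rows,",
      nrow(x$summary), "summary cells\n")
  print(x$summary[, c("dropout", "method", "mean_v_rubin",
                      "mean_v_anchored", "mean_v_primary_est",
                      "mean_v_full_sensitivity")], digits = 4)
  invisible(x)
}

#' Empirical power of the full-data primary analysis
#'
#' Fraction of replicates in which the full-data ANCOVA two-sided p-value
#' falls below `alpha`. With a null treatment effect this estimates the
#' type-I error rate.
#'
#' @param config a [sim_config()].
#' @param n_reps replicates (defaults to `config$n_reps`).
#' @param alpha significance level.
#' @return the rejection fraction in `[0, 1]`.
#' @export
estimate_power <- function(config, n_reps = config$n_reps, alpha = 0.05) {
  rej <- vapply(seq_len(n_reps), function(r) {
    d <- generate_complete_trial(config, derive_seed(config$seed, "pow", r))
    fit_ancova(d)$p_value < alpha
  }, logical(1))
  mean(rej)
}
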