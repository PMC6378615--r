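#' Specify a controlled multiple-imputation method
#'
#' Bundles the assumptions under which missing post-deviation data are
#' imputed. Available methods:
#' \describe{
#'   \item{MAR}{randomized-arm missing at random (the usual primary
#'     analysis).}
#'   \item{J2R}{jump to reference: post-deviation means equal the reference
#'     arm's means; pre-deviation means come from the randomized arm.}
#'   \item{CIR}{copy increments in reference: post-deviation means follow
#'     the reference arm's mean increments from the randomized-arm mean at
#'     the last pre-deviation visit.}
#'   \item{CR}{copy reference: the patient's whole joint distribution is
#'     taken from the reference arm; the conditional given the observed
#'     history is therefore also the reference arm's.}
#'   \item{LMCF}{last mean carried forward: post-deviation means frozen at
#'     the randomized arm's mean at the last observed visit.}
#'   \item{DELTA}{impute under randomized-arm MAR, then shift imputed
#'     values by a delta adjustment (see [apply_delta()]).}
#' }
#'
#' For `DELTA`, `delta_sd = 0` gives a fixed shift of `delta`;
#' `delta_sd > 0` draws one `delta_k ~ N(delta, delta_sd^2)` per imputation
#' (the elicited-prior variant, which is information negative).
#' `delta_mode = "cumulative"` shifts the visit-`k` imputation of a
#' patient deviating at visit `j` by `(k - j + 1) * delta_k`, so the shift
#' accumulates by `delta_k` per post-deviation visit; `"per_visit"` applies
#' `delta_k` at every post-deviation visit.
#'
#' @param method one of `"MAR"`, `"J2R"`, `"CIR"`, `"CR"`, `"LMCF"`,
#'   `"DELTA"`.
#' @param reference_arm label of the reference arm.
#' @param delta,delta_sd,delta_mode delta-adjustment parameters (outcome
#'   units); ignored by non-DELTA methods.
#' @param delta_arms arms whose imputed values receive the delta shift
#'   (`NULL` = all arms).
#' @param subsample_reference if `TRUE`, each imputation fits its
#'   imputation model on a random subset of the reference arm of the same
#'   size as the active-arm completers, which sharpens information
#'   anchoring when the deviation proportion is very large.
#' @param K number of imputations (at least 2).
#' @return an object of class `imputation_spec`.
#' @examples
#' imputation_spec("J2R", reference_arm = "reference", K = 50)
#' imputation_spec("DELTA", reference_arm = "reference", delta = -0.21,
#'                 delta_sd = 0.46)
#' @export
imputation_spec <- function(method = c("MAR", "J2R", "CIR", "CR", "LMCF",
                                       "DELTA"),
                            reference_arm = "reference",
                            delta = 0, delta_sd = 0,
                            delta_mode = c("cumulative", "per_visit"),
                            delta_arms = NULL,
                            subsample_reference = FALSE,
                            K = 50L) {
  method <- match.arg(method)
  delta_mode <- match.arg(delta_mode)
  if (K < 2L) stop("K must be at least 2")
  if (method == "DELTA" && !is.finite(delta))
    stop("DELTA imputation requires a finite 'delta'")
  if (delta_sd < 0) stop("'delta_sd' must be >= 0")
  structure(list(method = method, reference_arm = reference_arm,
                 delta = delta, delta_sd = delta_sd,
                 delta_mode = delta_mode, delta_arms = delta_arms,
                 subsample_reference = isTRUE(subsample_reference),
                 K = as.integer(K)),
            class = "imputation_spec")
}

#' @export
print.imputation_spec <- function(x, ...) {
  cat("imputation_spec: method =", x$method,
      "| reference arm =", x$reference_arm, "| K =", x$K, "\n")
  if (x$method == "DELTA")
    cat("  delta =", x$delta, "sd =", x$delta_sd, "mode =", x$delta_mode, "\n")
  invisible(x)
}

reference_based_methods <- c("J2R", "CIR", "CR", "LMCF")

#' Joint mean vector of the controlled model for one deviation pattern
#'
#' For a patient in `arm` who deviates at visit `dev_visit` (their first
#' missing visit), returns the `J`-vector of means of the controlled joint
#' distribution used for imputation. Pre-deviation means always come from
#' the randomized arm except under copy reference, where the whole profile
#' is the reference arm's. Deviating patients in the reference arm itself
#' are imputed under within-arm MAR for the reference-based methods.
#'
#' @param spec an [imputation_spec()].
#' @param draw an `mvn_draw` (or `mvn_params`) supplying the per-arm means.
#' @param arm the patient's randomized arm.
#' @param dev_visit first missing visit `j`, with `2 <= j <= J`.
#' @return numeric `J`-vector of means.
#' @export
build_joint_mean <- function(spec, draw, arm, dev_visit) {
  J <- draw$J
  j <- as.integer(dev_visit)
  if (j < 2L || j > J) stop("'dev_visit' must lie in 2..J")
  if (spec$method %in% reference_based_methods &&
      identical(draw$pooling, "separate"))
    stop("reference-based methods require a common (pooled) covariance; ",
         "refit with pooling = \"common\"")
  mu_z <- draw$mu[[arm]]
  if (is.null(mu_z)) stop("arm '", arm, "' not present in the parameter draw")
  method <- spec$method
  if (arm == spec$reference_arm && method %in% reference_based_methods)
    method <- "MAR"  # within-arm MAR for deviators in the reference arm
  if (method %in% c("MAR", "DELTA")) return(mu_z)
  mu_r <- draw$mu[[spec$reference_arm]]
  if (is.null(mu_r))
    stop("reference arm '", spec$reference_arm, "' not present in the draw")
  post <- j:J
  m <- mu_z
  switch(method,
    J2R = { m[post] <- mu_r[post] },
    CIR = { m[post] <- mu_z[j - 1L] + (mu_r[post] - mu_r[j - 1L]) },
    LMCF = { m[post] <- mu_z[j - 1L] },
    CR = { m <- mu_r }
  )
  m
}

#' Impute one completed dataset under a controlled assumption
#'
#' For each patient with missing visits (first missing visit `j`), the
#' missing block `j..J` is drawn from the conditional normal distribution
#' of the controlled joint model: mean vector from [build_joint_mean()],
#' covariance from the parameter draw, conditioned on the patient's
#' observed history `1..j-1`. Observed cells are never modified. For the
#' `DELTA` method the draw is under randomized-arm MAR; the delta shift is
#' applied separately by [apply_delta()] (or automatically by
#' [impute_all()]).
#'
#' @param data a `trial_data` object (monotone).
#' @param draw an `mvn_draw` from [draw_posterior()] (or `mvn_params` for
#'   imputation at fixed known parameters).
#' @param spec an [imputation_spec()].
#' @param seed optional integer seed for the imputation noise.
#' @return a completed `trial_data` with attributes `imputed` (logical
#'   mask of imputed cells), `method` and `draw_index`.
#' @export
impute_once <- function(data, draw, spec, seed = NULL) {
  stopifnot(inherits(data, "trial_data"))
  if (!is.null(seed)) set.seed(seed)
  y <- data$y
  J <- ncol(y)
  mask <- is.na(y)
  if (any(mask)) {
    fm <- first_missing_visit(data)
    for (arm in unique(data$arm[!is.na(fm)])) {
      sigma <- draw$sigma[[arm]]
      for (j in sort(unique(fm[data$arm == arm & !is.na(fm)]))) {
        rows <- which(data$arm == arm & !is.na(fm) & fm == j)
        hist_idx <- seq_len(j - 1L)
        miss_idx <- j:J
        m <- build_joint_mean(spec, draw, arm, j)
        cc <- cond_coef(sigma, hist_idx, miss_idx)
        H <- y[rows, hist_idx, drop = FALSE]
        dev <- sweep(H, 2L, m[hist_idx]) %*% t(cc$C)
        mean_m <- sweep(dev, 2L, m[miss_idx], `+`)
        U <- chol(cc$cov)
        noise <- matrix(stats::rnorm(length(rows) * length(miss_idx)),
                        nrow = length(rows)) %*% U
        y[rows, miss_idx] <- mean_m + noise
      }
    }
  }
  # observed cells untouched and all NA filled: rebuild without revalidating
  out <- structure(list(id = data$id, arm = data$arm, y = y,
                        visit_labels = data$visit_labels),
                   class = c("completed_trial", "trial_data"))
  attr(out, "imputed") <- mask
  attr(out, "method") <- spec$method
  attr(out, "draw_index") <- draw$draw_index
  out
}

#' Delta-adjust the imputed values of one completed dataset
#'
#' Applies the delta shift of the `DELTA` method to a dataset already
#' imputed under randomized-arm MAR. With `delta_mode = "cumulative"`, the
#' imputed value at visit `k >= j` of a patient deviating at visit `j` is
#' shifted by `(k - j + 1) * delta_k`, so the final visit of a patient
#' deviating at visit `j` receives `(J + 1 - j) * delta_k`. With
#' `"per_visit"`, every post-deviation visit is shifted by `delta_k`.
#' `delta_k` equals `spec$delta` when `spec$delta_sd == 0`; otherwise one
#' draw from `N(delta, delta_sd^2)` is taken for the whole dataset (i.e.
#' per imputation). Only imputed cells are modified.
#'
#' @param completed a `completed_trial` from [impute_once()].
#' @param spec an [imputation_spec()] with `method = "DELTA"`.
#' @param seed optional seed for the random-delta draw.
#' @param delta_k override the shift (used internally).
#' @return the shifted `completed_trial`; the applied `delta_k` is stored
#'   as attribute `delta_k`.
#' @export
apply_delta <- function(completed, spec, seed = NULL, delta_k = NULL) {
  if (!identical(spec$method, "DELTA"))
    stop("apply_delta() requires an imputation_spec with method = \"DELTA\"")
  mask <- attr(completed, "imputed")
  if (is.null(mask)) stop("'completed' carries no imputed-cell mask")
  if (is.null(delta_k)) {
    if (spec$delta_sd > 0) {
      if (!is.null(seed)) set.seed(seed)
      delta_k <- stats::rnorm(1L, spec$delta, spec$delta_sd)
    } else {
      delta_k <- spec$delta
    }
  }
  y <- completed$y
  J <- ncol(y)
  rows <- which(rowSums(mask) > 0L)
  if (!is.null(spec$delta_arms))
    rows <- rows[completed$arm[rows] %in% spec$delta_arms]
  for (i in rows) {
    j <- which(mask[i, ])[1L]
    ks <- j:J
    shift <- if (spec$delta_mode == "cumulative") (ks - j + 1) * delta_k
             else rep(delta_k, length(ks))
    y[i, ks] <- y[i, ks] + shift
  }
  out <- completed
  out$y <- y
  attr(out, "delta_k") <- delta_k
  out
}

#' Run a full controlled multiple imputation
#'
#' Composes [draw_posterior()], [impute_once()] and (for `DELTA`)
#' [apply_delta()]: draws `K` parameter samples from the exact monotone
#' posterior, imputes one completed dataset per draw under the controlled
#' assumption, and returns the `K` completed datasets. Reproducible from
#' the root `seed` via [derive_seed()] sub-streams.
#'
#' With `spec$subsample_reference = TRUE`, each imputation's parameter draw
#' is based on a dataset in which the reference arm is randomly subsampled
#' to the number of completers in the non-reference arm, which equalizes
#' the precision of the primary and sensitivity imputation models.
#'
#' @param data a `trial_data` object.
#' @param spec an [imputation_spec()].
#' @param seed integer root seed.
#' @param pooling covariance pooling for the imputation model; the
#'   reference-based methods require `"common"`.
#' @return list of `K` `completed_trial` objects, of class `mi_set`, with
#'   the spec and seed attached as attributes.
#' @export
impute_all <- function(data, spec, seed, pooling = c("common", "separate")) {
  pooling <- match.arg(pooling)
  if (spec$method %in% reference_based_methods && pooling != "common")
    stop("reference-based methods require pooling = \"common\"")
  K <- spec$K
  if (spec$subsample_reference) {
    non_ref <- setdiff(unique(data$arm), spec$reference_arm)
    n_keep <- min(vapply(non_ref, function(a)
      summarize_patterns(data, a)$n_complete, numeric(1)))
    ref_rows <- which(data$arm == spec$reference_arm)
    draws <- lapply(seq_len(K), function(k) {
      set.seed(derive_seed(seed, "subsample", k))
      keep <- sort(c(which(data$arm != spec$reference_arm),
                     sample(ref_rows, min(n_keep, length(ref_rows)))))
      sub <- trial_dataset(data$id[keep], data$arm[keep],
                           data$y[keep, , drop = FALSE], data$visit_labels)
      draw_posterior(sub, 2L, pooling, derive_seed(seed, "sub-draw", k))[[1L]]
    })
  } else {
    draws <- draw_posterior(data, K, pooling, seed)
  }
  out <- lapply(seq_len(K), function(k) {
    comp <- impute_once(data, draws[[k]], spec,
                        seed = derive_seed(seed, "impute", k))
    attr(comp, "draw_index") <- k
    if (spec$method == "DELTA")
      comp <- apply_delta(comp, spec, seed = derive_seed(seed, "delta", k))
    comp
  })
  attr(out, "spec") <- spec
  attr(out, "seed") <- seed
  class(out) <- "mi_set"
  out
}

#' @export
print.mi_set <- function(x, ...) {
  spec <- attr(x, "spec")
  cat("mi_set:", length(x), "completed datasets, method", spec$method, "\n")
  invisible(x)
}

#' Export an imputation set as a stacked CSV
#'
#' One row per patient per imputation, columns `imputation, id, arm,
#' y1..yJ` plus one `imputed_<visit>` flag column per visit.
#'
#' @param imputations an `mi_set` from [impute_all()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_imputations_csv <- function(imputations, path) {
  rows <- lapply(seq_along(imputations), function(k) {
    d <- imputations[[k]]
    mask <- attr(d, "imputed")
    flags <- as.data.frame(mask * 1L)
    names(flags) <- paste0("imputed_", d$visit_labels)
    cbind(data.frame(imputation = k, id = d$id, arm = d$arm,
                     stringsAsFactors = FALSE),
          as.data.frame(d$y), flags)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
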