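#' Construct a longitudinal trial dataset
#'
#' A `trial_data` object holds wide-format longitudinal outcomes for a
#' randomized trial: one row per patient, one column per scheduled visit,
#' with visit 1 the baseline. Missing outcome cells are `NA`. The object is
#' validated on construction: the baseline must be observed for every
#' patient and post-baseline missingness must be monotone (once a visit is
#' missed, all later visits are missed). Intermittent missingness is
#' rejected because the sequential-regression imputation posterior is exact
#' only for monotone patterns.
#'
#' @param id character vector of unique patient identifiers.
#' @param arm character vector of arm labels, one per patient.
#' @param y numeric matrix, `n` patients by `J >= 2` visits; `NA` marks a
#'   missing outcome.
#' @param visit_labels character vector of `J` visit labels; defaults to
#'   `y1..yJ`.
#' @return An object of class `trial_data`: a list with elements `id`,
#'   `arm`, `y` (the outcome matrix with `visit_labels` as column names)
#'   and `visit_labels`.
#' @examples
#' y <- rbind(c(2.0, 1.9, 1.8), c(2.1, NA, NA))
#' td <- trial_dataset(c("p1", "p2"), c("active", "reference"), y)
#' td
#' @export
trial_dataset <- function(id, arm, y, visit_labels = NULL) {
  if (!is.matrix(y)) y <- as.matrix(y)
  storage.mode(y) <- "double"
  n <- nrow(y)
  J <- ncol(y)
  if (J < 2L) stop("at least two visits (baseline + one follow-up) are required")
  if (length(id) != n || length(arm) != n)
    stop("'id' and 'arm' must have one entry per row of 'y'")
  id <- as.character(id)
  arm <- as.character(arm)
  if (anyDuplicated(id)) stop("patient identifiers must be unique")
  if (anyNA(arm) || any(!nzchar(arm))) stop("every patient needs an arm label")
  if (is.null(visit_labels)) visit_labels <- paste0("y", seq_len(J))
  if (length(visit_labels) != J) stop("'visit_labels' must have one label per visit")
  colnames(y) <- visit_labels
  rownames(y) <- NULL

  miss_base <- is.na(y[, 1L])
  if (any(miss_base))
    stop("baseline (visit 1) missing for patient(s): ",
         paste(id[miss_base], collapse = ", "))
  # monotone: no observed cell may follow a missing one
  obs <- !is.na(y)
  bad <- rowSums(obs[, -1L, drop = FALSE] & !obs[, -J, drop = FALSE]) > 0L
  if (any(bad))
    stop("non-monotone missingness (observed value after a missing visit) ",
         "for patient(s): ", paste(id[bad], collapse = ", "))

  structure(list(id = id, arm = arm, y = y, visit_labels = visit_labels),
            class = "trial_data")
}

#' @export
print.trial_data <- function(x, ...) {
  J <- ncol(x$y)
  cat("trial_data: ", nrow(x$y), " patients, ", J, " visits (",
      paste(x$visit_labels, collapse = ", "), ")\n", sep = "")
  for (a in sort(unique(x$arm))) {
    idx <- x$arm == a
    nmiss <- sum(is.na(x$y[idx, , drop = FALSE]))
    cat("  arm ", a, ": n = ", sum(idx), ", missing cells = ", nmiss, "\n",
        sep = "")
  }
  invisible(x)
}

#' @export
dim.trial_data <- function(x) dim(x$y)

#' Number of visits in a trial dataset
#' @param data a `trial_data` object.
#' @return integer number of scheduled visits (including baseline).
#' @export
n_visits <- function(data) ncol(data$y)

# first missing visit per patient; NA_integer_ for completers
# (monotone, so the first missing visit is one past the observed count)
first_missing_visit <- function(data) {
  n_obs <- rowSums(!is.na(data$y))
  fm <- n_obs + 1L
  fm[n_obs == ncol(data$y)] <- NA_integer_
  as.integer(fm)
}

#' Summarize monotone deviation patterns for one arm
#'
#' Counts, for the requested arm, the completers (`n_complete`) and the
#' patients whose first missing visit is `j`, for `j = 2..J`, together with
#' the corresponding proportions. The deviation visit is defined as the
#' first missing visit.
#'
#' @param data a `trial_data` object.
#' @param arm arm label to summarize.
#' @return An object of class `pattern_summary`: a list with `arm`, `n`,
#'   `n_complete`, `n_dev` (named integer vector over visits `2..J`),
#'   `prop_dev` (same shape, `n_dev / n`) and `prop_total` (overall
#'   deviation proportion).
#' @examples
#' y <- rbind(c(2, 2, 2), c(2, NA, NA), c(2, 2, NA))
#' td <- trial_dataset(paste0("p", 1:3), rep("active", 3), y)
#' summarize_patterns(td, "active")
#' @export
summarize_patterns <- function(data, arm) {
  stopifnot(inherits(data, "trial_data"))
  idx <- data$arm == arm
  if (!any(idx)) stop("no patients in arm '", arm, "'")
  J <- ncol(data$y)
  fm <- first_missing_visit(data)[idx]
  n <- sum(idx)
  n_dev <- vapply(2:J, function(j) sum(fm == j, na.rm = TRUE), integer(1))
  names(n_dev) <- paste0("visit", 2:J)
  out <- list(arm = arm, n = n, n_complete = sum(is.na(fm)),
              n_dev = n_dev, prop_dev = n_dev / n,
              prop_total = sum(n_dev) / n)
  class(out) <- "pattern_summary"
  out
}

#' @export
print.pattern_summary <- function(x, ...) {
  cat("pattern_summary for arm '", x$arm, "': n = ", x$n,
      ", completers = ", x$n_complete, "\n", sep = "")
  cat("  first missing visit: ",
      paste(sprintf("%s=%d", names(x$n_dev), x$n_dev), collapse = ", "),
      " (total deviation proportion ", signif(x$prop_total, 3), ")\n",
      sep = "")
  invisible(x)
}

#' Read a wide-format trial CSV
#'
#' Expects columns `id`, `arm` and `J` outcome columns (by default every
#' column other than `id` and `arm`, in file order). Missing outcomes may
#' be empty cells or the `na_token`. Numeric parsing is locale-independent
#' (decimal point only).
#'
#' @param path path to the CSV file.
#' @param id_col,arm_col names of the identifier and arm columns.
#' @param outcome_cols character vector of outcome column names in visit
#'   order, or `NULL` to use all remaining columns.
#' @param na_token string also treated as missing (besides the empty cell).
#' @return a validated [trial_dataset()].
#' @export
read_trial_csv <- function(path, id_col = "id", arm_col = "arm",
                           outcome_cols = NULL, na_token = "NA") {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, na.strings = NULL)
  for (col in c(id_col, arm_col))
    if (!col %in% names(raw)) stop("column '", col, "' not found in ", path)
  if (is.null(outcome_cols))
    outcome_cols <- setdiff(names(raw), c(id_col, arm_col))
  missing_cols <- setdiff(outcome_cols, names(raw))
  if (length(missing_cols))
    stop("outcome column(s) not found: ", paste(missing_cols, collapse = ", "))
  if (length(outcome_cols) < 2L)
    stop("need at least two outcome columns (baseline + one follow-up)")

  y <- matrix(NA_real_, nrow(raw), length(outcome_cols))
  for (k in seq_along(outcome_cols)) {
    cell <- raw[[outcome_cols[k]]]
    empty <- is.na(cell) | cell == "" | cell == na_token
    val <- suppressWarnings(as.numeric(cell))
    bad <- !empty & is.na(val)
    if (any(bad))
      stop("non-numeric outcome '", cell[bad][1L], "' in column '",
           outcome_cols[k], "' for patient ", raw[[id_col]][bad][1L])
    val[empty] <- NA_real_
    y[, k] <- val
  }
  trial_dataset(raw[[id_col]], raw[[arm_col]], y,
                visit_labels = outcome_cols)
}

#' Write a trial dataset as wide-format CSV
#'
#' Inverse of [read_trial_csv()] on its own output: missing cells are
#' written as the configured token (empty by default) and observed cells in
#' plain decimal notation.
#'
#' @param data a `trial_data` object.
#' @param path output path.
#' @param na_token string written for missing cells.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(data, path, na_token = "") {
  stopifnot(inherits(data, "trial_data"))
  cells <- apply(data$y, 2L, function(col) {
    out <- vapply(col, function(v)
      if (is.na(v)) na_token
      else format(v, digits = 15, scientific = FALSE, trim = TRUE),
      character(1))
    out
  })
  df <- data.frame(id = data$id, arm = data$arm, cells,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("id", "arm", data$visit_labels)
  utils::write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
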