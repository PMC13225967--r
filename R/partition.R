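# Calibration/prediction partitioning: deterministic Kennard-Stone maximin
# selection, stratified by cultivar with largest-remainder allocation, plus
# the descriptive tools used on the reference values (Tukey outlier flags,
# independent two-sample t test).

#' Kennard-Stone maximin selection
#'
#' Deterministic selection of `k` representative rows: seed with the two
#' mutually farthest rows (Euclidean distance), then repeatedly add the row
#' whose minimum distance to the already-selected set is largest. Ties are
#' broken by the lowest row index. There is no randomness, so the same matrix
#' always yields the same selection.
#'
#' @param X numeric matrix (rows = samples); must be finite.
#' @param k number of rows to select, `2 <= k <= nrow(X)`.
#' @return integer vector of selected row indices, in selection order.
#' @export
kennard_stone <- function(X, k) {
  X <- as_spectral_matrix(X)
  n <- nrow(X)
  if (k < 2 || k > n) abort_config("`k` must be between 2 and nrow(X).")
  check_finite_or_abort(X, "kennard_stone")
  D <- as.matrix(stats::dist(X))
  dimnames(D) <- NULL
  # farthest pair; which.max scans column-major so ties resolve to the
  # lowest-index pair deterministically
  ij <- arrayInd(which.max(D), dim(D))
  sel <- sort(c(ij[1], ij[2]))
  if (k == 2) return(sel)
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- which.max(mind)          # first index wins ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  sel
}

#' Stratified Kennard-Stone calibration/prediction split
#'
#' The global calibration size is the nearest integer to
#' `n * ratio / (ratio + 1)`; it is allocated to the strata proportionally by
#' the largest-remainder rule (so the nominal global size is guaranteed
#' regardless of stratum sizes), and Kennard-Stone then runs inside each
#' stratum on its spectra. With n = 183 and a 3:1 ratio this yields 137
#' calibration and 46 prediction samples.
#'
#' @param X samples x frequency matrix (the distance space; typically the
#'   valid-band absorption spectra), rows aligned with `table`.
#' @param table sample table with a `sample_id` column and the stratum column.
#' @param ratio calibration:prediction ratio (default 3, i.e. 3:1).
#' @param strata name of the stratum column in `table` (default
#'   `"cultivar"`).
#' @return object of class `thz_split`: list with `assignment` (tibble
#'   `sample_id`, `stratum`, `set`), `calibration_ids`, `prediction_ids`,
#'   `n_cal`, `n_pred`, `ratio`.
#' @export
stratified_split <- function(X, table, ratio = 3, strata = "cultivar") {
  X <- as_spectral_matrix(X)
  stopifnot(nrow(X) == nrow(table))
  if (!strata %in% names(table)) {
    abort_config(sprintf("stratum column '%s' not found in the sample table.", strata))
  }
  lab <- as.character(table[[strata]])
  n <- nrow(X)
  n_cal <- round(n * ratio / (ratio + 1))
  levels_ <- unique(lab)
  sizes <- vapply(levels_, function(l) sum(lab == l), integer(1))
  if (any(sizes < 2)) {
    abort_config("every stratum needs at least 2 samples for Kennard-Stone.")
  }
  quota <- n_cal * sizes / n
  k_s <- floor(quota)
  left <- n_cal - sum(k_s)
  if (left > 0) {
    extra <- order(quota - k_s, decreasing = TRUE)[seq_len(left)]  # ties: label order
    k_s[extra] <- k_s[extra] + 1
  }
  if (any(k_s < 2)) {
    abort_config("largest-remainder allocation left a stratum with fewer than 2 calibration samples; Kennard-Stone is undefined there.")
  }
  cal_idx <- integer(0)
  for (j in seq_along(levels_)) {
    rows <- which(lab == levels_[j])
    sel <- kennard_stone(X[rows, , drop = FALSE], k_s[j])
    cal_idx <- c(cal_idx, rows[sel])
  }
  set <- rep("prediction", n)
  set[cal_idx] <- "calibration"
  assignment <- tibble::tibble(
    sample_id = table$sample_id, stratum = lab, set = set
  )
  structure(
    list(assignment = assignment,
         calibration_ids = table$sample_id[set == "calibration"],
         prediction_ids = table$sample_id[set == "prediction"],
         n_cal = sum(set == "calibration"),
         n_pred = sum(set == "prediction"),
         ratio = ratio),
    class = "thz_split"
  )
}

#' @export
print.thz_split <- function(x, ...) {
  cat(sprintf("<thz_split> %d calibration / %d prediction (ratio %s:1)\n",
              x$n_cal, x$n_pred, format(x$ratio)))
  invisible(x)
}

#' Tukey outlier flags
#'
#' Flags values outside `[Q1 - k IQR, Q3 + k IQR]` with quartiles by linear
#' interpolation (quantile type 7). Flagged samples are identified, not
#' removed -- retaining high-ash flours keeps the model trained on the full
#' milling variability.
#'
#' @param y numeric vector, length >= 4.
#' @param k fence multiplier (default 1.5).
#' @return logical vector of flags.
#' @export
tukey_outliers <- function(y, k = 1.5) {
  if (length(y) < 4) abort_config("need at least 4 values for Tukey fences.")
  q <- stats::quantile(y, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2] - q[1]
  y < q[1] - k * iqr | y > q[2] + k * iqr
}

#' Independent two-sample t test
#'
#' Two-sided independent-samples t statistic and p value, pooled variance by
#' default (Welch available via `var_equal = FALSE`).
#'
#' @param y1,y2 numeric vectors (each length >= 2).
#' @param var_equal pool the variances (default TRUE).
#' @return tibble with `t`, `df`, `p`, `mean1`, `mean2`.
#' @export
two_sample_t <- function(y1, y2, var_equal = TRUE) {
  if (length(y1) < 2 || length(y2) < 2) {
    abort_config("both groups need at least 2 observations.")
  }
  if (stats::var(y1) == 0 && stats::var(y2) == 0) {
    abort_config("zero variance in both groups: the t statistic is undefined.")
  }
  ht <- stats::t.test(y1, y2, var.equal = var_equal)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter),
    p = ht$p.value, mean1 = mean(y1), mean2 = mean(y2)
  )
}
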