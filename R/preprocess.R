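# Spectral preprocessing operators: Savitzky-Golay smoothing and derivatives,
# standard normal variate, multiplicative scatter correction, and the
# non-finite diagnostics that gate model fitting.
#
# All operators act row-wise (one spectrum per row) and are therefore
# row-independent by construction.

# Savitzky-Golay weight matrix. Row j holds the convolution weights producing
# the (deriv-th derivative of the) local least-squares polynomial at point j.
# Edges use the window truncated to the available points, with the polynomial
# order reduced when fewer points than coefficients remain.
sg_weight_matrix <- function(p, window, polyorder, deriv = 0, x = NULL) {
  if (window %% 2 == 0) abort_config("`window` must be odd.")
  if (polyorder >= window) abort_config("`polyorder` must be below `window`.")
  if (deriv > polyorder) abort_config("derivative order must not exceed `polyorder`.")
  if (window > p) abort_config("`window` exceeds the number of spectral points.")
  if (is.null(x)) x <- seq_len(p)
  half <- window %/% 2
  W <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- max(1L, j - half):min(p, j + half)
    ord <- min(polyorder, length(idx) - 1L)
    if (deriv > ord) next                    # derivative inestimable at this edge
    V <- outer(x[idx] - x[j], 0:ord, `^`)
    A <- solve(crossprod(V), t(V))
    W[j, idx] <- factorial(deriv) * A[deriv + 1L, ]
  }
  W
}

#' Savitzky-Golay smoothing
#'
#' Per-spectrum local least-squares polynomial smoothing. With `window = 3`
#' and `polyorder = 1` the interior is exactly a 3-point moving average (the
#' usual "3-point average" smoother); with `polyorder = 2` a 3-point window
#' would reproduce the data exactly. Edges are handled by fitting on the
#' window truncated to the available points.
#'
#' @param X samples x frequency matrix (or data frame) of spectra.
#' @param window odd window length (points).
#' @param polyorder polynomial order, below `window`.
#' @param x optional abscissa (frequency axis); defaults to the point index.
#' @return smoothed matrix of the same shape.
#' @export
sg_smooth <- function(X, window = 3, polyorder = 1, x = NULL) {
  X <- as_spectral_matrix(X)
  W <- sg_weight_matrix(ncol(X), window, polyorder, deriv = 0, x = x)
  out <- X %*% t(W)
  dimnames(out) <- dimnames(X)
  out
}

#' Savitzky-Golay derivative
#'
#' Derivative of the local least-squares polynomial with respect to the
#' frequency axis, so the output is in per-THz units when `x` is a THz axis.
#' Removes additive baselines (order 1) or both baseline and linear drift
#' (order 2).
#'
#' @inheritParams sg_smooth
#' @param order derivative order, 1 or 2.
#' @export
sg_derivative <- function(X, order = 1, window = 5, polyorder = 2, x = NULL) {
  if (!order %in% c(1, 2)) abort_config("`order` must be 1 or 2.")
  if (polyorder < order) abort_config("`polyorder` must be >= the derivative order.")
  X <- as_spectral_matrix(X)
  W <- sg_weight_matrix(ncol(X), window, polyorder, deriv = order, x = x)
  out <- X %*% t(W)
  dimnames(out) <- dimnames(X)
  out
}

#' Standard normal variate transform
#'
#' Each spectrum is centered and scaled by its own standard deviation. A
#' spectrum with (near-)zero variance would be divided by zero; such rows are
#' reported in the diagnostics with their non-finite output retained, so the
#' failure is explicit rather than silently propagated into a model.
#'
#' @param X samples x frequency matrix of spectra.
#' @return list with `values` (transformed matrix) and `diagnostics`
#'   (tibble `row`, `sample_id`, `sd`, one row per degenerate spectrum).
#' @export
snv <- function(X) {
  X <- as_spectral_matrix(X)
  if (ncol(X) < 2) abort_config("SNV needs at least 2 spectral points.")
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  out <- (X - mu) / sdv
  bad <- which(sdv < 1e-12 | !is.finite(sdv))
  diagnostics <- tibble::tibble(
    row = bad,
    sample_id = (rownames(X) %||% as.character(seq_len(nrow(X))))[bad],
    sd = sdv[bad]
  )
  list(values = out, diagnostics = diagnostics)
}

#' Multiplicative scatter correction
#'
#' Each spectrum x is regressed on a reference spectrum by ordinary least
#' squares, x ~ a + b * reference, and corrected to (x - a) / b. The
#' reference defaults to the mean spectrum of `X`; when correcting a held-out
#' set, pass the calibration-set mean explicitly so no prediction-set
#' statistic leaks in.
#'
#' @param X samples x frequency matrix of spectra.
#' @param reference reference spectrum (defaults to `colMeans(X)`).
#' @return list with `values` and `diagnostics` (rows with |b| < 1e-12, left
#'   non-finite in the output).
#' @export
msc <- function(X, reference = NULL) {
  X <- as_spectral_matrix(X)
  if (is.null(reference)) reference <- colMeans(X)
  if (length(reference) != ncol(X)) {
    abort_config("`reference` must match the number of spectral points.")
  }
  rc <- reference - mean(reference)
  ss <- sum(rc^2)
  b <- as.vector((X - rowMeans(X)) %*% rc) / ss
  a <- rowMeans(X) - b * mean(reference)
  out <- (X - a) / b
  bad <- which(abs(b) < 1e-12 | !is.finite(b))
  diagnostics <- tibble::tibble(
    row = bad,
    sample_id = (rownames(X) %||% as.character(seq_len(nrow(X))))[bad],
    b = b[bad]
  )
  list(values = out, diagnostics = diagnostics)
}

#' Report non-finite entries of a matrix
#'
#' Model fitters in this package refuse any feature matrix whose report is
#' non-empty, turning silent NaN propagation (the classic SNV/second-
#' derivative failure on noise-dominated spectra) into an explicit error.
#'
#' @param X numeric matrix.
#' @return tibble with columns `row`, `col`, `value` for every non-finite
#'   entry (zero rows when the matrix is clean).
#' @export
assert_finite <- function(X) {
  X <- as_spectral_matrix(X)
  idx <- which(!is.finite(X), arr.ind = TRUE)
  tibble::tibble(
    row = as.integer(idx[, 1]),
    col = as.integer(idx[, 2]),
    value = X[idx]
  )
}

#' Preprocessing specification
#'
#' @param method one of `"none"`, `"SG"`, `"D1"`, `"D2"`, `"SNV"`, `"MSC"`.
#' @param sg_window,sg_polyorder Savitzky-Golay smoothing parameters
#'   (defaults 3 and 1: the 3-point moving average).
#' @param deriv_window,deriv_polyorder parameters for the D1/D2 derivatives.
#' @param msc_reference optional fixed MSC reference spectrum; when `NULL`
#'   the calibration-set mean is used and frozen for the prediction set.
#' @return object of class `preprocess_spec`.
#' @export
preprocess_spec <- function(method = c("none", "SG", "D1", "D2", "SNV", "MSC"),
                            sg_window = 3, sg_polyorder = 1,
                            deriv_window = 5, deriv_polyorder = 2,
                            msc_reference = NULL) {
  method <- match.arg(method)
  if (sg_window %% 2 == 0 || deriv_window %% 2 == 0) {
    abort_config("Savitzky-Golay windows must be odd.")
  }
  structure(
    list(method = method, sg_window = sg_window, sg_polyorder = sg_polyorder,
         deriv_window = deriv_window, deriv_polyorder = deriv_polyorder,
         msc_reference = msc_reference),
    class = "preprocess_spec"
  )
}

#' Apply a preprocessing specification to calibration and prediction spectra
#'
#' All statistics a method needs (currently only the MSC reference) are
#' computed from the calibration rows and applied frozen to the prediction
#' rows, respecting the hold-out-first discipline.
#'
#' @param spec a [preprocess_spec()].
#' @param X_cal calibration spectra (samples x frequency).
#' @param X_pred optional prediction spectra.
#' @param x frequency axis for the derivative operators.
#' @return list with `cal`, `pred` (or NULL) and `diagnostics` (tibble of
#'   degenerate rows across both sets, empty when clean).
#' @export
apply_preprocess <- function(spec, X_cal, X_pred = NULL, x = NULL) {
  stopifnot(inherits(spec, "preprocess_spec"))
  empty <- tibble::tibble(row = integer(), sample_id = character())
  run <- function(X, ref) {
    switch(spec$method,
      none = list(values = as_spectral_matrix(X), diagnostics = empty),
      SG   = list(values = sg_smooth(X, spec$sg_window, spec$sg_polyorder, x = x),
                  diagnostics = empty),
      D1   = list(values = sg_derivative(X, 1, spec$deriv_window, spec$deriv_polyorder, x = x),
                  diagnostics = empty),
      D2   = list(values = sg_derivative(X, 2, spec$deriv_window, spec$deriv_polyorder, x = x),
                  diagnostics = empty),
      SNV  = snv(X),
      MSC  = msc(X, reference = ref)
    )
  }
  ref <- spec$msc_reference %||% colMeans(as_spectral_matrix(X_cal))
  cal <- run(X_cal, ref)
  pred <- if (!is.null(X_pred)) run(X_pred, ref) else NULL
  diagnostics <- dplyr::bind_rows(
    dplyr::mutate(cal$diagnostics, set = "calibration"),
    if (!is.null(pred)) dplyr::mutate(pred$diagnostics, set = "prediction")
  )
  list(cal = cal$values, pred = pred$values, diagnostics = diagnostics)
}
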