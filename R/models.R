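# Regression frameworks: PLSR (NIPALS PLS1, latent variables by RMSECV), MLR
# (ordinary least squares, restricted to low-dimensional well-conditioned
# feature sets), PCR (components by cumulative explained variance), and
# RBF-kernel SVR with a power-of-two grid search, plus the shared
# cross-validation engine.

#' Cross-validation specification
#'
#' @param folds number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(folds = 10, seed = 1) {
  if (folds < 2) abort_config("`folds` must be at least 2.")
  structure(list(folds = as.integer(folds), seed = as.integer(seed)),
            class = "cv_spec")
}

make_folds <- function(n, folds, seed) {
  if (folds > n) abort_config("`folds` must not exceed the number of samples.")
  withr::with_seed(seed, sample(rep_len(seq_len(folds), n)))
}

# ---- PLS1 core (NIPALS) ----------------------------------------------------
# Column-centered X, centered y; returns the regression-coefficient path for
# 1..ncomp components so cross-validation can score every component count from
# a single fit. y-deflation is omitted (single response).
pls1_fit <- function(X, y, ncomp) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar); yc <- y - ybar
  ncomp <- min(ncomp, p, n - 1)
  W <- P <- matrix(0, p, ncomp)
  qv <- numeric(ncomp)
  a <- 0L
  for (k in seq_len(ncomp)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break                       # X fully deflated
    w <- w / nw
    tt <- drop(Xc %*% w)
    t2 <- sum(tt^2)
    if (t2 < 1e-24) break
    pk <- drop(crossprod(Xc, tt)) / t2
    qv[k] <- sum(yc * tt) / t2
    Xc <- Xc - tcrossprod(tt, pk)
    W[, k] <- w; P[, k] <- pk
    a <- k
  }
  if (a == 0L) {
    return(list(ncomp = 0L, B = matrix(0, p, 1), intercepts = ybar,
                xbar = xbar, ybar = ybar))
  }
  W <- W[, seq_len(a), drop = FALSE]
  P <- P[, seq_len(a), drop = FALSE]
  qv <- qv[seq_len(a)]
  R <- W %*% solve(crossprod(P, W))             # projection to original space
  Bsteps <- sweep(R, 2, qv, `*`)
  B <- Bsteps
  if (a > 1) B <- t(apply(Bsteps, 1, cumsum))   # coefficient path, p x a
  if (is.null(dim(B))) B <- matrix(B, nrow = 1) # p == 1 edge case
  intercepts <- ybar - drop(crossprod(xbar, B))
  list(ncomp = a, B = B, intercepts = intercepts, xbar = xbar, ybar = ybar)
}

pls1_predict_path <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (fit$ncomp == 0L) {
    return(matrix(fit$ybar, nrow(Xnew), 1))
  }
  sweep(Xnew %*% fit$B, 2, fit$intercepts, `+`)
}

# k-fold RMSECV of PLS1 for every component count 1..max_lv (shared by the
# selectors and fit_plsr). Folds with a truncated component path reuse their
# deepest available component for the missing columns.
pls_cv <- function(X, y, max_lv, fold_id) {
  X <- as.matrix(X)
  n <- length(y)
  max_lv <- max(1L, min(max_lv, ncol(X), n - 2L))
  preds <- matrix(NA_real_, n, max_lv)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    fit <- pls1_fit(X[!te, , drop = FALSE], y[!te], max_lv)
    ph <- pls1_predict_path(fit, X[te, , drop = FALSE])
    a <- max(1L, fit$ncomp)
    take <- pmin(seq_len(max_lv), ncol(ph))
    preds[te, ] <- ph[, take, drop = FALSE]
  }
  rmsecv <- sqrt(colMeans((y - preds)^2))
  list(rmsecv = rmsecv, best_lv = which.min(rmsecv), min = min(rmsecv),
       predictions = preds)
}

# ---- model matrix helper ---------------------------------------------------
model_newdata <- function(object, newdata) {
  X <- as_spectral_matrix(newdata)
  vars <- object$variables
  if (!is.null(vars) && !is.null(colnames(X))) {
    missing <- setdiff(vars, colnames(X))
    if (length(missing) > 0) {
      rlang::abort(sprintf("newdata is missing model variables: %s",
                           paste(missing, collapse = ", ")),
                   class = "thzash_missing_vars")
    }
    X <- X[, vars, drop = FALSE]
  } else if (ncol(X) != length(object$coefficients %||% vars)) {
    if (!is.null(vars) && ncol(X) != length(vars)) {
      rlang::abort("newdata has the wrong number of variables.",
                   class = "thzash_missing_vars")
    }
  }
  X
}

# ---- PLSR ------------------------------------------------------------------

#' Fit a PLS1 regression with cross-validated latent-variable count
#'
#' NIPALS partial least squares on column-centered data (no unit-variance
#' scaling: absorption spectra share units). The number of latent variables is
#' the minimiser of the k-fold RMSECV over `1..max_lv`; the full RMSECV trace
#' is kept on the fitted object.
#'
#' @param X calibration spectra (samples x variables).
#' @param y response (% ash).
#' @param max_lv largest latent-variable count searched.
#' @param cv a [cv_spec()].
#' @return object of class `thz_plsr`.
#' @export
fit_plsr <- function(X, y, max_lv = 10, cv = cv_spec()) {
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "fit_plsr")
  n <- nrow(X)
  if (n <= cv$folds) abort_config("need more samples than folds.")
  fold_id <- make_folds(n, cv$folds, cv$seed)
  cvres <- pls_cv(X, y, max_lv, fold_id)
  n_lv <- cvres$best_lv
  fit <- pls1_fit(X, y, n_lv)
  coefs <- fit$B[, fit$ncomp]
  structure(
    list(method = "PLSR", coefficients = coefs,
         intercept = fit$intercepts[fit$ncomp],
         n_lv = fit$ncomp, rmsecv_by_lv = cvres$rmsecv,
         rmsecv = cvres$min, cv_predictions = cvres$predictions[, n_lv],
         centering = fit$xbar, y_mean = fit$ybar,
         variables = colnames(X), cv = cv,
         fitted = drop(X %*% coefs) + fit$intercepts[fit$ncomp]),
    class = c("thz_plsr", "thz_model")
  )
}

#' @export
predict.thz_plsr <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  drop(X %*% object$coefficients) + object$intercept
}

# ---- MLR -------------------------------------------------------------------

#' Fit a multiple linear regression on a low-dimensional feature set
#'
#' Ordinary least squares with intercept. MLR is only valid on feature sets
#' that are both low-dimensional (p < n) and well conditioned; a rank
#' deficiency or a centered cross-product condition number above `max_cond`
#' triggers a refusal error rather than a silently unstable fit.
#'
#' @param X feature matrix (p < n).
#' @param y response.
#' @param max_cond largest admissible condition number of the centered
#'   cross-product (default 1e10).
#' @return object of class `thz_mlr`.
#' @export
fit_mlr <- function(X, y, max_cond = 1e10) {
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "fit_mlr")
  n <- nrow(X); p <- ncol(X)
  if (p >= n) {
    rlang::abort(sprintf(
      "MLR refused: p = %d variables >= n = %d samples. MLR is restricted to low-dimensional feature sets to avoid the curse of dimensionality.",
      p, n), class = "thzash_mlr_refusal")
  }
  d <- svd(sweep(X, 2, colMeans(X)), nu = 0, nv = 0)$d
  cond <- if (min(d) <= 0) Inf else (max(d) / min(d))^2
  if (!is.finite(cond) || cond > max_cond) {
    rlang::abort(sprintf(
      "MLR refused: condition number of the centered cross-product is %.3g (limit %.1g); the feature set is multicollinear.",
      cond, max_cond), class = "thzash_mlr_refusal")
  }
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, X), y)
  structure(
    list(method = "MLR", intercept = unname(fit$coefficients[1]),
         coefficients = fit$coefficients[-1], variables = colnames(X),
         condition_number = cond, fitted = unname(fit$fitted.values)),
    class = c("thz_mlr", "thz_model")
  )
}

#' @export
predict.thz_mlr <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  drop(X %*% object$coefficients) + object$intercept
}

# ---- PCR -------------------------------------------------------------------

#' Fit a principal component regression
#'
#' Principal components of the centered spectra; the retained count is the
#' smallest k whose cumulative explained variance reaches
#' `variance_threshold` (default 0.95), or the k-fold RMSECV minimiser when
#' `select = "cv"`. The response is regressed on the retained scores by OLS.
#'
#' @param X spectra.
#' @param y response.
#' @param variance_threshold cumulative explained-variance threshold in
#'   (0, 1].
#' @param select `"variance"` (threshold rule, default) or `"cv"`.
#' @param cv a [cv_spec()], used when `select = "cv"`.
#' @return object of class `thz_pcr`.
#' @export
fit_pcr <- function(X, y, variance_threshold = 0.95,
                    select = c("variance", "cv"), cv = cv_spec()) {
  select <- match.arg(select)
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "fit_pcr")
  if (nrow(X) < 3) abort_config("PCR needs at least 3 samples.")
  if (variance_threshold <= 0 || variance_threshold > 1) {
    abort_config("`variance_threshold` must be in (0, 1].")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[ev > 1e-12 * ev[1]]
  kmax <- min(length(ev), nrow(X) - 2L)
  cum <- cumsum(ev[seq_len(kmax)]) / sum(pc$sdev^2)
  if (select == "variance") {
    k <- which(cum >= variance_threshold - 1e-12)[1]
    if (is.na(k)) k <- kmax
  } else {
    fold_id <- make_folds(nrow(X), cv$folds, cv$seed)
    errs <- vapply(seq_len(kmax), function(kk) {
      pred <- numeric(nrow(X))
      for (f in sort(unique(fold_id))) {
        te <- fold_id == f
        sub <- fit_pcr_fixed(X[!te, , drop = FALSE], y[!te], kk)
        pred[te] <- drop(model_newdata(sub, X[te, , drop = FALSE]) %*%
                           sub$coefficients) + sub$intercept
      }
      sqrt(mean((y - pred)^2))
    }, numeric(1))
    k <- which.min(errs)
  }
  out <- fit_pcr_fixed(X, y, k)
  out$cum_variance <- cum
  out
}

fit_pcr_fixed <- function(X, y, k) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(k, ncol(pc$rotation))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  fit <- stats::lm.fit(cbind(1, scores), y)
  beta <- fit$coefficients[-1]
  beta[is.na(beta)] <- 0
  b <- drop(pc$rotation[, seq_len(k), drop = FALSE] %*% beta)
  structure(
    list(method = "PCR", n_pc = k, coefficients = b,
         intercept = unname(fit$coefficients[1]) - sum(pc$center * b),
         centering = pc$center, variables = colnames(X),
         fitted = drop(as.matrix(X) %*% b) +
           unname(fit$coefficients[1]) - sum(pc$center * b)),
    class = c("thz_pcr", "thz_model")
  )
}

#' @export
predict.thz_pcr <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  drop(X %*% object$coefficients) + object$intercept
}

# ---- SVR -------------------------------------------------------------------

#' Fit an RBF-kernel support vector regression with grid search
#'
#' The spectra are z-scored from calibration statistics (RBF kernels are
#' scale sensitive); C and gamma run over integer powers of two and the pair
#' minimising the k-fold RMSECV wins, ties going to the smaller C then the
#' smaller gamma. The epsilon tube defaults to `0.01 * sd(y)`.
#'
#' @param X spectra.
#' @param y response (must not be constant).
#' @param C_exponents,gamma_exponents integer exponent grids (defaults
#'   -5..10 and -10..5: a 16 x 16 grid).
#' @param cv a [cv_spec()].
#' @param epsilon epsilon-insensitive tube width.
#' @return object of class `thz_svr`.
#' @export
fit_svr <- function(X, y, C_exponents = -5:10, gamma_exponents = -10:5,
                    cv = cv_spec(), epsilon = NULL) {
  X <- as_spectral_matrix(X)
  check_finite_or_abort(X, "fit_svr")
  if (stats::sd(y) < 1e-12) abort_config("degenerate response: zero variance.")
  epsilon <- epsilon %||% (0.01 * stats::sd(y))
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(X, 2, mu), 2, sdv, `/`)
  n <- nrow(Z)
  fold_id <- make_folds(n, cv$folds, cv$seed)
  grid <- expand.grid(Ce = sort(C_exponents), ge = sort(gamma_exponents))
  grid <- grid[order(grid$Ce, grid$ge), ]
  best <- NULL
  best_err <- Inf
  errs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cost <- 2^grid$Ce[g]; gamma <- 2^grid$ge[g]
    pred <- numeric(n)
    for (f in sort(unique(fold_id))) {
      te <- fold_id == f
      m <- e1071::svm(x = Z[!te, , drop = FALSE], y = y[!te],
                      type = "eps-regression", kernel = "radial",
                      cost = cost, gamma = gamma, epsilon = epsilon,
                      scale = FALSE)
      pred[te] <- stats::predict(m, Z[te, , drop = FALSE])
    }
    errs[g] <- sqrt(mean((y - pred)^2))
    if (errs[g] < best_err) {           # strict <: first (smallest C, gamma) wins ties
      best_err <- errs[g]
      best <- c(cost = cost, gamma = gamma)
    }
  }
  final <- e1071::svm(x = Z, y = y, type = "eps-regression", kernel = "radial",
                      cost = best["cost"], gamma = best["gamma"],
                      epsilon = epsilon, scale = FALSE)
  structure(
    list(method = "SVR", svm = final, cost = unname(best["cost"]),
         gamma = unname(best["gamma"]), epsilon = epsilon,
         rmsecv = best_err, grid_rmsecv = errs,
         centering = mu, scaling = sdv, variables = colnames(X),
         fitted = unname(stats::predict(final, Z))),
    class = c("thz_svr", "thz_model")
  )
}

#' @export
predict.thz_svr <- function(object, newdata, ...) {
  X <- model_newdata(object, newdata)
  Z <- sweep(sweep(X, 2, object$centering), 2, object$scaling, `/`)
  unname(stats::predict(object$svm, Z))
}

# ---- cross-validation engine -----------------------------------------------

#' k-fold cross-validation of an arbitrary fitter
#'
#' Seeded fold assignment; the entire fitting pipeline (centering, scaling,
#' hyperparameter choice) is re-run inside each fold, and the out-of-fold
#' predictions over all n samples give RMSECV = sqrt(mean((y - yhat)^2)).
#'
#' @param fitter function of `(X, y)` returning a model with a `predict`
#'   method.
#' @param X spectra.
#' @param y response.
#' @param cv a [cv_spec()]; `folds = n` gives leave-one-out.
#' @return object of class `thz_cv`: list with `rmsecv`, `predictions`,
#'   `fold_id`.
#' @export
cross_validate <- function(fitter, X, y, cv = cv_spec()) {
  X <- as_spectral_matrix(X)
  n <- nrow(X)
  fold_id <- make_folds(n, cv$folds, cv$seed)
  if (n - max(table(fold_id)) < 2) {
    abort_config("a fold would leave fewer than 2 training samples.")
  }
  pred <- numeric(n)
  for (f in sort(unique(fold_id))) {
    te <- fold_id == f
    m <- fitter(X[!te, , drop = FALSE], y[!te])
    pred[te] <- stats::predict(m, X[te, , drop = FALSE])
  }
  structure(
    list(rmsecv = sqrt(mean((y - pred)^2)), predictions = pred,
         fold_id = fold_id),
    class = "thz_cv"
  )
}

#' @export
print.thz_cv <- function(x, ...) {
  cat(sprintf("<thz_cv> RMSECV = %.6g over %d folds\n",
              x$rmsecv, length(unique(x$fold_id))))
  invisible(x)
}
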