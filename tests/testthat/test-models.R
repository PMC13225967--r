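# Regression frameworks and the cross-validation engine.

ols_fit <- function(X, y) {
  cf <- solve(crossprod(cbind(1, X)), crossprod(cbind(1, X), y))
  drop(cbind(1, X) %*% cf)
}

test_that("PLSR finds a single latent direction exactly", {
  set.seed(10)
  # X = t p' + t2 p2' with t2 orthogonal to y = t and p2 orthogonal to p:
  # the response lives exactly on the first latent direction
  tt <- qr.Q(qr(cbind(1, matrix(rnorm(80), 40, 2))))[, 2:3]  # mean-zero scores
  pp <- qr.Q(qr(matrix(rnorm(16), 8, 2)))
  X <- tcrossprod(tt[, 1], pp[, 1]) + 0.5 * tcrossprod(tt[, 2], pp[, 2])
  y <- tt[, 1]
  fit <- fit_plsr(X, y, max_lv = 5, cv = cv_spec(5, seed = 1))
  expect_equal(fit$n_lv, 1)
  expect_lt(fit$rmsecv, 1e-8)
  expect_equal(unname(fit$fitted), y, tolerance = 1e-8)
})

test_that("PLSR with full latent variables reproduces OLS", {
  set.seed(11)
  X <- matrix(rnorm(30 * 6), 30, 6)
  y <- rnorm(30)
  fit <- thzash:::pls1_fit(X, y, ncomp = 6)
  pred <- thzash:::pls1_predict_path(fit, X)[, 6]
  expect_equal(pred, ols_fit(X, y), tolerance = 1e-8)
})

test_that("PLSR predictions are invariant to variable order", {
  set.seed(12)
  X <- matrix(rnorm(30 * 6), 30, 6)
  colnames(X) <- sprintf("v%d", 1:6)
  y <- drop(X %*% c(1, -1, 0.5, 0, 0, 2)) + rnorm(30, 0, 0.05)
  perm <- c(3, 1, 6, 2, 5, 4)
  f1 <- fit_plsr(X, y, max_lv = 4, cv = cv_spec(5, seed = 2))
  f2 <- fit_plsr(X[, perm], y, max_lv = 4, cv = cv_spec(5, seed = 2))
  Xnew <- matrix(rnorm(5 * 6), 5, 6, dimnames = list(NULL, colnames(X)))
  expect_equal(predict(f2, Xnew), predict(f1, Xnew), tolerance = 1e-8)
  # predicting the calibration mean spectrum returns the mean response
  xm <- matrix(colMeans(X), 1, dimnames = list(NULL, colnames(X)))
  expect_equal(unname(predict(f1, xm)), mean(y), tolerance = 1e-10)
})

test_that("MLR matches hand and oracle fits, refuses ill-posed problems", {
  fit <- fit_mlr(matrix(1:5, 5, 1), 2 * (1:5) + 1)
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  set.seed(13)
  X <- matrix(rnorm(50 * 10), 50, 10)
  y <- rnorm(50)
  fit2 <- fit_mlr(X, y)
  expect_equal(unname(fit2$fitted), ols_fit(X, y), tolerance = 1e-8)
  # manual a + X b equals predict()
  expect_equal(predict(fit2, X),
               drop(X %*% fit2$coefficients) + fit2$intercept, tolerance = 1e-12)
  # duplicated column -> refusal naming the restriction
  expect_error(fit_mlr(cbind(X, X[, 1]), y), class = "thzash_mlr_refusal")
  # p >= n -> refusal
  expect_error(fit_mlr(matrix(rnorm(5 * 6), 5, 6), rnorm(5)),
               class = "thzash_mlr_refusal")
})

test_that("PCR reduces to OLS at threshold 1 and respects dominant directions", {
  set.seed(14)
  X <- matrix(rnorm(30 * 5), 30, 5)
  y <- rnorm(30)
  fit <- fit_pcr(X, y, variance_threshold = 1.0)
  expect_equal(unname(fit$fitted), ols_fit(X, y), tolerance = 1e-8)
  # one dominant direction carrying ~99% of variance
  base <- rnorm(30)
  Xd <- cbind(10 * base, matrix(rnorm(30 * 4, sd = 0.1), 30, 4))
  fit2 <- fit_pcr(Xd, rnorm(30), variance_threshold = 0.95)
  expect_equal(fit2$n_pc, 1)
  expect_equal(formals(fit_pcr)$variance_threshold, 0.95)
  expect_error(fit_pcr(X, y, variance_threshold = 1.2),
               class = "thzash_invalid_config")
  expect_error(fit_pcr(X, y, variance_threshold = 0),
               class = "thzash_invalid_config")
})

test_that("SVR grid defaults span 16 x 16 integer exponents and fit sanely", {
  expect_equal(length(eval(formals(fit_svr)$C_exponents)), 16)
  expect_equal(length(eval(formals(fit_svr)$gamma_exponents)), 16)
  expect_equal(length(eval(formals(fit_svr)$C_exponents)) *
                 length(eval(formals(fit_svr)$gamma_exponents)), 256)
  set.seed(15)
  X <- matrix(rnorm(40 * 3), 40, 3)
  y <- drop(X %*% c(1, 2, -1)) + rnorm(40, 0, 0.05)
  cv <- cv_spec(5, seed = 3)
  svr <- fit_svr(X, y, C_exponents = seq(-2, 8, 2), gamma_exponents = seq(-6, 2, 2),
                 cv = cv)
  plsr <- fit_plsr(X, y, max_lv = 3, cv = cv)
  # on nearly linear data the tuned SVR stays within 2x of PLSR
  expect_lt(svr$rmsecv, 2 * plsr$rmsecv)
  # duplicating a training row leaves prediction (nearly) unchanged at
  # fixed hyperparameters
  m1 <- e1071::svm(x = X, y = y, type = "eps-regression", kernel = "radial",
                   cost = 4, gamma = 0.25, epsilon = 0.01, scale = FALSE)
  m2 <- e1071::svm(x = X[c(1, 1:40), ], y = y[c(1, 1:40)],
                   type = "eps-regression", kernel = "radial",
                   cost = 4, gamma = 0.25, epsilon = 0.01, scale = FALSE)
  expect_equal(predict(m2, X), predict(m1, X), tolerance = 1e-2)
  expect_error(fit_svr(X, rep(1, 40)), class = "thzash_invalid_config")
})

test_that("cross_validate matches an explicit leave-one-out loop", {
  set.seed(16)
  X <- matrix(rnorm(20 * 3), 20, 3)
  y <- drop(X %*% c(1, 0.5, -2)) + rnorm(20, 0, 0.1)
  fitter <- function(X, y) fit_mlr(X, y)
  cvres <- cross_validate(fitter, X, y, cv = cv_spec(20, seed = 1))
  loo <- vapply(1:20, function(i) {
    m <- fit_mlr(X[-i, ], y[-i])
    predict(m, X[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(cvres$predictions, loo, tolerance = 1e-12)
  expect_equal(cvres$rmsecv, sqrt(mean((y - loo)^2)), tolerance = 1e-12)
})

test_that("cross_validate degenerate cases behave as the formula dictates", {
  set.seed(17)
  y <- rnorm(30)
  X <- matrix(rnorm(30), 30, 1)
  # a constant predictor pinned at mean(y): RMSECV equals the population sd
  const_fitter <- function(X_, y_) structure(list(c = mean(y)), class = "konst")
  assign("predict.konst", function(object, newdata, ...) rep(object$c, nrow(newdata)),
         envir = globalenv())
  on.exit(rm("predict.konst", envir = globalenv()), add = TRUE)
  cvres <- cross_validate(const_fitter, X, y, cv = cv_spec(5, seed = 2))
  expect_equal(cvres$rmsecv, sqrt(mean((y - mean(y))^2)), tolerance = 1e-12)
  # perfect model on noiseless linear data
  yl <- drop(X) * 3 + 1
  cvp <- cross_validate(function(X_, y_) fit_mlr(X_, y_), X, yl,
                        cv = cv_spec(5, seed = 2))
  expect_lt(cvp$rmsecv, 1e-8)
  expect_error(cross_validate(function(X_, y_) fit_mlr(X_, y_), X, y,
                              cv = cv_spec(40, seed = 1)),
               class = "thzash_invalid_config")
})

test_that("fitters are deterministic and store their variable subset", {
  set.seed(18)
  X <- matrix(rnorm(30 * 5), 30, 5)
  colnames(X) <- sprintf("f%d", 1:5)
  y <- rnorm(30)
  a <- fit_plsr(X, y, max_lv = 3, cv = cv_spec(5, seed = 9))
  b <- fit_plsr(X, y, max_lv = 3, cv = cv_spec(5, seed = 9))
  expect_identical(a$coefficients, b$coefficients)
  expect_equal(a$variables, colnames(X))
  # missing variables in newdata are reported by name
  expect_error(predict(a, X[, 1:3]), class = "thzash_missing_vars")
})

test_that("prediction-set corruption cannot leak into calibration results", {
  pl <- planted_spectra(n = 60, p = 60, centers = c(15, 35), decoy = 50, seed = 19)
  cal <- 1:45
  X_cal <- pl$X[cal, ]; y_cal <- pl$y[cal]
  X_pred <- pl$X[-cal, ]
  run <- function(Xp) {
    sel <- cars_select(X_cal, y_cal, n_runs = 20, cv_folds = 5, seed = 1)
    fit <- fit_plsr(X_cal[, sel$chosen], y_cal, max_lv = 5, cv = cv_spec(5, seed = 1))
    list(sel = sel$chosen, coef = fit$coefficients,
         pred = predict(fit, Xp[, sel$chosen]))
  }
  clean <- run(X_pred)
  corrupted <- run(X_pred * 1000 + 7)
  expect_identical(clean$sel, corrupted$sel)
  expect_identical(clean$coef, corrupted$coef)
})
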