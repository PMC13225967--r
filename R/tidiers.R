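# broom-style tidy()/glance() methods for fitted models and selection results.

#' @export
tidy.thz_plsr <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$variables %||% sprintf("x%d", seq_along(x$coefficients))),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.thz_plsr <- function(x, ...) {
  tibble::tibble(method = "PLSR", n_lv = x$n_lv, rmsecv = x$rmsecv,
                 n_vars = length(x$coefficients))
}

#' @export
tidy.thz_mlr <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$variables %||% sprintf("x%d", seq_along(x$coefficients))),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.thz_mlr <- function(x, ...) {
  tibble::tibble(method = "MLR", n_vars = length(x$coefficients),
                 condition_number = x$condition_number)
}

#' @export
tidy.thz_pcr <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$variables %||% sprintf("x%d", seq_along(x$coefficients))),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.thz_pcr <- function(x, ...) {
  tibble::tibble(method = "PCR", n_pc = x$n_pc,
                 n_vars = length(x$coefficients))
}

#' @export
glance.thz_svr <- function(x, ...) {
  tibble::tibble(method = "SVR", cost = x$cost, gamma = x$gamma,
                 epsilon = x$epsilon, rmsecv = x$rmsecv,
                 n_support = x$svm$tot.nSV)
}

#' @export
tidy.selection_result <- function(x, ...) {
  tibble::tibble(
    variable = x$chosen,
    freq_THz = x$chosen_freq_THz %||% rep(NA_real_, length(x$chosen)),
    method = x$method
  )
}

#' @export
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    method = x$method, n_chosen = length(x$chosen),
    best_iteration = x$best_iteration,
    best_rmsecv = min(x$rmsecv_trace, na.rm = TRUE)
  )
}
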