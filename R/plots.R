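# ggplot2 visualisations for the main result types.

#' @export
autoplot.spectral_dataset <- function(object, band_only = TRUE, alpha = 0.3, ...) {
  df <- tibble::as_tibble(object)
  if (band_only) df <- dplyr::filter(df, .data$in_band)
  ylab <- switch(object$parameter,
    frequency_domain = "magnitude (a.u.)",
    absorption = expression(alpha ~ (cm^-1)),
    transmittance = "transmittance",
    refractive_index = "refractive index")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$freq_THz, y = .data$value,
                                   group = .data$sample_id)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::labs(x = "frequency (THz)", y = ylab,
                  title = object$parameter) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.selection_result <- function(object, ...) {
  df <- tibble::tibble(
    iteration = seq_along(object$rmsecv_trace),
    rmsecv = object$rmsecv_trace,
    n_vars = as.numeric(object$n_vars_trace)
  )
  long <- tidyr::pivot_longer(df, c("rmsecv", "n_vars"),
                              names_to = "trace", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$iteration, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_iteration,
                        linetype = "dashed", colour = "red") +
    ggplot2::facet_wrap(~trace, ncol = 1, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s sampling trace", object$method),
                  x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.thz_cv <- function(object, y = NULL, ...) {
  df <- tibble::tibble(predicted = object$predictions,
                       fold = factor(object$fold_id))
  if (!is.null(y)) df$reference <- y
  if (is.null(y)) {
    rlang::abort("pass the reference values via `y` to plot predictions.")
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference, y = .data$predicted,
                                   colour = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "reference ash (%)", y = "predicted ash (%)") +
    ggplot2::theme_minimal()
}

#' Predicted-versus-reference scatter for a pipeline result
#'
#' @param result output of [run_pipeline()].
#' @return a ggplot.
#' @export
plot_predictions <- function(result) {
  df <- result$artifacts$predictions
  rep <- result$report
  ggplot2::ggplot(df, ggplot2::aes(x = .data$y_a, y = .data$y_p)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(
      x = "reference ash (%)", y = "predicted ash (%)",
      title = rep$combination,
      subtitle = sprintf("Rp = %.3f, RMSEP = %.4f%%, RPD = %.2f (%s)",
                         rep$Rp, rep$RMSEP, rep$RPD, rep$grade)
    ) +
    ggplot2::theme_minimal()
}

#' Valid-band screening plot
#'
#' @param band tibble from [screen_valid_band()].
#' @param snr_floor_db threshold to draw.
#' @return a ggplot.
#' @export
plot_valid_band <- function(band, snr_floor_db = 10) {
  ggplot2::ggplot(band, ggplot2::aes(x = .data$freq_THz, y = .data$snr_db)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = snr_floor_db, linetype = "dashed") +
    ggplot2::geom_ribbon(data = dplyr::filter(band, .data$in_band),
                         ggplot2::aes(ymin = -Inf, ymax = Inf),
                         alpha = 0.1, fill = "forestgreen") +
    ggplot2::labs(x = "frequency (THz)", y = "SNR (dB)",
                  title = "valid-band screen") +
    ggplot2::theme_minimal()
}
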