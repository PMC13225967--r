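# Time-domain -> frequency-domain conversion and extraction of the four
# spectral datasets (frequency-domain magnitude, absorption coefficient,
# transmittance, refractive index) under the standard thin-pellet first-pass
# transmission model, plus SNR-based valid-band screening.

#' Fourier-transform time-domain traces
#'
#' Discrete Fourier transform of each (sample, replicate) trace, optionally
#' Hann-windowed and zero-padded. Returns the one-sided spectrum excluding the
#' DC bin; the frequency axis is in THz (time in ps), and the phase is
#' unwrapped from the low-frequency end.
#'
#' @param traces tibble with columns `sample_id`, `replicate`, `time_ps`,
#'   `amplitude`; the time axis of each trace must be strictly increasing with
#'   a uniform step.
#' @param window `"none"` or `"hann"`.
#' @param zero_pad_factor integer >= 1; the trace is zero-padded to
#'   `zero_pad_factor` times its length before transforming.
#' @return tibble with columns `sample_id`, `replicate`, `freq_THz`, `re`,
#'   `im`, `magnitude`, `phase`.
#' @export
fourier_spectra <- function(traces, window = c("none", "hann"),
                            zero_pad_factor = 1) {
  window <- match.arg(window)
  stopifnot(zero_pad_factor >= 1)
  one <- function(df, key) {
    x <- df$amplitude
    t <- df$time_ps
    dt <- diff(t)
    if (length(dt) < 2) abort_config("trace too short for a spectrum.")
    bad <- which(abs(dt - dt[1]) > 1e-8 * abs(dt[1]))
    if (length(bad) > 0) {
      abort_config(sprintf(
        "non-uniform time axis for sample '%s' replicate %s: first offending step at index %d (%.6g vs %.6g ps).",
        key$sample_id, key$replicate, bad[1] + 1L, dt[bad[1]], dt[1]))
    }
    n0 <- length(x)
    if (window == "hann") {
      x <- x * 0.5 * (1 - cos(2 * pi * (seq_len(n0) - 1) / (n0 - 1)))
    }
    n <- n0 * as.integer(zero_pad_factor)
    if (n > n0) x <- c(x, rep(0, n - n0))
    sp <- stats::fft(x)
    k <- seq_len(floor(n / 2))          # bins 1..n/2, DC excluded
    f <- k / (n * dt[1])                # ps^-1 == THz
    z <- sp[k + 1L]
    tibble::tibble(
      sample_id = key$sample_id, replicate = key$replicate,
      freq_THz = f, re = Re(z), im = Im(z),
      magnitude = Mod(z), phase = unwrap_phase(Arg(z))
    )
  }
  traces |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_map(one) |>
    dplyr::bind_rows()
}

#' Average replicate spectra in the complex domain
#'
#' Replicates of one sample are averaged on the complex spectrum (not on
#' derived parameters), then magnitude and unwrapped phase are recomputed.
#'
#' @param spectra output of [fourier_spectra()].
#' @return tibble with one spectrum per `sample_id` (`replicate` dropped).
#' @export
average_spectra <- function(spectra) {
  spectra |>
    dplyr::group_by(.data$sample_id, .data$freq_THz) |>
    dplyr::summarise(re = mean(.data$re), im = mean(.data$im), .groups = "drop") |>
    dplyr::arrange(.data$sample_id, .data$freq_THz) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(
      magnitude = sqrt(.data$re^2 + .data$im^2),
      phase = unwrap_phase(atan2(.data$im, .data$re))
    ) |>
    dplyr::ungroup()
}

#' Screen the valid frequency band by signal-to-noise ratio
#'
#' Estimates the noise floor as the standard deviation of the replicate
#' reference magnitudes at each frequency, smoothed over `smooth_bins`
#' adjacent bins: the floor of additive white noise is flat in frequency,
#' so neighbouring bins share it, and a handful of replicates give a noisy
#' pointwise sd. The mean magnitude itself is *not* smoothed -- at a steep
#' band edge it changes by orders of magnitude across a few bins and
#' smoothing it would drag dead frequencies into the band. The valid band is
#' the longest contiguous run of frequencies where the mean reference
#' magnitude exceeds the floor by at least `snr_floor_db` decibels.
#'
#' @param reference_spectra replicate reference spectra from
#'   [fourier_spectra()] (>= 2 replicates), unless `noise_floor` is given.
#' @param snr_floor_db SNR threshold in dB (default 10).
#' @param noise_floor optional explicit noise-floor estimate: a scalar or a
#'   per-frequency vector of magnitude units, used instead of the replicate sd.
#' @param smooth_bins width of the frequency smoothing window (bins).
#' @return tibble with columns `freq_THz`, `mean_magnitude`, `noise_floor`,
#'   `snr_db`, `in_band`. Errors with class `thzash_empty_band` if no
#'   frequency passes.
#' @export
screen_valid_band <- function(reference_spectra, snr_floor_db = 10,
                              noise_floor = NULL, smooth_bins = 9) {
  agg <- reference_spectra |>
    dplyr::group_by(.data$freq_THz) |>
    dplyr::summarise(mean_magnitude = mean(.data$magnitude),
                     sd_magnitude = stats::sd(.data$magnitude),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$freq_THz)
  if (is.null(noise_floor)) {
    if (any(agg$n_rep < 2)) {
      abort_config("need >= 2 replicate reference spectra, or an explicit `noise_floor`.")
    }
    floor_vec <- agg$sd_magnitude
  } else {
    floor_vec <- rep_len(noise_floor, nrow(agg))
  }
  mean_s <- agg$mean_magnitude
  floor_s <- running_mean(floor_vec, smooth_bins)
  snr_db <- ifelse(floor_s <= 0,
                   ifelse(mean_s > 0, Inf, -Inf),
                   20 * log10(mean_s / floor_s))
  pass <- is.finite(snr_db) & snr_db >= snr_floor_db | snr_db == Inf
  if (!any(pass)) {
    rlang::abort("no frequency passes the SNR floor: the valid band is empty.",
                 class = "thzash_empty_band")
  }
  tibble::tibble(
    freq_THz = agg$freq_THz, mean_magnitude = mean_s,
    noise_floor = floor_s, snr_db = snr_db,
    in_band = longest_true_run(pass)
  )
}

# Positive phase delay accumulated inside the sample. Unwrapping through
# frequency bins where the spectrum has no power can pick up arbitrary 2*pi
# multiples, so the offset is anchored on the frequencies where the reference
# has healthy magnitude (>= 1% of its peak): a line fitted there must
# extrapolate to zero phase at zero frequency, and the nearest 2*pi multiple
# of its intercept is removed.
phase_delay <- function(sample_phase, reference_phase, freq_THz,
                        reference_magnitude = NULL) {
  dphi <- reference_phase - sample_phase
  k <- seq_along(dphi)
  if (!is.null(reference_magnitude)) {
    healthy <- which(reference_magnitude >= 0.01 * max(reference_magnitude))
    if (length(healthy) >= 2) k <- healthy
  }
  fit <- stats::lm.fit(cbind(1, freq_THz[k]), dphi[k])
  offset <- 2 * pi * round(fit$coefficients[1] / (2 * pi))
  dphi - offset
}

#' Refractive index from sample and reference spectra
#'
#' n(nu) = 1 + c * dphi(nu) / (2 pi nu d), with dphi the unwrapped phase delay
#' the sample adds relative to the reference, c the vacuum speed of light and
#' d the pellet thickness.
#'
#' @param sample,reference tibbles with `freq_THz` and `phase` on identical
#'   grids (single spectra, e.g. rows of [average_spectra()] output).
#' @param thickness_mm pellet thickness (> 0), mm.
#' @return tibble `freq_THz`, `n`.
#' @export
compute_refractive_index <- function(sample, reference, thickness_mm) {
  if (thickness_mm <= 0) abort_config("`thickness_mm` must be positive.")
  if (!isTRUE(all.equal(sample$freq_THz, reference$freq_THz))) {
    abort_config("sample and reference spectra must share one frequency grid.")
  }
  f <- sample$freq_THz
  keep <- f > 0
  dphi <- phase_delay(sample$phase, reference$phase, f,
                      reference_magnitude = reference$magnitude)
  tibble::tibble(
    freq_THz = f[keep],
    n = 1 + C_MM_PER_PS * dphi[keep] / (2 * pi * f[keep] * thickness_mm)
  )
}

#' Absorption coefficient from sample and reference spectra
#'
#' alpha(nu) = (2 / d) * ln(rho(nu) * A_ref / A_samp) in cm^-1, with the
#' thickness converted from mm. With `fresnel = TRUE` the first-pass
#' reflection loss rho = 4 n / (n + 1)^2 is included (n from
#' [compute_refractive_index()]); the default omits it.
#'
#' @inheritParams compute_refractive_index
#' @param fresnel include the Fresnel reflection-loss factor.
#' @return tibble `freq_THz`, `alpha_cm` (NA where the amplitude ratio is not
#'   positive; the number of masked points is attached as attribute
#'   `n_masked`).
#' @export
compute_absorption <- function(sample, reference, thickness_mm, fresnel = FALSE) {
  if (thickness_mm <= 0) abort_config("`thickness_mm` must be positive.")
  if (!isTRUE(all.equal(sample$freq_THz, reference$freq_THz))) {
    abort_config("sample and reference spectra must share one frequency grid.")
  }
  d_cm <- thickness_mm / 10
  rho <- 1
  if (fresnel) {
    n <- compute_refractive_index(sample, reference, thickness_mm)$n
    rho <- 4 * n / (n + 1)^2
  }
  ratio <- rho * reference$magnitude / sample$magnitude
  ok <- is.finite(ratio) & ratio > 0
  alpha <- rep(NA_real_, length(ratio))
  alpha[ok] <- (2 / d_cm) * log(ratio[ok])
  out <- tibble::tibble(freq_THz = sample$freq_THz, alpha_cm = alpha)
  attr(out, "n_masked") <- sum(!ok)
  out
}

#' Transmittance from sample and reference spectra
#'
#' T(nu) = (A_samp / A_ref)^2.
#'
#' @inheritParams compute_refractive_index
#' @return tibble `freq_THz`, `transmittance` (NA where the reference
#'   amplitude is zero).
#' @export
compute_transmittance <- function(sample, reference) {
  if (!isTRUE(all.equal(sample$freq_THz, reference$freq_THz))) {
    abort_config("sample and reference spectra must share one frequency grid.")
  }
  tr <- ifelse(reference$magnitude > 0,
               (sample$magnitude / reference$magnitude)^2, NA_real_)
  tibble::tibble(freq_THz = sample$freq_THz, transmittance = tr)
}

#' Container for one samples-by-frequency spectral dataset
#'
#' @param parameter one of `"frequency_domain"`, `"absorption"`,
#'   `"transmittance"`, `"refractive_index"`.
#' @param freq_THz frequency axis.
#' @param values samples x frequency matrix (rownames = sample ids).
#' @param valid_mask logical vector marking the screened valid band.
#' @return object of class `spectral_dataset`.
#' @export
spectral_dataset <- function(parameter, freq_THz, values, valid_mask = NULL) {
  parameter <- match.arg(parameter, c("frequency_domain", "absorption",
                                      "transmittance", "refractive_index"))
  values <- as.matrix(values)
  if (is.null(valid_mask)) valid_mask <- rep(TRUE, ncol(values))
  stopifnot(length(freq_THz) == ncol(values),
            length(valid_mask) == ncol(values))
  if (any(!is.finite(values[, valid_mask, drop = FALSE]))) {
    rlang::warn("spectral dataset contains non-finite values inside the valid band.")
  }
  structure(
    list(parameter = parameter, freq_THz = freq_THz, values = values,
         valid_mask = valid_mask, sample_ids = rownames(values)),
    class = "spectral_dataset"
  )
}

#' @export
print.spectral_dataset <- function(x, ...) {
  rng <- range(x$freq_THz[x$valid_mask])
  cat(sprintf("<spectral_dataset: %s> %d samples x %d frequencies, valid band %.3f-%.3f THz (%d points)\n",
              x$parameter, nrow(x$values), ncol(x$values), rng[1], rng[2],
              sum(x$valid_mask)))
  invisible(x)
}

#' Valid-band model matrix of a spectral dataset
#'
#' @param dataset a `spectral_dataset`.
#' @param band_only restrict columns to the valid band (default).
#' @return numeric matrix with frequency-labelled columns
#'   (6-decimal THz names).
#' @export
dataset_matrix <- function(dataset, band_only = TRUE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  keep <- if (band_only) dataset$valid_mask else rep(TRUE, ncol(dataset$values))
  m <- dataset$values[, keep, drop = FALSE]
  colnames(m) <- sprintf("%.6f", dataset$freq_THz[keep])
  m
}

#' @export
#' @method as_tibble spectral_dataset
#' @importFrom tibble as_tibble
as_tibble.spectral_dataset <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_ids %||% seq_len(nrow(x$values)),
                    each = length(x$freq_THz)),
    freq_THz = rep(x$freq_THz, nrow(x$values)),
    value = as.vector(t(x$values)),
    in_band = rep(x$valid_mask, nrow(x$values)),
    parameter = x$parameter
  )
}

#' Extract the four optical spectral datasets of a cohort
#'
#' Runs the full conversion for every sample: Fourier transform, complex
#' replicate averaging, restriction to the instrument band, SNR screening
#' from the replicate reference spectra, then the four parameter datasets.
#'
#' @param cohort a `thz_cohort` (or a list with `traces`, `reference`,
#'   `samples` tibbles of the same shape).
#' @param snr_floor_db SNR threshold for [screen_valid_band()].
#' @param fresnel passed to [compute_absorption()].
#' @param freq_range instrument band (THz); frequencies outside are dropped
#'   before screening.
#' @return list with elements `datasets` (named list of `spectral_dataset`:
#'   `frequency_domain`, `absorption`, `transmittance`, `refractive_index`),
#'   `band` (the screening tibble) and `spectra` (averaged complex spectra).
#' @export
extract_optics <- function(cohort, snr_floor_db = 10, fresnel = FALSE,
                           freq_range = NULL) {
  if (is.null(freq_range)) {
    freq_range <- c(cohort$config$freq_min %||% -Inf,
                    cohort$config$freq_max %||% Inf)
  }
  sample_spec <- fourier_spectra(cohort$traces) |>
    dplyr::filter(.data$freq_THz >= freq_range[1], .data$freq_THz <= freq_range[2])
  ref_spec <- fourier_spectra(cohort$reference) |>
    dplyr::filter(.data$freq_THz >= freq_range[1], .data$freq_THz <= freq_range[2])

  band <- screen_valid_band(ref_spec, snr_floor_db = snr_floor_db)

  avg <- average_spectra(sample_spec)
  ref_avg <- average_spectra(ref_spec)

  ids <- sort(unique(avg$sample_id))
  freq <- ref_avg$freq_THz
  thick <- cohort$samples$thickness_mm[match(ids, cohort$samples$sample_id)]

  mats <- list(frequency_domain = NULL, absorption = NULL,
               transmittance = NULL, refractive_index = NULL)
  rows <- lapply(seq_along(ids), function(i) {
    s <- dplyr::filter(avg, .data$sample_id == ids[i])
    list(
      fd = s$magnitude,
      ab = compute_absorption(s, ref_avg, thick[i], fresnel = fresnel)$alpha_cm,
      tr = compute_transmittance(s, ref_avg)$transmittance,
      ri = compute_refractive_index(s, ref_avg, thick[i])$n
    )
  })
  build <- function(field) {
    m <- do.call(rbind, lapply(rows, `[[`, field))
    rownames(m) <- ids
    m
  }
  mask <- band$in_band
  datasets <- list(
    frequency_domain = spectral_dataset("frequency_domain", freq, build("fd"), mask),
    absorption       = spectral_dataset("absorption", freq, build("ab"), mask),
    transmittance    = spectral_dataset("transmittance", freq, build("tr"), mask),
    refractive_index = spectral_dataset("refractive_index", freq, build("ri"), mask)
  )
  list(datasets = datasets, band = band,
       spectra = avg, reference_spectrum = ref_avg)
}
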