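# Synthetic THz-TDS cohort generator.
#
# Emulates a transmission THz-TDS study of wheat-flour pellets: a reference
# pulse plus per-sample pulses whose frequency-dependent attenuation is linked
# to a known ash value through Gaussian mineral absorption bands. Everything is
# seeded so downstream stages can be tested against ground truth.

#' Default mineral absorption bands
#'
#' Four ash-linked bands in the 0.1--1.1 THz region, where collective
#' vibration / phonon-resonance modes of inorganic mineral constituents
#' (phosphates, carbonates, metal cations) absorb, plus one ash-insensitive
#' decoy band at 2 THz whose amplitude varies from sample to sample
#' independently of ash. The decoy contributes spectral variance that carries
#' no information about the response, which is exactly the trap that
#' variance-driven methods (e.g. PCR) can fall into and that supervised
#' selectors are expected to avoid.
#'
#' @param slope absorption gain per percent ash at an informative band center
#'   (cm^-1 per % ash).
#' @param decoy_jitter_sd sd of the decoy band's per-sample random amplitude
#'   (cm^-1).
#' @return tibble with columns `center_THz`, `width_THz`, `slope`, `jitter_sd`.
#' @export
default_mineral_bands <- function(slope = 0.35, decoy_jitter_sd = 0.2) {
  tibble::tibble(
    center_THz = c(0.30, 0.55, 0.80, 1.05, 2.00),
    width_THz  = c(0.04, 0.04, 0.04, 0.04, 0.06),
    slope      = c(slope, slope, slope, slope, 0),
    jitter_sd  = c(0, 0, 0, 0, decoy_jitter_sd)
  )
}

#' Configuration for a synthetic THz-TDS cohort
#'
#' Defaults emulate the study conditions: 183 samples from 3 cultivars in
#' equal proportions, reference ash between 0.36 and 0.71 %, pellet thickness
#' 1.2 +/- 0.5 mm, a 0.1--4.5 THz spectral range sampled every 0.0125 THz and
#' 3 replicate traces per sample.
#'
#' @param n_samples number of flour samples (>= 4).
#' @param cultivars tibble or data frame with columns `name` and `fraction`
#'   (fractions must sum to 1).
#' @param ash_range numeric length-2, per-sample true ash drawn uniformly
#'   within this range (% by mass).
#' @param thickness_mean,thickness_jitter pellet thickness distribution (mm):
#'   uniform within `thickness_mean +/- thickness_jitter`.
#' @param freq_min,freq_max,freq_step instrument frequency grid (THz).
#' @param n_eff constant effective refractive index of the pellet
#'   (non-dispersive, so the pulse delay is frequency independent).
#' @param mineral_bands tibble of absorption bands, see
#'   [default_mineral_bands()].
#' @param baseline_absorption frequency-flat background absorption (cm^-1).
#' @param noise_sd additive white time-domain noise per replicate (a.u., on
#'   the scale of a unit-peak reference pulse). The default puts the peak
#'   spectral dynamic range near 70 dB and, together with the default band
#'   slope, gives an ash-feature signal-to-noise ratio of about 20 at the
#'   informative band centers after replicate averaging.
#' @param replicates replicate traces per sample (and for the reference).
#' @param pulse list of reference-pulse shape parameters: `center_freq` (THz),
#'   `edge_low`, `edge_high` (log-frequency edge-steepness constants) and
#'   `t0_ps` (pulse arrival time).
#' @param seed master integer seed; all per-sample and per-replicate draws are
#'   derived from it by counter so the cohort does not depend on iteration
#'   order.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 183,
                          cultivars = tibble::tibble(
                            name = c("A", "B", "C"),
                            fraction = rep(1 / 3, 3)
                          ),
                          ash_range = c(0.36, 0.71),
                          thickness_mean = 1.2,
                          thickness_jitter = 0.5,
                          freq_min = 0.1,
                          freq_max = 4.5,
                          freq_step = 0.0125,
                          n_eff = 1.5,
                          mineral_bands = default_mineral_bands(),
                          baseline_absorption = 5,
                          noise_sd = 6e-5,
                          replicates = 3,
                          pulse = list(center_freq = 0.75, edge_low = 1.35,
                                       edge_high = 1.74, t0_ps = 8),
                          seed = 1) {
  cultivars <- tibble::as_tibble(cultivars)
  mineral_bands <- tibble::as_tibble(mineral_bands)
  if (!is.numeric(n_samples) || n_samples < 4) {
    abort_config("`n_samples` must be at least 4.")
  }
  if (length(ash_range) != 2 || ash_range[1] >= ash_range[2]) {
    abort_config("`ash_range` must be (min, max) with min < max.")
  }
  if (!all(c("name", "fraction") %in% names(cultivars))) {
    abort_config("`cultivars` needs columns `name` and `fraction`.")
  }
  if (abs(sum(cultivars$fraction) - 1) > 1e-8) {
    abort_config("cultivar fractions must sum to 1.")
  }
  if (nrow(mineral_bands) == 0) {
    abort_config("`mineral_bands` must contain at least one band.")
  }
  if (!all(c("center_THz", "width_THz", "slope") %in% names(mineral_bands))) {
    abort_config("`mineral_bands` needs columns `center_THz`, `width_THz`, `slope`.")
  }
  if (is.null(mineral_bands$jitter_sd)) mineral_bands$jitter_sd <- 0
  if (any(mineral_bands$center_THz < freq_min | mineral_bands$center_THz > freq_max)) {
    abort_config("all band centers must lie inside the frequency grid.")
  }
  if (noise_sd < 0) abort_config("`noise_sd` must be non-negative.")
  if (replicates < 1) abort_config("`replicates` must be at least 1.")
  if (thickness_jitter < 0 || thickness_jitter >= thickness_mean) {
    abort_config("`thickness_jitter` must be non-negative and below `thickness_mean`.")
  }
  n_grid <- floor((freq_max - freq_min) / freq_step) + 1
  if (n_grid < 16) abort_config("degenerate frequency grid: fewer than 16 points.")
  structure(
    list(
      n_samples = as.integer(n_samples), cultivars = cultivars,
      ash_range = ash_range, thickness_mean = thickness_mean,
      thickness_jitter = thickness_jitter, freq_min = freq_min,
      freq_max = freq_max, freq_step = freq_step, n_eff = n_eff,
      mineral_bands = mineral_bands, baseline_absorption = baseline_absorption,
      noise_sd = noise_sd, replicates = as.integer(replicates),
      pulse = pulse, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Time grid implied by the frequency grid: window T = 1/freq_step so the DFT
# bin spacing matches, Nyquist at least 10% above freq_max.
synth_time_grid <- function(config) {
  m <- ceiling(config$freq_max * 1.1 / config$freq_step)
  n <- 2L * as.integer(m)
  t_window <- 1 / config$freq_step
  dt <- t_window / n
  list(n = n, dt = dt, time_ps = (seq_len(n) - 1) * dt,
       freq_THz = (0:m) * config$freq_step)
}

# Reference magnitude profile: unit peak at `center_freq`, super-Gaussian in
# log-frequency (8th power) with separate low/high edge constants. The steep
# edges concentrate the 40 dB -> 10 dB SNR transition into a few bins, so the
# screened valid band is predominantly high-SNR -- mirroring instruments whose
# usable band supports full-spectrum absorption modelling -- while a 10 dB
# floor still excludes both grid endpoints against a noise floor ~70 dB below
# the peak.
pulse_magnitude <- function(freq_THz, pulse) {
  m <- numeric(length(freq_THz))
  pos <- freq_THz > 0
  lf <- log(freq_THz[pos] / pulse$center_freq)
  cc <- ifelse(lf < 0, pulse$edge_low, pulse$edge_high)
  m[pos] <- exp(-lf^8 / (2 * cc))
  m
}

# inverse FFT of a one-sided spectrum (k = 0..n/2) back to a real signal
ifft_real <- function(pos_spec, n) {
  stopifnot(length(pos_spec) == n / 2 + 1)
  full <- c(pos_spec, Conj(rev(pos_spec[2:(length(pos_spec) - 1L)])))
  Re(stats::fft(full, inverse = TRUE)) / n
}

# one-sided reference spectrum (complex, includes the arrival-time phase)
reference_spectrum <- function(config) {
  tg <- synth_time_grid(config)
  mag <- pulse_magnitude(tg$freq_THz, config$pulse)
  spec <- mag * exp(-2i * pi * tg$freq_THz * config$pulse$t0_ps)
  x <- ifft_real(spec, tg$n)
  scale <- max(abs(x))
  list(spec = spec / scale, time = tg, amplitude = x / scale)
}

#' Generate the clean reference pulse
#'
#' A band-limited, zero-mean single pulse whose magnitude spectrum rises
#' steeply out of the noise at the low-frequency edge, stays flat-topped over
#' roughly 0.25--3 THz and falls away again towards the Nyquist edge, so that
#' SNR-based valid-band screening is non-trivial. The peak time-domain
#' amplitude is normalised to 1 a.u.
#'
#' @param config a [cohort_config()].
#' @param seed unused (the clean pulse is deterministic); kept so the call
#'   signature matches the other generators.
#' @return tibble with columns `sample_id` ("REF"), `replicate`, `time_ps`,
#'   `amplitude`.
#' @export
reference_pulse <- function(config = cohort_config(), seed = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  ref <- reference_spectrum(config)
  tibble::tibble(
    sample_id = "REF", replicate = 1L,
    time_ps = ref$time$time_ps, amplitude = ref$amplitude
  )
}

#' Ground-truth absorption coefficient of the forward model
#'
#' alpha(nu) = baseline + sum over bands of (slope * ash + jitter) *
#' exp(-(nu - center)^2 / (2 width^2)), in cm^-1.
#'
#' @param freq_THz frequencies at which to evaluate (THz).
#' @param ash true ash content (%).
#' @param config a [cohort_config()].
#' @param jitter optional per-band amplitude offsets (cm^-1), e.g. the decoy
#'   band's sample-specific draw; defaults to 0 for every band.
#' @return numeric vector of absorption coefficients (cm^-1).
#' @export
ash_absorption <- function(freq_THz, ash, config, jitter = NULL) {
  b <- config$mineral_bands
  if (is.null(jitter)) jitter <- rep(0, nrow(b))
  a <- rep(config$baseline_absorption, length(freq_THz))
  for (k in seq_len(nrow(b))) {
    amp <- b$slope[k] * ash + jitter[k]
    a <- a + amp * exp(-(freq_THz - b$center_THz[k])^2 / (2 * b$width_THz[k]^2))
  }
  a
}

#' Generate a seeded synthetic cohort
#'
#' Each sample trace is the reference pulse delayed by `(n_eff - 1) d / c` and
#' attenuated in the frequency domain by `exp(-alpha(nu; ash) d / 2)` (field
#' amplitude, thickness d in cm for alpha in cm^-1), with independent additive
#' white noise per replicate. True ash values are drawn uniformly per cultivar
#' within `ash_range`; thickness is drawn uniformly within
#' `thickness_mean +/- thickness_jitter` and recorded in the sample table.
#' The reference is measured with the same number of noisy replicates, which
#' is what the SNR band screen uses to estimate the noise floor.
#'
#' @param config a [cohort_config()].
#' @return object of class `thz_cohort`: a list with elements
#'   * `samples`: tibble (`sample_id`, `cultivar`, `ash_true`, `thickness_mm`,
#'     `set`),
#'   * `traces`: long tibble of sample traces (`sample_id`, `replicate`,
#'     `time_ps`, `amplitude`),
#'   * `reference`: long tibble of replicate reference traces,
#'   * `band_effects`: per-sample per-band amplitude offsets actually drawn
#'     (needed to reconstruct each sample's exact ground-truth alpha),
#'   * `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_samples
  seed <- config$seed

  # cultivar counts by largest remainder so they always total n
  quota <- config$cultivars$fraction * n
  counts <- floor(quota)
  left <- n - sum(counts)
  if (left > 0) {
    counts[order(quota - counts, decreasing = TRUE)[seq_len(left)]] <-
      counts[order(quota - counts, decreasing = TRUE)[seq_len(left)]] + 1
  }
  cultivar <- rep(config$cultivars$name, counts)

  ids <- sprintf("S%03d", seq_len(n))
  ash <- vapply(seq_len(n), function(i) {
    withr::with_seed(derive_seed(seed, 1, i),
                     stats::runif(1, config$ash_range[1], config$ash_range[2]))
  }, numeric(1))
  thick <- vapply(seq_len(n), function(i) {
    withr::with_seed(derive_seed(seed, 2, i),
                     stats::runif(1, config$thickness_mean - config$thickness_jitter,
                                  config$thickness_mean + config$thickness_jitter))
  }, numeric(1))

  nb <- nrow(config$mineral_bands)
  jit <- t(vapply(seq_len(n), function(i) {
    withr::with_seed(derive_seed(seed, 3, i),
                     stats::rnorm(nb, 0, config$mineral_bands$jitter_sd))
  }, numeric(nb)))

  samples <- tibble::tibble(
    sample_id = ids, cultivar = cultivar, ash_true = ash,
    thickness_mm = thick, set = "unassigned"
  )

  ref <- reference_spectrum(config)
  tg <- ref$time
  fpos <- tg$freq_THz

  one_sample_clean <- function(i) {
    alpha <- ash_absorption(fpos, ash[i], config, jitter = jit[i, ])
    d_cm <- thick[i] / 10
    delay_ps <- (config$n_eff - 1) * thick[i] / C_MM_PER_PS
    h <- exp(-alpha * d_cm / 2) * exp(-2i * pi * fpos * delay_ps)
    ifft_real(ref$spec * h, tg$n)
  }

  reps <- config$replicates
  trace_list <- vector("list", n)
  for (i in seq_len(n)) {
    clean <- one_sample_clean(i)
    rep_traces <- lapply(seq_len(reps), function(r) {
      noise <- if (config$noise_sd > 0) {
        withr::with_seed(derive_seed(seed, 10, i, r),
                         stats::rnorm(tg$n, 0, config$noise_sd))
      } else 0
      tibble::tibble(sample_id = ids[i], replicate = r,
                     time_ps = tg$time_ps, amplitude = clean + noise)
    })
    trace_list[[i]] <- dplyr::bind_rows(rep_traces)
  }
  traces <- dplyr::bind_rows(trace_list)

  reference <- dplyr::bind_rows(lapply(seq_len(reps), function(r) {
    noise <- if (config$noise_sd > 0) {
      withr::with_seed(derive_seed(seed, 11, 0, r),
                       stats::rnorm(tg$n, 0, config$noise_sd))
    } else 0
    tibble::tibble(sample_id = "REF", replicate = r,
                   time_ps = tg$time_ps, amplitude = ref$amplitude + noise)
  }))

  band_effects <- tibble::as_tibble(jit, .name_repair = ~ sprintf("band_%d", seq_len(nb)))
  band_effects <- dplyr::bind_cols(tibble::tibble(sample_id = ids), band_effects)

  structure(
    list(samples = samples, traces = traces, reference = reference,
         band_effects = band_effects, config = config),
    class = "thz_cohort"
  )
}

#' True absorption spectrum of one cohort sample
#'
#' Reconstructs the exact alpha(nu) the forward model used for a sample,
#' including its random band offsets (the decoy band draw).
#'
#' @param cohort a `thz_cohort`.
#' @param sample_id sample identifier.
#' @param freq_THz frequencies (THz).
#' @return numeric vector (cm^-1).
#' @export
cohort_alpha <- function(cohort, sample_id, freq_THz) {
  i <- match(sample_id, cohort$samples$sample_id)
  if (is.na(i)) abort_config(sprintf("unknown sample_id '%s'", sample_id))
  jit <- as.numeric(cohort$band_effects[i, -1])
  ash_absorption(freq_THz, cohort$samples$ash_true[i], cohort$config, jitter = jit)
}

#' @export
print.thz_cohort <- function(x, ...) {
  cat(sprintf(
    "<thz_cohort> %d samples x %d replicates, %d cultivars, ash %.2f-%.2f %%\n",
    nrow(x$samples), x$config$replicates,
    length(unique(x$samples$cultivar)),
    min(x$samples$ash_true), max(x$samples$ash_true)
  ))
  invisible(x)
}

#' Planted-band spectral matrix for selector benchmarking
#'
#' A direct samples-by-variables matrix with a known answer: five informative
#' Gaussian bands whose amplitudes scale linearly with the response, one decoy
#' band with a random response-independent amplitude, a smooth shared
#' baseline, and white noise calibrated so the per-point ash-feature SNR at a
#' band center equals `snr`.
#'
#' @param n samples.
#' @param p variables.
#' @param centers indices of the informative band centers.
#' @param decoy index of the decoy band center.
#' @param width band sd in index units.
#' @param snr per-point signal-to-noise ratio at a band center (band-amplitude
#'   span across the response range over the noise sd).
#' @param ash_range response range, uniform.
#' @param seed integer seed.
#' @return list with `X` (n x p), `y`, `centers`, `decoy`, `width`, `freq`
#'   (a nominal 0.1--1.1 THz axis for labelling).
#' @export
planted_spectra <- function(n = 100, p = 200,
                            centers = c(25, 60, 95, 130, 165), decoy = 190,
                            width = 2.5, snr = 20,
                            ash_range = c(0.36, 0.71), seed = 1) {
  withr::with_seed(seed, {
    y <- stats::runif(n, ash_range[1], ash_range[2])
    idx <- seq_len(p)
    base <- 5 + 0.5 * sin(2 * pi * idx / p)
    X <- matrix(rep(base, each = n), n, p)
    span <- diff(ash_range)
    for (cc in centers) {
      g <- exp(-(idx - cc)^2 / (2 * width^2))
      X <- X + outer(y, g)           # unit slope per unit response
    }
    g <- exp(-(idx - decoy)^2 / (2 * width^2))
    X <- X + outer(stats::runif(n, 0, span), g)
    X <- X + matrix(stats::rnorm(n * p, 0, span / snr), n, p)
  })
  freq <- seq(0.1, 1.1, length.out = p)
  colnames(X) <- sprintf("f%03d", seq_len(p))
  list(X = X, y = y, centers = centers, decoy = decoy, width = width, freq = freq)
}
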