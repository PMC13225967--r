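# Synthetic-cohort generator: pulse contracts, forward model, determinism, IO.

test_that("reference pulse is zero-mean, band-limited and deterministic", {
  cfg <- cohort_config()
  p1 <- reference_pulse(cfg)
  p2 <- reference_pulse(cfg)
  expect_identical(p1, p2)
  # derivative-free zero-DC contract: the pulse integrates to ~0
  expect_lt(abs(sum(p1$amplitude)) / sum(abs(p1$amplitude)), 1e-10)
  # spectral ratio contract: 1 THz carries far more power than 4.4 THz
  sp <- fourier_spectra(p1)
  m_at <- function(f) sp$magnitude[which.min(abs(sp$freq_THz - f))]
  expect_gt(m_at(1) / m_at(4.4), 10)
  # the 40 dB bandwidth contract over the flat-top region, against the
  # default noise floor estimated from replicate reference spectra
  co <- generate_cohort(cohort_config(n_samples = 4, seed = 2))
  ref <- fourier_spectra(co$reference) |>
    dplyr::filter(freq_THz >= 0.25, freq_THz <= 2.8)
  agg <- ref |>
    dplyr::group_by(freq_THz) |>
    dplyr::summarise(snr = mean(magnitude) / sd(magnitude))
  expect_true(all(20 * log10(agg$snr) > 40))
})

test_that("degenerate frequency grids are refused", {
  expect_error(cohort_config(freq_min = 1, freq_max = 1.1, freq_step = 0.05),
               class = "thzash_invalid_config")
  expect_error(cohort_config(noise_sd = -1), class = "thzash_invalid_config")
  expect_error(cohort_config(mineral_bands = default_mineral_bands()[0, ]),
               class = "thzash_invalid_config")
  expect_error(cohort_config(ash_range = c(0.7, 0.3)),
               class = "thzash_invalid_config")
})

test_that("default cohort matches the study conditions", {
  co <- generate_cohort(cohort_config(seed = 7))
  expect_equal(nrow(co$samples), 183)
  expect_equal(length(unique(co$samples$cultivar)), 3)
  expect_true(all(co$samples$ash_true >= 0.36 & co$samples$ash_true <= 0.71))
  expect_true(all(abs(co$samples$thickness_mm - 1.2) <= 0.5))
  expect_equal(unique(co$samples$set), "unassigned")
  expect_equal(dplyr::n_distinct(co$traces$replicate), 3)
  expect_equal(dplyr::n_distinct(co$reference$replicate), 3)
})

test_that("identical config and seed reproduce the cohort exactly", {
  a <- generate_cohort(small_cohort_config(n = 6, seed = 42))
  b <- generate_cohort(small_cohort_config(n = 6, seed = 42))
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
  expect_equal(a$traces$amplitude, b$traces$amplitude, tolerance = 1e-12)
})

test_that("with alpha forced to ~0 the sample trace is the delayed reference", {
  co <- generate_cohort(cohort_config(
    n_samples = 4, noise_sd = 0, baseline_absorption = 0,
    ash_range = c(0, 1e-12),
    mineral_bands = default_mineral_bands(slope = 0, decoy_jitter_sd = 0),
    seed = 1
  ))
  id <- co$samples$sample_id[1]
  d <- co$samples$thickness_mm[1]
  tr <- dplyr::filter(co$traces, sample_id == id, replicate == 1)
  sp_s <- fourier_spectra(tr)
  sp_r <- fourier_spectra(dplyr::filter(co$reference, replicate == 1))
  keep <- sp_r$magnitude > 1e-6 * max(sp_r$magnitude)
  # attenuation factor is 1: magnitudes equal
  expect_equal(sp_s$magnitude[keep], sp_r$magnitude[keep], tolerance = 1e-9)
  # shift theorem: phase difference is 2 pi nu dt with dt = (n_eff - 1) d / c
  dt <- (1.5 - 1) * d / 0.299792458
  dphi <- (sp_r$phase - sp_s$phase)[keep]
  expected <- 2 * pi * sp_r$freq_THz[keep] * dt
  # independent unwrapping fixes each spectrum's branch only up to 2 pi
  offset <- 2 * pi * round((dphi[1] - expected[1]) / (2 * pi))
  expect_equal(dphi - offset, expected, tolerance = 1e-6)
})

test_that("replicate traces differ only by noise, averaging at the expected rate", {
  co <- generate_cohort(small_cohort_config(n = 4, seed = 3, noise_sd = 0))
  per_rep <- co$traces |>
    dplyr::group_by(sample_id, replicate) |>
    dplyr::summarise(h = sum(amplitude^2), .groups = "drop") |>
    dplyr::group_by(sample_id) |>
    dplyr::summarise(v = var(h))
  expect_true(all(per_rep$v < 1e-20))

  # replicate-mean error scales as noise_sd / sqrt(replicates)
  sd_of_mean <- function(reps) {
    noisy <- generate_cohort(small_cohort_config(n = 4, seed = 3, replicates = reps))
    clean <- dplyr::filter(co$traces, replicate == 1)
    m <- noisy$traces |>
      dplyr::group_by(sample_id, time_ps) |>
      dplyr::summarise(amplitude = mean(amplitude), .groups = "drop")
    sd(m$amplitude - clean$amplitude)
  }
  ratio <- sd_of_mean(3) / sd_of_mean(48)
  expect_gt(ratio, 4 * 0.8)       # expected sqrt(48/3) = 4
  expect_lt(ratio, 4 * 1.2)
})

test_that("higher ash attenuates every informative band center (noiseless)", {
  lo <- generate_cohort(cohort_config(
    n_samples = 4, noise_sd = 0, seed = 9, ash_range = c(0.36, 0.360001),
    mineral_bands = default_mineral_bands(decoy_jitter_sd = 0)))
  hi <- generate_cohort(cohort_config(
    n_samples = 4, noise_sd = 0, seed = 9, ash_range = c(0.709999, 0.71),
    mineral_bands = default_mineral_bands(decoy_jitter_sd = 0)))
  sp_lo <- average_spectra(fourier_spectra(lo$traces))
  sp_hi <- average_spectra(fourier_spectra(hi$traces))
  centers <- default_mineral_bands()$center_THz[1:4]
  for (id in lo$samples$sample_id) {
    a <- dplyr::filter(sp_lo, sample_id == id)
    b <- dplyr::filter(sp_hi, sample_id == id)
    for (cc in centers) {
      j <- which.min(abs(a$freq_THz - cc))
      expect_lt(b$magnitude[j], a$magnitude[j])
    }
  }
})

test_that("cohorts round-trip through disk and refuse accidental overwrite", {
  co <- generate_cohort(small_cohort_config(n = 5, seed = 11))
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  # (n_samples + reference) * replicates trace files
  expect_equal(sum(grepl("^trace_", basename(files))), (5 + 1) * 3)
  expect_error(write_cohort(co, dir), class = "thzash_exists")
  back <- read_cohort(dir)
  expect_equal(back$samples, co$samples)
  a <- dplyr::arrange(co$traces, sample_id, replicate, time_ps)
  b <- dplyr::arrange(back$traces, sample_id, replicate, time_ps)
  expect_equal(b$amplitude, a$amplitude, tolerance = 1e-12)
  expect_equal(back$config$mineral_bands, co$config$mineral_bands)
})

test_that("planted spectra carry the designed signal and decoy", {
  pl <- planted_spectra(n = 60, seed = 4)
  expect_equal(dim(pl$X), c(60, 200))
  j <- pl$centers[2]
  expect_gt(cor(pl$y, pl$X[, j]), 0.9)
  expect_lt(abs(cor(pl$y, pl$X[, pl$decoy])), 0.5)
  # decoy still varies between samples
  expect_gt(sd(pl$X[, pl$decoy]), 2 * sd(pl$X[, 5]))
})
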