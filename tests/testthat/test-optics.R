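# Frequency-domain conversion, optical-constant extraction, band screening.

make_trace <- function(amplitude, dt = 0.1) {
  tibble::tibble(sample_id = "X", replicate = 1L,
                 time_ps = (seq_along(amplitude) - 1) * dt,
                 amplitude = amplitude)
}

test_that("a pure cosine peaks at the nearest grid frequency", {
  t <- seq(0, 64 - 0.05, by = 0.05)      # 64 ps window -> 0.015625 THz bins
  sp <- fourier_spectra(make_trace(cos(2 * pi * 1 * t), dt = 0.05))
  peak <- sp$freq_THz[which.max(sp$magnitude)]
  expect_equal(peak, sp$freq_THz[which.min(abs(sp$freq_THz - 1))])
})

test_that("fft path matches a brute-force discrete Fourier sum", {
  co <- noiseless_cohort(n = 4)
  tr <- dplyr::filter(co$reference, replicate == 1)
  x <- tr$amplitude[1:128]
  sp <- fourier_spectra(make_trace(x))
  oracle <- dft_oracle(x)[2:65]          # one-sided (k = 1..n/2), DC dropped
  expect_equal(sp$magnitude, Mod(oracle), tolerance = 1e-10)
  expect_equal(sp$re, Re(oracle), tolerance = 1e-10)
})

test_that("a delayed trace keeps its magnitude and shifts phase linearly", {
  n <- 256
  x <- exp(-((1:n) - 60)^2 / 50)
  sp0 <- fourier_spectra(make_trace(x))
  # circular shift by 10 samples = 1 ps: the exact DFT shift-theorem setting
  sp1 <- fourier_spectra(make_trace(c(x[(n - 9):n], x[1:(n - 10)])))
  expect_equal(sp1$magnitude, sp0$magnitude, tolerance = 1e-8)
  keep <- sp0$magnitude > 1e-3 * max(sp0$magnitude)
  dphi <- (sp0$phase - sp1$phase)[keep]
  expect_equal(dphi - 2 * pi * round((dphi[1] - 2 * pi * sp0$freq_THz[keep][1]) / (2 * pi)),
               2 * pi * sp0$freq_THz[keep] * 1, tolerance = 1e-6)
})

test_that("non-uniform time axes are rejected with the offending step named", {
  tr <- make_trace(rnorm(32))
  tr$time_ps[20] <- tr$time_ps[20] + 0.03
  expect_error(fourier_spectra(tr), regexp = "index 20|index 21",
               class = "thzash_invalid_config")
})

test_that("identical sample and reference give n = 1, alpha = 0, T = 1", {
  co <- noiseless_cohort(n = 4)
  ref <- average_spectra(fourier_spectra(co$reference))
  n <- compute_refractive_index(ref, ref, thickness_mm = 1.2)
  expect_equal(n$n, rep(1, nrow(n)), tolerance = 1e-12)
  a <- compute_absorption(ref, ref, thickness_mm = 1.2)
  expect_equal(a$alpha_cm, rep(0, nrow(a)), tolerance = 1e-12)
  tr <- compute_transmittance(ref, ref)
  expect_equal(tr$transmittance, rep(1, nrow(tr)), tolerance = 1e-12)
})

test_that("optical-constant formulas scale as stated", {
  f <- seq(0.2, 2, by = 0.1)
  ref <- tibble::tibble(freq_THz = f, magnitude = rep(2, length(f)),
                        phase = rep(0, length(f)))
  smp <- tibble::tibble(freq_THz = f, magnitude = rep(1, length(f)),
                        phase = -2 * pi * f * 0.5)
  n1 <- compute_refractive_index(smp, ref, thickness_mm = 2)
  n2 <- compute_refractive_index(smp, ref, thickness_mm = 1)
  # halving thickness at fixed phase delay doubles n - 1
  expect_equal(n2$n - 1, 2 * (n1$n - 1), tolerance = 1e-12)
  a1 <- compute_absorption(smp, ref, thickness_mm = 2)
  a2 <- compute_absorption(smp, ref, thickness_mm = 4)
  # doubling thickness at fixed amplitude ratio halves alpha
  expect_equal(a2$alpha_cm, a1$alpha_cm / 2, tolerance = 1e-12)
  # amplitude ratio 0.5 gives T = 0.25
  expect_equal(compute_transmittance(smp, ref)$transmittance,
               rep(0.25, length(f)), tolerance = 1e-12)
  expect_error(compute_refractive_index(smp, ref, thickness_mm = 0),
               class = "thzash_invalid_config")
})

test_that("noiseless forward model round-trips through extraction", {
  co <- noiseless_cohort(n = 4, seed = 5)
  band <- numerical_band(co)
  opt <- extract_optics(co)
  mask <- band$in_band
  ab <- opt$datasets$absorption
  for (id in co$samples$sample_id) {
    truth <- cohort_alpha(co, id, ab$freq_THz)
    rel <- abs(ab$values[id, mask] - truth[mask]) / abs(truth[mask])
    expect_lt(max(rel), 0.01)
  }
  ri <- opt$datasets$refractive_index
  expect_equal(unname(ri$values[, mask]),
               matrix(1.5, 4, sum(mask)), tolerance = 0.01)
  # -ln T / d is algebraically identical to alpha (fresnel off)
  tr <- opt$datasets$transmittance
  d_cm <- co$samples$thickness_mm / 10
  for (i in seq_len(4)) {
    id <- co$samples$sample_id[i]
    expect_equal(-log(tr$values[id, mask]) / d_cm[i],
                 unname(ab$values[id, mask]), tolerance = 1e-9)
  }
})

test_that("alpha is invariant to a global amplitude rescaling", {
  co <- noiseless_cohort(n = 4)
  ref <- average_spectra(fourier_spectra(co$reference))
  smp <- average_spectra(fourier_spectra(
    dplyr::filter(co$traces, sample_id == co$samples$sample_id[1])))
  a0 <- compute_absorption(smp, ref, 1.2)
  smp2 <- dplyr::mutate(smp, magnitude = magnitude * 7.3)
  ref2 <- dplyr::mutate(ref, magnitude = magnitude * 7.3)
  a1 <- compute_absorption(smp2, ref2, 1.2)
  expect_equal(a1$alpha_cm, a0$alpha_cm, tolerance = 1e-12)
})

test_that("valid-band screening behaves monotonically and excludes edges", {
  co <- generate_cohort(small_cohort_config(n = 4, seed = 21))
  ref <- fourier_spectra(co$reference) |>
    dplyr::filter(freq_THz >= 0.1, freq_THz <= 4.5)
  b10 <- screen_valid_band(ref, snr_floor_db = 10)
  expect_false(b10$in_band[1])
  expect_false(b10$in_band[nrow(b10)])
  # raising the floor never widens the band
  for (fl in c(20, 30, 40)) {
    b <- screen_valid_band(ref, snr_floor_db = fl)
    expect_true(all(b10$in_band[b$in_band]))
  }
  # noiseless spectra with a tiny numerical floor: mask covers the support
  co0 <- noiseless_cohort(n = 4)
  b0 <- numerical_band(co0)
  expect_gt(sum(b0$in_band), 200)
  # no frequency passing is an explicit error
  expect_error(screen_valid_band(ref, noise_floor = 1e9),
               class = "thzash_empty_band")
  expect_error(
    screen_valid_band(dplyr::filter(ref, replicate == 1)),
    class = "thzash_invalid_config")
})

test_that("masked datasets contain no non-finite values", {
  co <- generate_cohort(small_cohort_config(n = 6, seed = 2))
  opt <- extract_optics(co)
  for (ds in opt$datasets) {
    expect_true(all(is.finite(ds$values[, ds$valid_mask])))
  }
  m <- dataset_matrix(opt$datasets$absorption)
  expect_equal(nrow(m), 6)
  expect_true(all(grepl("^\\d\\.\\d{6}$", colnames(m))))
})

test_that("full noiseless round trip holds across random configurations", {
  set.seed(77)
  for (rep in 1:3) {
    nb <- 2 + rep
    bands <- tibble::tibble(
      center_THz = sort(runif(nb, 0.4, 2.5)),
      width_THz = runif(nb, 0.03, 0.08),
      slope = runif(nb, 0.5, 3), jitter_sd = 0
    )
    cfg <- cohort_config(
      n_samples = 4, noise_sd = 0, seed = 100 + rep,
      n_eff = runif(1, 1.2, 1.9),
      baseline_absorption = runif(1, 1, 8), mineral_bands = bands
    )
    co <- generate_cohort(cfg)
    band <- numerical_band(co)
    opt <- extract_optics(co)
    mask <- band$in_band
    ab <- opt$datasets$absorption
    for (id in co$samples$sample_id) {
      truth <- cohort_alpha(co, id, ab$freq_THz)
      expect_lt(max(abs(ab$values[id, mask] - truth[mask]) / abs(truth[mask])),
                0.01)
    }
    expect_equal(unname(opt$datasets$refractive_index$values[, mask]),
                 matrix(cfg$n_eff, 4, sum(mask)), tolerance = 0.01)
  }
})
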