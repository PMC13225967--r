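# Shared fixtures, built in code at test time.

# small, fast cohort: fewer samples, otherwise default physics
small_cohort_config <- function(n = 12, seed = 1, noise_sd = 6e-5, ...) {
  cohort_config(n_samples = n, seed = seed, noise_sd = noise_sd, ...)
}

# noiseless cohort with no decoy jitter, for exact round trips
noiseless_cohort <- function(n = 4, seed = 5, ...) {
  generate_cohort(cohort_config(
    n_samples = n, seed = seed, noise_sd = 0,
    mineral_bands = default_mineral_bands(decoy_jitter_sd = 0), ...
  ))
}

# valid band for a noiseless cohort: replicate sd is zero, so screen against
# an explicit numerical floor (double-precision FFT noise scale)
numerical_band <- function(cohort) {
  ref <- fourier_spectra(cohort$reference) |>
    dplyr::filter(freq_THz >= cohort$config$freq_min,
                  freq_THz <= cohort$config$freq_max)
  screen_valid_band(ref, noise_floor = 1e-9 * max(ref$magnitude),
                    smooth_bins = 1)
}

# does `chosen` hit every planted band center (within tol index units)?
bands_hit <- function(chosen, centers, tol = 4) {
  vapply(centers, function(cc) any(abs(chosen - cc) <= tol), logical(1))
}

# brute-force O(N^2) discrete Fourier sum (oracle for the FFT path)
dft_oracle <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk) {
    sum(x * exp(-2i * pi * kk * (0:(n - 1)) / n))
  }, complex(1))
}

# exhaustive maximin Kennard-Stone oracle
ks_oracle <- function(X, k) {
  D <- as.matrix(dist(X))
  ij <- arrayInd(which.max(D), dim(D))
  sel <- sort(c(ij[1], ij[2]))
  while (length(sel) < k) {
    cand <- setdiff(seq_len(nrow(X)), sel)
    mind <- vapply(cand, function(i) min(D[i, sel]), numeric(1))
    sel <- c(sel, cand[which.max(mind)])
  }
  sel
}
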