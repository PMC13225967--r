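---
title: "Models and methods behind thzash"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind thzash}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`thzash` implements the calibration workflow used to quantify wheat-flour
ash content from transmission terahertz time-domain spectroscopy. This
vignette explains the models, the synthetic data they are validated
against, and the numerical and design choices a user should know before
trusting — or modifying — the defaults.

## The measurement model

A THz-TDS instrument records the transmitted electric-field pulse as a
function of optical delay, for flour/polyethylene pellets and for a
reference. After discrete Fourier transformation (replicates averaged in
the complex domain, so phase noise averages rather than magnitude bias),
the thin-pellet first-pass transmission model gives the optical constants:

* refractive index: `n(ν) = 1 + c·Δφ(ν) / (2π ν d)`, where `Δφ` is the
  phase delay the pellet adds (reference-minus-sample under the FFT sign
  convention used here — the sign that makes a later-arriving pulse give
  `n > 1`) and `d` the pellet thickness;
* absorption coefficient: `α(ν) = (2/d)·ln(ρ·A_ref/A_samp)` in cm⁻¹, with
  the Fresnel reflection-loss factor `ρ = 4n/(n+1)²` available but off by
  default (the synthetic forward model contains no interface loss, and
  whether the original workflow applied one is unknowable — both variants
  are exposed);
* transmittance: `T(ν) = (A_samp/A_ref)²`.

Phase unwrapping proceeds from the lowest frequency; because bins outside
the pulse's support contain no signal, unwrapping through them can pick up
arbitrary 2π multiples, so the offset is re-anchored by fitting a line to
`Δφ(ν)` over the frequencies where the reference holds at least 1% of its
peak magnitude and removing the nearest 2π multiple of its intercept — a
physical delay must extrapolate to zero phase at zero frequency.

Multiple-reflection (Fabry–Pérot) deconvolution and material-parameter
fitting beyond this first-pass model are out of scope.

## Valid-band screening

`screen_valid_band()` estimates the noise floor as the across-replicate
standard deviation of the reference magnitude, smoothed over 9 bins
(white-noise floors are flat in frequency, and 3 replicates give a noisy
pointwise sd; the *mean* magnitude is deliberately not smoothed, because on
a steep band edge smoothing drags dead bins into the band). The valid band
is the longest contiguous run with SNR above the floor, 10 dB by default.

The pipeline, however, screens the absorption dataset at 30 dB. The reason
is an error-propagation fact worth internalising: `α` inherits the
*relative* amplitude error amplified by `2/d`, so at a 10 dB amplitude SNR
(≈ 30% error) the absorption noise is several cm⁻¹ — orders of magnitude
above any mineral signature — while 30 dB keeps it near 0.4 cm⁻¹ at the
very edge and far better inboard. Band-edge absorption noise is the single
most consequential nuisance in this workflow: it can swamp the covariance
structure that PLS weights and CARS eliminations rely on, and it degrades
Kennard–Stone's coverage of the concentration range (below).

## The synthetic cohort

`generate_cohort()` emulates the study design: 183 samples from 3 cultivars
in equal thirds, true ash uniform on 0.36–0.71%, pellet thickness uniform
in 1.2 ± 0.5 mm, a 0.1–4.5 THz grid at 0.0125 THz, and 3 replicate traces
per sample (the reference is measured with the same number of replicates —
that is what the noise-floor estimate needs). The forward model delays the
reference pulse by `(n_eff − 1)·d/c` with a constant `n_eff = 1.5`
(dispersion out of scope) and attenuates the field by `exp(−α·d/2)`, with

`α(ν; ash) = baseline + Σ_bands (slope·ash + jitter)·G(ν; center, width)`.

Four Gaussian bands at 0.30, 0.55, 0.80 and 1.05 THz carry the ash signal —
the region where mineral collective-vibration and phonon-resonance modes
absorb — plus one *decoy* band at 2.0 THz whose amplitude varies randomly
per sample, independent of ash. The decoy contributes exactly the kind of
response-free spectral variance that variance-driven methods (PCR, and
Kennard–Stone distances) can be misled by, and that supervised selectors
must learn to exclude.

Two calibrated constants set the difficulty, chosen once and frozen:

* `noise_sd = 6e-5` (time-domain, per replicate, unit-peak pulse) puts the
  peak spectral dynamic range near 70 dB — the class of instrument being
  emulated;
* `slope = 0.35 cm⁻¹` per % ash makes the ash-feature signal-to-noise ratio
  (band-center α span across the ash range over the post-averaging α noise
  sd) ≈ 20 at the informative band centers (13–31 across the four bands).

The reference pulse is a band-limited, zero-mean pulse whose magnitude is
super-Gaussian in log-frequency (8th power, peak at 0.75 THz, separate
low/high edge constants). A first-derivative Gaussian — the textbook
idealisation — cannot simultaneously keep the 0.25–3 THz interior 40 dB
above this noise floor *and* fall below a 10 dB SNR at the 0.1 and 4.5 THz
grid edges; the steep log-frequency edges deliver both, and concentrate
the unusable 10–40 dB transition into a few bins so that the screened band
is predominantly high-SNR, mirroring instruments on which full-spectrum
absorption modelling is serviceable.

What the generator does **not** emulate: polyethylene binder scattering,
etalon echoes, humidity lines (measurements are modelled as dry-air),
instrument drift, cultivar-specific spectral structure beyond ash, and any
nonlinearity in the ash–absorption link. Passing tests therefore
demonstrate correctness of the machinery and recoverability under a known
linear forward model — not performance on real flour. One consequence is
visible in every simulated report: calibrations are *cleaner* than the
real-world ones (RPD in the twenties rather than ~5), because the only
obstacles are white noise, the decoy and band-edge amplification.

Seeding is counter-based: one master seed, with per-sample and
per-replicate streams derived by counter, so cohort content is independent
of iteration order and any subset of samples is reproducible.

## Partitioning

`stratified_split()` fixes the *global* calibration size to the nearest
integer of `n·ratio/(ratio+1)` and allocates it to cultivar strata by
largest remainder — this guarantees 137/46 at n = 183 regardless of stratum
sizes, which independent per-stratum rounding would not. Kennard–Stone then
runs inside each stratum: seed with the farthest pair, repeatedly add the
sample maximising the minimum distance to the selected set, ties to the
lowest row index; fully deterministic.

Two honest caveats, both verified on simulated cohorts. First, KS covers
the *spectral* space; it concentrates on the ash range only insofar as
spectral distance is ash-aligned, and band-edge noise or decoy variance
weakens that alignment. Second, even on an ash-aligned space,
zero-tolerance range bracketing at n = 183 hinges on which of two
nearly-identical extreme samples the noise favours. What the method
delivers — and what the tests assert — is the quantified version: per
stratum, the calibration range covers the prediction range to within 2% of
the stratum span (validation stays in interpolation mode) in well over 80%
of strata.

Tukey outlier flags use type-7 (linear-interpolation) quartiles with 1.5 ×
IQR fences; flagged samples are reported, never removed. The two-sample t
test defaults to pooled variance, with Welch as an option.

## Preprocessing

Savitzky–Golay filters are built as explicit weight matrices from local
least-squares polynomial fits; edges use the window truncated to the
available points (with the order reduced if necessary). The "3-point
average" smoother is SG window 3, order 1 — the only reading that smooths
at all, since window 3 with the conventional order 2 is the identity.
Derivatives are taken with respect to the frequency axis (per-THz units)
with default window 5 / order 2. MSC regresses each spectrum on the
calibration-set mean — frozen for the prediction set, so no held-out
statistic leaks. SNV scales each spectrum by its own sd; spectra with sd
below 1e-12 produce non-finite rows that are *reported*, and every model
fitter refuses a matrix whose `assert_finite()` report is non-empty. This
is deliberate: the classic failure mode of SNV and second derivatives on
noise-dominated spectral regions is a silently NaN-poisoned feature matrix,
and the package converts it into a structured, named refusal.

## Frequency selectors

All four selectors consume calibration rows only and share a fixed
cross-validation fold assignment (seeded independently of their Monte Carlo
streams) so their RMSECV values are comparable.

**CARS.** Each of `n_runs` (default 100) Monte Carlo runs fits a PLS model
on a random 80% row subset of the retained variables (latent variables by
inner 5-fold CV), weights variables by normalised |coefficients|, applies
enforced elimination to the top `⌈r_i·p⌉` weights — `r_i` decaying
exponentially from all `p` at run 1 to 2 at the last run — and then redraws
the retained set by `p` weighted samples with replacement, so the survivor
count tracks the decay schedule while low-weight variables drop out. Each
run's subset is scored by 10-fold RMSECV on the full calibration set. The
returned run is, by default, the *fewest-variable* run within one standard
error of the minimum RMSECV (`tie_rule = "one_se"`): fully pruned runs sit
on a flat RMSECV plateau on which strict argmin systematically returns the
largest subset, defeating the purpose of selection; the strict rule remains
available and is what the "best iteration attains the trace minimum"
invariant is stated under.

**SPA** grows, from every start variable, a chain by maximal projection
onto the orthogonal complement of the chain so far, then scores every
(start, size) candidate with cross-validated OLS error; ties (within 1e-10)
go to fewer variables, then the earlier start. It is fully deterministic —
fold assignment is sequential.

**GA** evolves binary chromosomes with tournament selection, single-point
crossover, bit-flip mutation and elitism of one, fitness being negative
PLS RMSECV; after the final generation, variables whose selection frequency
across the population falls inside `[freq_lower, freq_upper]` (defaults
0.3–1.0; the two-threshold retention rule) are kept, falling back to the
best chromosome with a warning if the window is empty.

**BOSS** repeatedly draws variable subsets by weighted bootstrap sampling,
fits PLS sub-models, and replaces the sampling weights with the normalised
summed |coefficients| of the best 10% of sub-models — soft shrinkage, no
forced elimination. The cap of 2000 iterations is honoured, but iteration
stops once the count of sampleable variables stabilises (relative change
below 1e-3 over 10 iterations), which at desk scale happens within tens of
iterations; both knobs are exposed because "iterations" in this family is
sometimes counted in sub-models rather than outer sweeps.

## Regression models

PLS1 is NIPALS on column-centered data (no unit-variance scaling —
absorption spectra share units), single response so without y-deflation,
returning the full coefficient path so one fit per fold scores every
latent-variable count; the count is the k-fold RMSECV minimiser. MLR is OLS
with an intercept behind two guards — `p < n` and a centered cross-product
condition number below 1e10 — that turn the method's well-known fragility
under multicollinearity into a refusal with the reason named. PCR keeps the
smallest component count reaching 95% cumulative explained variance (a
cross-validation-chosen count is available as an option, since
variance-based and CV-based component selection are both in common use and
reports rarely state which was meant). SVR z-scores the spectra internally, fixes
the ε-tube at 0.01·sd(y), and grid-searches integer powers of two,
C ∈ 2⁻⁵…2¹⁰ and γ ∈ 2⁻¹⁰…2⁵ (16 × 16 = 256 pairs), by 10-fold RMSECV with
ties to the smaller C then smaller γ.

`cross_validate()` re-runs the entire fitting pipeline inside every fold —
centering, scaling, latent-variable and hyperparameter choice — so no
fold-test statistic leaks into fold-training; a canary test corrupts the
prediction rows and asserts bit-identical calibration results.

## Evaluation

Rc and Rp are implemented in coefficient-of-determination form, `1 − SSres/SStot`, with each set's own reference mean;
because the label "correlation coefficient" is ambiguous, Pearson
correlations are reported alongside (`rc_pearson`, `rp_pearson`).
Calibration predictions are out-of-fold CV predictions by default (Rc pairs
with RMSECV), with an in-sample option (`rc_mode = "fit"`) since published
tables are often ambiguous on this point. `SD_pred` uses the sample (m−1)
convention. RPD grades: `< 1.5` not usable, `[1.5, 2.0)` rough,
`[2.0, 2.5)` quantitative, `≥ 2.5` excellent; a zero RMSEP reports RPD as
`Inf`, graded excellent.

## Problem sizes used in validation

The test suite and the acceptance script validate at the following scales,
chosen to exercise the stated study conditions while remaining desk-sized:
optical round trips on 20 random noiseless 4-sample configurations;
selector recovery on 20 seeded planted cohorts (100 × 200, five informative
bands + one decoy, per-point feature SNR 20) with CARS at 50 runs, BOSS at
40 sub-models × ≤ 20 iterations with 5-fold scoring, GA at population 24 ×
30 generations; and the full pipeline on 10 seeded 183-sample cohorts with
default CARS (100 runs, 10-fold). On such cohorts SG-CARS-PLSR reaches
Rp ≈ 0.998 with RPD ≈ 20–30 and all chosen frequencies inside the
0.2–1.1 THz mineral region, while full-spectrum PCR at the 95% variance
threshold spends its components on the decoy band and predicts at chance —
the designed illustration of variance-versus-relevance. PLSR, MLR and SVR
on CARS-selected variables are statistically tied on this generator
(differences in the fourth decimal of Rp): once selection isolates clean
linear features, any sensible regressor is near-perfect, so the
linear-versus-nonlinear separations reported on real flour should be
expected to reappear only with real-data imperfections.

## Known limitations

* The forward model is linear and additive-Gaussian; none of the pellet
  physics (scattering, etalon, humidity) is emulated.
* Band-edge absorption noise is intrinsic to any amplitude-SNR screen; the
  30 dB pipeline default is a deliberate, documented trade — looser floors
  admit α noise that can destabilise full-spectrum weight models.
* Strict concentration-range bracketing by Kennard–Stone is not a
  guarantee; only the 2%-tolerance interpolation-mode property is.
* The GA retention thresholds (0.3/1.0) and the BOSS stabilisation rule are
  package choices where the underlying conventions are unstated; both are
  exposed as parameters.
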