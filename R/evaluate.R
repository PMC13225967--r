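# Model evaluation: the six chemometric indicators (Rc, RMSECV, Rp, RMSEP,
# RPD, Bias), RPD grading, comparison reports and the end-to-end pipeline.

#' Evaluation metrics for one calibration/prediction pair
#'
#' For the calibration set (reference values and out-of-fold cross-validation
#' predictions) computes Rc = 1 - SSres/SStot and RMSECV = sqrt(mean(e^2));
#' for the prediction set, Rp and RMSEP analogously, plus
#' RPD = SD_pred / RMSEP (SD_pred the sample standard deviation of the
#' prediction-set reference values), Bias = mean(y_a - y_p), and the RPD
#' grade. Because the coefficient-of-determination form of Rc/Rp can differ
#' from a Pearson correlation, both are reported (`rc_pearson`,
#' `rp_pearson`).
#'
#' @param cal data frame with columns `y_a` (reference) and `y_p`
#'   (cross-validated predictions) for the calibration set.
#' @param pred data frame with columns `y_a` and `y_p` for the prediction
#'   set.
#' @param combination optional label (e.g. "SG-CARS-PLSR").
#' @param hyper optional label for the model complexity (LVs or
#'   hyperparameters).
#' @return a one-row tibble of class `thz_report` with columns `combination`,
#'   `LVs_or_hparams`, `Rc`, `RMSECV`, `Rp`, `RMSEP`, `RPD`, `Bias`, `grade`,
#'   `rc_pearson`, `rp_pearson`, `n_cal`, `m_pred`.
#' @export
compute_metrics <- function(cal, pred, combination = NA_character_,
                            hyper = NA_character_) {
  stopifnot(all(c("y_a", "y_p") %in% names(cal)),
            all(c("y_a", "y_p") %in% names(pred)),
            nrow(cal) >= 2, nrow(pred) >= 2)
  r2 <- function(y_a, y_p) {
    sstot <- sum((y_a - mean(y_a))^2)
    if (sstot <= 0) abort_config("all reference values equal: R is undefined.")
    1 - sum((y_a - y_p)^2) / sstot
  }
  rc <- r2(cal$y_a, cal$y_p)
  rmsecv <- sqrt(mean((cal$y_a - cal$y_p)^2))
  rp <- r2(pred$y_a, pred$y_p)
  rmsep <- sqrt(mean((pred$y_a - pred$y_p)^2))
  sd_pred <- stats::sd(pred$y_a)
  rpd <- if (rmsep == 0) Inf else sd_pred / rmsep
  bias <- mean(pred$y_a - pred$y_p)
  safe_cor <- function(a, b) if (stats::sd(b) > 0) stats::cor(a, b) else NA_real_
  out <- tibble::tibble(
    combination = combination, LVs_or_hparams = hyper,
    Rc = rc, RMSECV = rmsecv, Rp = rp, RMSEP = rmsep,
    RPD = rpd, Bias = bias, grade = rpd_grade(rpd),
    rc_pearson = safe_cor(cal$y_a, cal$y_p),
    rp_pearson = safe_cor(pred$y_a, pred$y_p),
    n_cal = nrow(cal), m_pred = nrow(pred)
  )
  class(out) <- c("thz_report", class(out))
  out
}

#' Grade a ratio of performance to deviation
#'
#' Below 1.5 the model is not usable; 1.5 to below 2.0 indicates rough
#' prediction capability; 2.0 to below 2.5 means quantitatively applicable;
#' 2.5 or higher signifies excellent performance. Boundaries are
#' lower-inclusive.
#'
#' @param rpd non-negative RPD value (may be `Inf`).
#' @return character vector in
#'   `c("not_usable", "rough", "quantitative", "excellent")`.
#' @export
rpd_grade <- function(rpd) {
  if (any(!is.na(rpd) & rpd < 0)) abort_config("RPD must be non-negative.")
  dplyr::case_when(
    is.na(rpd) ~ NA_character_,
    rpd >= 2.5 ~ "excellent",
    rpd >= 2.0 ~ "quantitative",
    rpd >= 1.5 ~ "rough",
    TRUE ~ "not_usable"
  )
}

#' Combine evaluation reports into a comparison table
#'
#' Binds one-row reports, keeps the canonical column order and flags the best
#' row (lowest RMSEP, ties broken by highest Rp).
#'
#' @param reports list of `thz_report` rows (or a pre-bound tibble).
#' @return tibble with a logical `best` column.
#' @export
build_report <- function(reports) {
  if (inherits(reports, "data.frame")) reports <- list(reports)
  if (length(reports) == 0) abort_config("no reports to combine.")
  tab <- dplyr::bind_rows(reports)
  ord <- order(tab$RMSEP, -tab$Rp)
  tab$best <- seq_len(nrow(tab)) == ord[1]
  front <- c("combination", "LVs_or_hparams", "Rc", "RMSECV", "Rp", "RMSEP",
             "RPD", "Bias", "grade")
  tab <- dplyr::relocate(tab, dplyr::all_of(front))
  class(tab) <- c("thz_report", class(tab))
  tab
}

#' Write a comparison report as CSV and JSON
#'
#' @param report tibble from [build_report()] or [compute_metrics()].
#' @param path output path without extension (writes `<path>.csv` and
#'   `<path>.json`).
#' @export
write_report <- function(report, path) {
  readr::write_csv(report, paste0(path, ".csv"))
  jsonlite::write_json(report, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---- end-to-end pipeline ---------------------------------------------------

#' Pipeline configuration
#'
#' @param simulate a [cohort_config()] (or NULL when `cohort_dir` is given).
#' @param cohort_dir directory with a written cohort, read instead of
#'   simulating.
#' @param dataset which spectral dataset to model (default `"absorption"`).
#' @param snr_floor_db valid-band SNR threshold (dB). The pipeline default of
#'   30 dB is stricter than the screening op's 10 dB default because the
#'   absorption coefficient inherits the *relative* amplitude error amplified
#'   by 2/d: a 10 dB amplitude SNR (~30% error) maps to several cm^-1 of
#'   absorption noise, far above any mineral signature, whereas 30 dB keeps
#'   the absorption noise at the band edge usable.
#' @param preprocess a [preprocess_spec()].
#' @param split_ratio calibration:prediction ratio.
#' @param selector `"none"`, `"SPA"`, `"CARS"`, `"GA"` or `"BOSS"`.
#' @param selector_args list of extra arguments for the selector.
#' @param model `"PLSR"`, `"MLR"`, `"PCR"` or `"SVR"`.
#' @param model_args list of extra arguments for the fitter.
#' @param cv_folds folds for model selection and calibration metrics.
#' @param rc_mode `"cv"` (calibration predictions are out-of-fold, default)
#'   or `"fit"` (in-sample refit predictions).
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = cohort_config(), cohort_dir = NULL,
                            dataset = "absorption", snr_floor_db = 30,
                            preprocess = preprocess_spec("SG"),
                            split_ratio = 3,
                            selector = "CARS", selector_args = list(),
                            model = "PLSR", model_args = list(),
                            cv_folds = 10, rc_mode = c("cv", "fit"),
                            seed = 1) {
  rc_mode <- match.arg(rc_mode)
  structure(
    list(simulate = simulate, cohort_dir = cohort_dir, dataset = dataset,
         snr_floor_db = snr_floor_db, preprocess = preprocess,
         split_ratio = split_ratio, selector = selector,
         selector_args = selector_args, model = model,
         model_args = model_args, cv_folds = cv_folds, rc_mode = rc_mode,
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalar fields override the [pipeline_config()] defaults; `simulate` and
#' `preprocess` sub-lists override the corresponding constructor defaults.
#'
#' @param path a .yaml/.yml or .json file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      abort_config("the yaml package is needed to read YAML configs.")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  args <- raw
  if (!is.null(raw$simulate)) args$simulate <- do.call(cohort_config, raw$simulate)
  if (!is.null(raw$preprocess)) args$preprocess <- do.call(preprocess_spec, raw$preprocess)
  do.call(pipeline_config, args)
}

abort_stage <- function(stage, msg, ...) {
  rlang::abort(sprintf("pipeline stage '%s' failed: %s", stage, msg),
               class = "thzash_pipeline_error", stage = stage, ...)
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load -> Fourier transform -> valid-band screen ->
#' optical-parameter extraction -> stratified Kennard-Stone split ->
#' preprocessing -> characteristic-frequency selection -> model fit ->
#' evaluation, with the hold-out discipline throughout: the split happens
#' before preprocessing and selection, preprocessing statistics are frozen
#' from the calibration set, and selectors and model selection see
#' calibration rows only. A preprocessing step that produces non-finite
#' values aborts at the finiteness gate with a classed error carrying the
#' diagnostic report (no silent NaN propagation into a metrics row).
#'
#' @param config a [pipeline_config()] or a path to a YAML/JSON file.
#' @return list with `report` (one-row metrics tibble), and `artifacts`
#'   (cohort, band screen, split, selection result, fitted model,
#'   predictions).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  cohort <- if (!is.null(config$cohort_dir)) {
    read_cohort(config$cohort_dir)
  } else {
    cfg <- config$simulate
    cfg$seed <- seed
    generate_cohort(cfg)
  }

  optics <- tryCatch(
    extract_optics(cohort, snr_floor_db = config$snr_floor_db),
    thzash_empty_band = function(e) abort_stage("screen_valid_band", conditionMessage(e))
  )
  ds <- optics$datasets[[config$dataset]]
  if (is.null(ds)) abort_stage("extract", sprintf("unknown dataset '%s'", config$dataset))
  X <- dataset_matrix(ds)
  freq_band <- ds$freq_THz[ds$valid_mask]
  raw_gate <- assert_finite(X)
  if (nrow(raw_gate) > 0) {
    abort_stage("assert_finite",
                sprintf("the %s dataset contains %d non-finite entries inside the valid band; refusing to continue.",
                        config$dataset, nrow(raw_gate)),
                report = raw_gate)
  }

  samples <- cohort$samples[match(rownames(X), cohort$samples$sample_id), ]
  split <- stratified_split(X, samples, ratio = config$split_ratio)
  cal <- split$assignment$set == "calibration"
  y <- samples$ash_true

  pp <- apply_preprocess(config$preprocess, X[cal, , drop = FALSE],
                         X[!cal, , drop = FALSE], x = freq_band)
  gate <- dplyr::bind_rows(assert_finite(pp$cal), assert_finite(pp$pred))
  if (nrow(gate) > 0 || nrow(pp$diagnostics) > 0) {
    abort_stage("assert_finite",
                sprintf("preprocessing '%s' produced %d non-finite entries (%d degenerate spectra); model fitting refused.",
                        config$preprocess$method, nrow(gate), nrow(pp$diagnostics)),
                report = gate, diagnostics = pp$diagnostics)
  }
  X_cal <- pp$cal
  X_pred <- pp$pred
  y_cal <- y[cal]
  y_pred <- y[!cal]

  selection <- switch(config$selector,
    none = NULL,
    CARS = do.call(cars_select, c(list(X = X_cal, y = y_cal, seed = seed,
                                       freq = freq_band), config$selector_args)),
    SPA  = do.call(spa_select, c(list(X = X_cal, y = y_cal, freq = freq_band),
                                 config$selector_args)),
    GA   = do.call(ga_select, c(list(X = X_cal, y = y_cal, seed = seed,
                                     freq = freq_band), config$selector_args)),
    BOSS = do.call(boss_select, c(list(X = X_cal, y = y_cal, seed = seed,
                                       freq = freq_band), config$selector_args)),
    abort_stage("select", sprintf("unknown selector '%s'", config$selector))
  )
  vars <- if (is.null(selection)) seq_len(ncol(X_cal)) else selection$chosen
  Xc <- X_cal[, vars, drop = FALSE]
  Xp <- X_pred[, vars, drop = FALSE]

  cv <- cv_spec(config$cv_folds, seed = derive_seed(seed, 401))
  fitter <- switch(config$model,
    PLSR = function(X, y) do.call(fit_plsr, c(list(X = X, y = y, cv = cv), config$model_args)),
    MLR  = function(X, y) do.call(fit_mlr, c(list(X = X, y = y), config$model_args)),
    PCR  = function(X, y) do.call(fit_pcr, c(list(X = X, y = y), config$model_args)),
    SVR  = function(X, y) do.call(fit_svr, c(list(X = X, y = y, cv = cv), config$model_args)),
    abort_stage("fit", sprintf("unknown model '%s'", config$model))
  )
  model <- fitter(Xc, y_cal)
  cal_pred <- if (config$rc_mode == "cv") {
    cross_validate(fitter, Xc, y_cal, cv = cv)$predictions
  } else {
    stats::predict(model, Xc)
  }
  pred_pred <- stats::predict(model, Xp)

  hyper <- switch(config$model,
    PLSR = sprintf("%d LVs", model$n_lv),
    PCR = sprintf("%d PCs", model$n_pc),
    SVR = sprintf("C=%g, gamma=%g", model$cost, model$gamma),
    MLR = sprintf("%d vars", length(model$coefficients))
  )
  label <- paste(config$preprocess$method, config$selector, config$model, sep = "-")
  report <- compute_metrics(
    cal = tibble::tibble(y_a = y_cal, y_p = cal_pred),
    pred = tibble::tibble(y_a = y_pred, y_p = pred_pred),
    combination = label, hyper = hyper
  )
  list(report = report,
       artifacts = list(cohort = cohort, band = optics$band, split = split,
                        selection = selection, model = model,
                        matrices = list(X_cal = X_cal, X_pred = X_pred,
                                        y_cal = y_cal, y_pred = y_pred,
                                        chosen = vars, freq = freq_band),
                        predictions = tibble::tibble(
                          sample_id = samples$sample_id[!cal],
                          y_a = y_pred, y_p = pred_pred)))
}
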