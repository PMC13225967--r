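# Plain-text cohort serialization: one two-column CSV per trace, a samples.csv
# metadata table and the generating configuration as JSON.

#' Write a cohort to a directory
#'
#' Writes `trace_<id>_r<rep>.csv` files (header `time_ps,amplitude`), the
#' replicate reference traces as `trace_REF_r<rep>.csv`, `samples.csv`
#' (header `sample_id,cultivar,ash_true,thickness_mm,set`) and `config.json`.
#' Refuses to touch a directory that already holds a cohort unless
#' `overwrite = TRUE`.
#'
#' @param cohort a `thz_cohort`.
#' @param dir target directory (created if missing).
#' @param overwrite allow replacing an existing cohort.
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "thz_cohort"))
  if (file.exists(file.path(dir, "samples.csv")) && !overwrite) {
    rlang::abort(
      sprintf("directory '%s' already contains a cohort; use overwrite = TRUE.", dir),
      class = "thzash_exists"
    )
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)

  write_one <- function(df) {
    path <- file.path(dir, sprintf("trace_%s_r%d.csv", df$sample_id[1], df$replicate[1]))
    readr::write_csv(df[, c("time_ps", "amplitude")], path)
    path
  }
  all_traces <- dplyr::bind_rows(cohort$traces, cohort$reference)
  paths <- all_traces |>
    dplyr::group_by(.data$sample_id, .data$replicate) |>
    dplyr::group_map(~ write_one(dplyr::bind_cols(.y, .x)))
  written <- c(written, unlist(paths))

  readr::write_csv(cohort$samples, file.path(dir, "samples.csv"))
  cfg <- cohort$config
  cfg$cultivars <- as.data.frame(cfg$cultivars)
  cfg$mineral_bands <- as.data.frame(cfg$mineral_bands)
  jsonlite::write_json(unclass(cfg), file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(cohort$band_effects, file.path(dir, "band_effects.csv"))
  written <- c(written, file.path(dir, c("samples.csv", "config.json", "band_effects.csv")))
  invisible(written)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory holding the cohort files.
#' @return a `thz_cohort`.
#' @export
read_cohort <- function(dir) {
  samples_path <- file.path(dir, "samples.csv")
  if (!file.exists(samples_path)) {
    rlang::abort(sprintf("no cohort found in '%s' (missing samples.csv).", dir),
                 class = "thzash_io")
  }
  samples <- readr::read_csv(samples_path, show_col_types = FALSE)
  cfg <- jsonlite::read_json(file.path(dir, "config.json"), simplifyVector = TRUE)
  cfg$cultivars <- tibble::as_tibble(cfg$cultivars)
  cfg$mineral_bands <- tibble::as_tibble(cfg$mineral_bands)
  config <- do.call(cohort_config, cfg[setdiff(names(cfg), character(0))])

  files <- list.files(dir, pattern = "^trace_.*\\.csv$", full.names = TRUE)
  meta <- regmatches(basename(files), regexec("^trace_(.*)_r(\\d+)\\.csv$", basename(files)))
  traces <- dplyr::bind_rows(lapply(seq_along(files), function(k) {
    df <- readr::read_csv(files[k], show_col_types = FALSE)
    tibble::tibble(sample_id = meta[[k]][2],
                   replicate = as.integer(meta[[k]][3]),
                   time_ps = df$time_ps, amplitude = df$amplitude)
  }))
  traces <- dplyr::arrange(traces, .data$sample_id, .data$replicate, .data$time_ps)
  reference <- dplyr::filter(traces, .data$sample_id == "REF")
  traces <- dplyr::filter(traces, .data$sample_id != "REF")

  band_effects <- readr::read_csv(file.path(dir, "band_effects.csv"),
                                  show_col_types = FALSE)
  structure(
    list(samples = samples, traces = traces, reference = reference,
         band_effects = band_effects, config = config),
    class = "thz_cohort"
  )
}
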