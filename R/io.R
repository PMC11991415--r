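#' Read a spectra CSV
#'
#' Schema: one row per (leaf, sensor, replicate) with columns `leaf_id`,
#' `species`, `sensor`, `replicate`, `led`, `integration_ms`, `current_ma`
#' followed by one count column per channel named by center wavelength
#' (`ch_450`, ...). Comma-separated, UTF-8, header row, dot decimals.
#'
#' @param path CSV file path.
#' @param layout The expected `sensor_layout`.
#' @return Tibble of validated readings in file order.
#' @export
read_spectra <- function(path, layout) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_spectra(tbl, layout)
}

id_columns <- c("leaf_id", "species", "sensor", "replicate", "led",
                "integration_ms", "current_ma")

validate_spectra <- function(tbl, layout) {
  missing <- setdiff(id_columns, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing columns: ", paste(missing, collapse = ", ")),
                 class = "chlorocal_missing_columns")
  }
  labels <- channel_labels(layout)
  ch_cols <- grep("^ch_", names(tbl), value = TRUE)
  if (!identical(sort(ch_cols), sort(labels))) {
    rlang::abort(sprintf(
      "Expected %d channel columns for layout %s, found %d.",
      length(labels), layout$name, length(ch_cols)),
      class = "chlorocal_channel_count")
  }
  if (!all(tbl$sensor == layout$name)) {
    rlang::abort(paste0("Sensor column does not match layout ", layout$name),
                 class = "chlorocal_unknown_sensor")
  }
  counts <- as.matrix(tbl[labels])
  if (any(!is.finite(counts)) || any(counts < 0)) {
    rlang::abort("Raw counts must be finite and non-negative.",
                 class = "chlorocal_negative_counts")
  }
  if (!all(tbl$replicate %in% 1:3)) {
    rlang::abort("Replicate must be 1, 2 or 3.",
                 class = "chlorocal_bad_replicate")
  }
  tbl[c(id_columns, labels)]
}

#' Write a spectra CSV
#'
#' @param readings Tibble of readings (see [read_spectra()] for the schema).
#' @param path Output path.
#' @export
write_spectra <- function(readings, path) {
  readr::write_csv(readings, path)
  invisible(path)
}

#' Read a reference-chlorophyll CSV
#'
#' Accepts either per-disk per-area chlorophyll (`leaf_id`, `species`,
#' `disk`, `chl`) or raw absorbance pairs (`leaf_id`, `species`, `disk`,
#' `a647`, `a664`), which are converted through the DMF extract equation
#' and the assay geometry. An optional logical `excluded` column is
#' preserved; every leaf must retain at least one usable disk.
#'
#' @param path CSV file path.
#' @param assay Assay geometry for the absorbance form
#'   ([reference_assay()]).
#' @return Tibble `leaf_id`, `species`, `disk`, `chl`, `excluded`.
#' @export
read_references <- function(path, assay = reference_assay()) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  base <- c("leaf_id", "species", "disk")
  missing <- setdiff(base, names(tbl))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing columns: ", paste(missing, collapse = ", ")),
                 class = "chlorocal_missing_columns")
  }
  if (all(c("a647", "a664") %in% names(tbl))) {
    out <- reference_table(tbl, assay)
  } else if ("chl" %in% names(tbl)) {
    out <- tbl[c(base, "chl")]
  } else {
    rlang::abort("References need either `chl` or `a647`/`a664` columns.",
                 class = "chlorocal_missing_columns")
  }
  out$excluded <- if ("excluded" %in% names(tbl)) as.logical(tbl$excluded)
    else FALSE
  usable <- tapply(!out$excluded, out$leaf_id, any)
  if (any(!usable)) {
    rlang::abort(paste0("Leaves with no usable disks: ",
                        paste(names(usable)[!usable], collapse = ", ")),
                 class = "chlorocal_empty_reference")
  }
  out
}

#' Write a reference-chlorophyll CSV
#'
#' @param references Tibble with `leaf_id`, `species`, `disk` and `chl`
#'   (and optionally `excluded`).
#' @param path Output path.
#' @export
write_references <- function(references, path) {
  readr::write_csv(references, path)
  invisible(path)
}

#' Write an outlier report CSV
#'
#' @param outliers Output of [detect_spectral_outliers()] plus a `sensor`
#'   column if available.
#' @param path Output path.
#' @export
write_outlier_report <- function(outliers, path) {
  readr::write_csv(outliers, path)
  invisible(path)
}
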