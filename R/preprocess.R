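#' Convert raw counts to reflectance
#'
#' Reflectance is the channel-wise ratio of a leaf reading to the
#' white-reference reading taken in the same session, `R = measured / ref`.
#'
#' @param measured Numeric vector of raw counts for one reading.
#' @param reference Numeric vector of raw white-reference counts, same length.
#' @return Numeric vector of unitless reflectance values.
#' @export
to_reflectance <- function(measured, reference) {
  if (length(measured) != length(reference)) {
    rlang::abort("`measured` and `reference` must have the same length.",
                 class = "chlorocal_channel_count")
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    rlang::abort("Every white-reference channel must be positive.",
                 class = "chlorocal_degenerate_reference")
  }
  measured / reference
}

#' Convert reflectance to absorbance
#'
#' `A = -log10(R)`, channel-wise.
#'
#' @param reflectance Numeric vector of positive reflectance values.
#' @return Numeric vector of absorbances.
#' @export
to_absorbance <- function(reflectance) {
  if (any(!is.finite(reflectance)) || any(reflectance <= 0)) {
    rlang::abort("Absorbance requires strictly positive reflectance.",
                 class = "chlorocal_nonpositive_reflectance")
  }
  -log10(reflectance)
}

#' Total chlorophyll concentration from DMF-extract absorbances
#'
#' Computes the total chlorophyll concentration of a dimethylformamide leaf
#' extract from its absorbances at 647 nm and 664 nm:
#' `0.18 * (20.27 * A647 + 7.04 * A664)` in micrograms per millilitre. The
#' leading factor folds the cuvette path length and the dilution of the
#' extract into the published absorption coefficients, so it multiplies both
#' terms.
#'
#' @param a647,a664 Non-negative absorbances at 647 nm and 664 nm
#'   (vectorized).
#' @return Concentration in ug/mL.
#' @export
total_chlorophyll <- function(a647, a664) {
  if (any(a647 < 0) || any(a664 < 0)) {
    rlang::abort("Absorbances must be non-negative.",
                 class = "chlorocal_negative_absorbance")
  }
  0.18 * (20.27 * a647 + 7.04 * a664)
}

#' Per-area chlorophyll from extract concentration
#'
#' Converts an extract concentration to leaf-area basis given the extraction
#' volume and the total punched disk area dissolved in it:
#' `concentration * volume / area`.
#'
#' @param concentration Chlorophyll concentration in ug/mL.
#' @param extract_volume Extraction solvent volume in mL.
#' @param disk_area Total leaf-disk area in cm^2.
#' @return Chlorophyll in ug/cm^2.
#' @export
per_area_chlorophyll <- function(concentration, extract_volume, disk_area) {
  if (extract_volume <= 0 || disk_area <= 0) {
    rlang::abort("Extract volume and disk area must be positive.",
                 class = "chlorocal_bad_assay"
    )
  }
  concentration * extract_volume / disk_area
}

#' Reference assay geometry
#'
#' Defaults describe one extraction per disk measurement: three 6 mm-diameter
#' punches (0.28 cm^2 each) pooled in 5 mL of DMF. Used to convert between
#' per-area chlorophyll and extract absorbances.
#'
#' @param extract_volume_ml Solvent volume per extraction, mL.
#' @param disk_area_cm2 Total punched area per extraction, cm^2.
#' @param a_ratio Ratio A647/A664 used when synthesizing absorbance pairs
#'   (typical chlorophyll a/b mixtures give roughly 0.4).
#' @return A list with the three fields.
#' @export
reference_assay <- function(extract_volume_ml = 5,
                            disk_area_cm2 = 3 * 0.28,
                            a_ratio = 0.4) {
  stopifnot(extract_volume_ml > 0, disk_area_cm2 > 0, a_ratio > 0)
  list(extract_volume_ml = extract_volume_ml,
       disk_area_cm2 = disk_area_cm2,
       a_ratio = a_ratio)
}

#' Normalize a table of raw spectra against a white reference
#'
#' @param readings Tibble of raw readings with channel columns named as in
#'   the layout (see [read_spectra()]).
#' @param reference Named numeric vector of white-reference counts, one per
#'   channel label.
#' @param layout The `sensor_layout` the readings belong to.
#' @return The same tibble with channel columns replaced by reflectance.
#' @export
normalize_spectra <- function(readings, reference, layout) {
  labels <- channel_labels(layout)
  if (!all(labels %in% names(readings))) {
    rlang::abort("Readings are missing channel columns for this layout.",
                 class = "chlorocal_missing_columns")
  }
  ref <- reference[labels]
  if (any(is.na(ref))) {
    rlang::abort("Reference is missing channels required by the layout.",
                 class = "chlorocal_missing_columns")
  }
  if (any(ref <= 0)) {
    rlang::abort("Every white-reference channel must be positive.",
                 class = "chlorocal_degenerate_reference")
  }
  out <- readings
  out[labels] <- sweep(as.matrix(readings[labels]), 2, ref, "/")
  out
}

#' Per-disk reference chlorophyll table from absorbance pairs
#'
#' Applies the DMF extract equation and the assay geometry to each disk's
#' (A647, A664) pair, yielding per-area chlorophyll per disk.
#'
#' @param references Tibble with columns `leaf_id`, `species`, `disk`,
#'   `a647`, `a664`.
#' @param assay Assay geometry from [reference_assay()].
#' @return Tibble with columns `leaf_id`, `species`, `disk`, `chl` (ug/cm^2).
#' @export
reference_table <- function(references, assay = reference_assay()) {
  conc <- total_chlorophyll(references$a647, references$a664)
  tibble::tibble(
    leaf_id = references$leaf_id,
    species = references$species,
    disk = references$disk,
    chl = per_area_chlorophyll(conc, assay$extract_volume_ml,
                               assay$disk_area_cm2)
  )
}
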