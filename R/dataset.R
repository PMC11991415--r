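#' Assemble a modeling dataset from a simulated or loaded population
#'
#' Runs the preprocessing chain for one sensor layout and one species:
#' white-reference normalization, replicate-residue (or full-spectrum)
#' Mahalanobis outlier removal, reference-disk outlier filtering, leaf-mean
#' reference chlorophyll, and global chlorophyll quantile bins for
#' stratified splitting. Leaves that lose all replicates to outlier removal
#' are dropped with a warning.
#'
#' @param population A `leaf_population` (see [simulate_population()]), or a
#'   compatible list with `spectra`, `references`, `reference_counts`,
#'   `layouts`, `assay`.
#' @param sensor Layout name (`"vis6"`, `"nir6"`, `"full18"`).
#' @param species Species to model (single label); default: the only species
#'   present.
#' @param outlier_mode `"residue"` (default), `"full"`, or `"none"`.
#' @param input `"reflectance"` (default) or `"absorbance"`.
#' @param n_bins Number of chlorophyll quantile bins for stratification.
#' @return An object of class `chl_data`: list with `x` (spectra matrix),
#'   `y` (reference chlorophyll per spectrum), `leaf` (leaf id per row),
#'   `leaf_chl` (named per-leaf reference values), `bins` (named bin per
#'   leaf), `layout`, `species`, `outliers` (the outlier report), `input`.
#' @export
build_modeling_data <- function(population, sensor,
                                species = NULL,
                                outlier_mode = c("residue", "full", "none"),
                                input = c("reflectance", "absorbance"),
                                n_bins = 10) {
  outlier_mode <- rlang::arg_match(outlier_mode)
  input <- rlang::arg_match(input)
  if (!sensor %in% names(population$spectra)) {
    rlang::abort(paste0("Unknown sensor layout: ", sensor),
                 class = "chlorocal_unknown_sensor")
  }
  layout <- population$layouts[[sensor]]
  readings <- population$spectra[[sensor]]
  refs <- population$references
  if (is.null(species)) {
    species <- unique(readings$species)
    if (length(species) > 1) {
      rlang::abort("Multiple species present; supply `species`.",
                   class = "chlorocal_bad_argument")
    }
  }
  readings <- readings[readings$species == species, , drop = FALSE]
  refs <- refs[refs$species == species, , drop = FALSE]
  if (nrow(readings) == 0) {
    rlang::abort(paste0("No readings for species: ", species),
                 class = "chlorocal_bad_argument")
  }

  refl <- normalize_spectra(readings, population$reference_counts[[sensor]],
                            layout)
  outliers <- NULL
  if (outlier_mode != "none") {
    outliers <- detect_spectral_outliers(refl, layout, mode = outlier_mode)
    keep <- !outliers$flagged
    dropped_leaves <- setdiff(unique(refl$leaf_id), unique(refl$leaf_id[keep]))
    if (length(dropped_leaves) > 0) {
      rlang::warn(paste0("Leaves dropped (all replicates flagged): ",
                         paste(dropped_leaves, collapse = ", ")))
    }
    refl <- refl[keep, , drop = FALSE]
  }

  disk_tbl <- filter_reference_outliers(
    reference_table(refs, population$assay)
  )
  leaf_refs <- leaf_reference_means(disk_tbl)
  leaf_chl <- stats::setNames(leaf_refs$mean_chl, leaf_refs$leaf_id)

  keep_leaves <- intersect(unique(refl$leaf_id), names(leaf_chl))
  refl <- refl[refl$leaf_id %in% keep_leaves, , drop = FALSE]
  leaf_chl <- leaf_chl[keep_leaves]

  labels <- channel_labels(layout)
  x <- as.matrix(refl[labels])
  if (input == "absorbance") x <- -log10(pmax(x, 1e-9))
  bins <- stats::setNames(quantile_bins(leaf_chl, n_bins), names(leaf_chl))

  structure(
    list(
      x = x,
      y = unname(leaf_chl[refl$leaf_id]),
      leaf = refl$leaf_id,
      leaf_chl = leaf_chl,
      bins = bins,
      layout = layout,
      species = species,
      outliers = outliers,
      input = input
    ),
    class = "chl_data"
  )
}

#' @export
print.chl_data <- function(x, ...) {
  cat(sprintf("<chl_data> %s/%s: %d spectra, %d leaves, %d channels (%s)\n",
              x$species, x$layout$name, nrow(x$x), length(x$leaf_chl),
              ncol(x$x), x$input))
  invisible(x)
}

#' Restrict a modeling dataset to a subset of leaves
#'
#' @param data A `chl_data`.
#' @param leaves Character vector of leaf ids to keep.
#' @return A `chl_data` containing only those leaves.
#' @export
subset_leaves <- function(data, leaves) {
  keep <- data$leaf %in% leaves
  out <- data
  out$x <- data$x[keep, , drop = FALSE]
  out$y <- data$y[keep]
  out$leaf <- data$leaf[keep]
  out$leaf_chl <- data$leaf_chl[names(data$leaf_chl) %in% leaves]
  out$bins <- data$bins[names(data$bins) %in% leaves]
  out
}
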