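#' Mahalanobis distances of spectra from their sample mean
#'
#' Computes `D = sqrt((x - mu)' Sigma^{-1} (x - mu))` per row, with `mu` the
#' column means and `Sigma` the sample covariance (n - 1 denominator). When
#' the covariance is ill-conditioned (condition number above
#' `ridge_condition`, common for strongly correlated NIR channels on small
#' subsets), a ridge of `1e-8 * trace(Sigma)/p` is added before inversion.
#'
#' @param x Numeric matrix, one spectrum per row.
#' @param ridge_condition Condition-number threshold above which the ridge
#'   engages.
#' @return Numeric vector of non-negative distances, one per row.
#' @export
mahalanobis_distances <- function(x, ridge_condition = 1e12) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 3) {
    rlang::abort("At least 3 spectra are needed for Mahalanobis distances.",
                 class = "chlorocal_insufficient_rows")
  }
  mu <- colMeans(x)
  sigma <- stats::cov(x)
  k <- tryCatch(kappa(sigma, exact = TRUE), error = function(e) Inf)
  if (!is.finite(k) || k > ridge_condition) {
    sigma <- sigma + diag(1e-8 * sum(diag(sigma)) / p, p)
  }
  d2 <- tryCatch(
    stats::mahalanobis(x, mu, sigma),
    error = function(e) {
      stats::mahalanobis(x, mu, sigma + diag(1e-8 * sum(diag(sigma)) / p, p))
    }
  )
  sqrt(pmax(d2, 0))
}

#' Replicate residue spectra
#'
#' For each leaf's triplicate, the residue of one replicate is that replicate
#' minus the mean of the other two. Residues isolate replicate-level
#' measurement error from genuine leaf-to-leaf spectral variation, so
#' distance-based screening on residues spares unusual but internally
#' consistent leaves (e.g. young leaves).
#'
#' @param reflectance Tibble of reflectance rows with `leaf_id`, `replicate`
#'   and the layout's channel columns.
#' @param layout The `sensor_layout`.
#' @return Tibble with `leaf_id`, `replicate` and channel columns holding the
#'   residues, ordered as the input.
#' @export
replicate_residues <- function(reflectance, layout) {
  labels <- channel_labels(layout)
  counts <- table(reflectance$leaf_id)
  bad <- names(counts)[counts != 3]
  if (length(bad) > 0) {
    rlang::abort(
      paste0("Residues need exactly 3 replicates per leaf; offending leaves: ",
             paste(bad, collapse = ", ")),
      class = "chlorocal_replicate_count"
    )
  }
  x <- as.matrix(reflectance[labels])
  # r_i = x_i - mean(others) = 1.5 * (x_i - leaf mean)
  leaf_mean <- rowsum(x, reflectance$leaf_id) / 3
  res <- 1.5 * (x - leaf_mean[reflectance$leaf_id, , drop = FALSE])
  out <- reflectance[c("leaf_id", "replicate")]
  out[labels] <- res
  out
}

#' Flag distances exceeding a 3-sigma cutoff
#'
#' A reading is flagged when its distance exceeds the mean distance plus
#' three standard deviations of the distances.
#'
#' @param distances Numeric vector of at least 3 distances.
#' @return Logical vector of flags.
#' @export
flag_outliers_3sigma <- function(distances) {
  if (length(distances) < 3) {
    rlang::abort("At least 3 distances are needed for a 3-sigma cutoff.",
                 class = "chlorocal_insufficient_rows")
  }
  distances > mean(distances) + 3 * stats::sd(distances)
}

#' Screen reflectance spectra for outliers
#'
#' Computes Mahalanobis distances per (sensor, species) dataset either on the
#' full reflectance spectra (`mode = "full"`) or on replicate residues
#' (`mode = "residue"`, the default used for data cleaning) and applies the
#' 3-sigma cutoff within each species group.
#'
#' @param reflectance Tibble with `leaf_id`, `species`, `replicate` and the
#'   layout's channel columns.
#' @param layout The `sensor_layout`.
#' @param mode `"residue"` or `"full"`.
#' @return Tibble `leaf_id`, `species`, `replicate`, `distance`, `flagged`,
#'   `mode`, in the input row order.
#' @export
detect_spectral_outliers <- function(reflectance, layout,
                                     mode = c("residue", "full")) {
  mode <- rlang::arg_match(mode)
  labels <- channel_labels(layout)
  out <- reflectance[c("leaf_id", "species", "replicate")]
  out$distance <- NA_real_
  out$flagged <- NA
  for (sp in unique(reflectance$species)) {
    idx <- which(reflectance$species == sp)
    grp <- reflectance[idx, , drop = FALSE]
    x <- if (mode == "residue") {
      as.matrix(replicate_residues(grp, layout)[labels])
    } else {
      as.matrix(grp[labels])
    }
    d <- mahalanobis_distances(x)
    out$distance[idx] <- d
    out$flagged[idx] <- flag_outliers_3sigma(d)
  }
  out$mode <- mode
  out
}

#' Screen reference disk chlorophyll values for outliers
#'
#' A disk is an outlier when its residual from its leaf's mean exceeds three
#' times the pooled within-leaf standard deviation of its species. Exclusion
#' proceeds iteratively: each round drops at most the worst offending disk
#' per leaf, then leaf means and the pooled SD are recomputed from the disks
#' still in play, so a single deviant disk cannot drag its siblings out with
#' it. The pooled SD is floored at `1e-6` ug/cm^2 to avoid zero-variance
#' degeneracy.
#'
#' @param references Tibble with `leaf_id`, `species`, `disk`, `chl`
#'   (per-area chlorophyll per disk).
#' @return The input tibble with a logical `excluded` column added.
#' @seealso [leaf_reference_means()]
#' @export
filter_reference_outliers <- function(references) {
  refs <- references
  refs$excluded <- FALSE
  repeat {
    keep <- !refs$excluded
    leaf_mean <- tapply(refs$chl[keep], refs$leaf_id[keep], mean)
    resid <- refs$chl - leaf_mean[refs$leaf_id]
    # pooled within-leaf SD per species over non-excluded disks
    pooled <- vapply(split(seq_len(nrow(refs))[keep],
                           refs$species[keep]), function(ii) {
      nn <- table(refs$leaf_id[ii])
      df <- sum(pmax(as.integer(nn) - 1L, 0L))
      if (df == 0) return(1e-6)
      max(sqrt(sum(resid[ii]^2) / df), 1e-6)
    }, numeric(1))
    thr <- 3 * pooled[refs$species]
    offending <- keep & abs(resid) > thr
    if (!any(offending)) break
    # drop only the worst offender within each leaf this round
    for (lf in unique(refs$leaf_id[offending])) {
      ii <- which(offending & refs$leaf_id == lf)
      worst <- ii[which.max(abs(resid[ii]))]
      refs$excluded[worst] <- TRUE
    }
  }
  lost <- tapply(refs$excluded, refs$leaf_id, all)
  if (any(lost)) {
    rlang::abort(
      paste0("All disks excluded for leaves: ",
             paste(names(lost)[lost], collapse = ", ")),
      class = "chlorocal_empty_reference"
    )
  }
  refs
}

#' Per-leaf mean reference chlorophyll
#'
#' @param references Disk table with an `excluded` column, e.g. from
#'   [filter_reference_outliers()].
#' @return Tibble `leaf_id`, `species`, `mean_chl` over non-excluded disks.
#' @export
leaf_reference_means <- function(references) {
  if (is.null(references$excluded)) references$excluded <- FALSE
  keep <- references[!references$excluded, , drop = FALSE]
  if (nrow(keep) == 0) {
    rlang::abort("No usable reference disks.",
                 class = "chlorocal_empty_reference")
  }
  dplyr::summarise(dplyr::group_by(keep, .data$leaf_id, .data$species),
                   mean_chl = mean(.data$chl), .groups = "drop")
}
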