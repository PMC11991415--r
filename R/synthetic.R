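#' Species profiles for the synthetic leaf simulator
#'
#' One profile per study species, parameterizing chlorophyll range and the
#' noise structure of its spectra. Broad, smooth leaves (mango, banana) get
#' the lowest replicate noise and no background mixing; narrow leaves (rice,
#' sugarcane) do not always cover the optical path, so a fraction of a flat
#' dark background mixes into each replicate; jasmine has the narrowest
#' chlorophyll range and a rough, textured surface. `chip_artifact_sd`
#' controls the smooth per-chip multiplicative spot-texture disagreement of
#' the 18-channel sensor's three apertures on non-uniform targets.
#'
#' @return Tibble with one row per species and columns `species`, `chl_min`,
#'   `chl_max` (ug/cm^2), `replicate_noise_sd`, `leaf_texture_sd`,
#'   `background_mix_max`, `chip_artifact_sd`, `disk_noise_sd` (ug/cm^2).
#' @export
default_profiles <- function() {
  tibble::tibble(
    species = c("banana", "jasmine", "mango", "rice", "sugarcane"),
    chl_min = c(15, 25, 5, 15, 10),
    chl_max = c(75, 55, 90, 65, 70),
    replicate_noise_sd = c(0.010, 0.020, 0.010, 0.025, 0.020),
    leaf_texture_sd = c(0.03, 0.06, 0.03, 0.04, 0.04),
    background_mix_max = c(0, 0, 0, 0.35, 0.20),
    chip_artifact_sd = c(0.01, 0.02, 0.01, 0.08, 0.04),
    disk_noise_sd = c(2.5, 3.0, 2.5, 2.5, 2.5)
  )
}

validate_profile <- function(profile) {
  stopifnot(
    nrow(profile) == 1,
    profile$chl_min > 0, profile$chl_min < profile$chl_max,
    profile$replicate_noise_sd >= 0, profile$leaf_texture_sd >= 0,
    profile$background_mix_max >= 0, profile$background_mix_max < 1,
    profile$chip_artifact_sd >= 0, profile$disk_noise_sd >= 0
  )
  invisible(profile)
}

#' Mean leaf reflectance as a function of chlorophyll
#'
#' Beer--Lambert-style link `R(lambda) = R0(lambda) * exp(-k(lambda) * chl)`
#' with the chlorophyll absorption coefficient `k` peaking in the blue
#' (~450 nm) and red (~672 nm) and vanishing beyond ~730 nm, and a baseline
#' `R0` that rises from ~0.42 in the visible to ~0.85 on the NIR plateau.
#' This yields the canonical leaf signature (low red/blue, moderate green,
#' high NIR) with reflectance decreasing monotonically in chlorophyll at
#' every visible wavelength.
#'
#' @param wavelength_nm Wavelengths in nm (vectorized).
#' @param chl Chlorophyll in ug/cm^2 (scalar).
#' @return Reflectance values in (0, 1).
#' @export
leaf_reflectance_model <- function(wavelength_nm, chl) {
  r0 <- 0.42 + 0.43 * stats::plogis((wavelength_nm - 705) / 18)
  vis <- stats::plogis(-(wavelength_nm - 712) / 14)
  k <- vis * (0.004 +
                0.026 * exp(-((wavelength_nm - 450) / 40)^2) +
                0.026 * exp(-((wavelength_nm - 672) / 28)^2))
  r0 * exp(-k * chl)
}

#' White-reference intensity curve
#'
#' Emulates a white LED (sharp blue peak plus a broad phosphor hump) with an
#' additional IR source so every channel of every layout sees signal.
#'
#' @param wavelength_nm Wavelengths in nm.
#' @return Raw counts (positive).
#' @export
reference_intensity <- function(wavelength_nm) {
  200 +
    20000 * exp(-((wavelength_nm - 455) / 18)^2) +
    12000 * exp(-((wavelength_nm - 570) / 80)^2) +
    6000 * stats::plogis((wavelength_nm - 780) / 25)
}

reference_counts_for <- function(layout) {
  v <- reference_intensity(layout$channels$center_nm)
  names(v) <- channel_labels(layout)
  v
}

acquisition_meta <- function(layout_name) {
  switch(layout_name,
    vis6 = list(led = "white", integration_ms = 140, current_ma = 12.5),
    nir6 = list(led = "white", integration_ms = 700, current_ma = 12.5),
    full18 = list(led = "white+ir", integration_ms = 140, current_ma = 12.5)
  )
}

#' Simulate one species' leaf population
#'
#' Draws leaves with uniform chlorophyll over the profile's range, builds
#' their mean reflectance with [leaf_reflectance_model()], and produces three
#' replicate raw readings per leaf per layout plus three reference disk
#' absorbance pairs per leaf. Replicates differ by per-channel relative
#' noise, a per-leaf multiplicative texture factor, and a convex mixture
#' with a flat 4% background for narrow leaves. For the three-aperture
#' 18-channel layout the background-mix coefficient is common to the
#' replicate (one leaf placement) with a 15% per-chip deviation, and each
#' chip further sees its own smooth multiplicative spot-texture perturbation
#' (log-scale SD `chip_artifact_sd`), emulating apertures that view
#' different areas of a non-uniform target. Raw counts are reflectance
#' times the layout's reference
#' intensity plus shot-like noise. All randomness flows from `seed`.
#'
#' @param profile One-row tibble as in [default_profiles()].
#' @param n_leaves Number of leaves (>= 1).
#' @param layouts Named list of `sensor_layout` objects.
#' @param seed Integer seed; identical inputs give identical output.
#' @param shot_noise Scale of the shot-like count noise (SD =
#'   `shot_noise * sqrt(counts)`); set 0 for the noise-free limit.
#' @param assay Reference assay geometry ([reference_assay()]).
#' @return A `leaf_population`: list with `leaves` (leaf_id, species,
#'   true_chl), `references` (disk absorbance pairs), `spectra` (named list
#'   of raw-reading tibbles per layout), `reference_counts` (white-reference
#'   vectors per layout) and `assay`.
#' @export
simulate_population <- function(profile, n_leaves,
                                layouts = sensor_layouts(), seed,
                                shot_noise = 1, assay = reference_assay()) {
  validate_profile(profile)
  if (n_leaves < 1) {
    rlang::abort("`n_leaves` must be at least 1.",
                 class = "chlorocal_bad_argument")
  }
  if (!all(vapply(layouts, inherits, logical(1), "sensor_layout"))) {
    rlang::abort("`layouts` must be sensor_layout objects.",
                 class = "chlorocal_unknown_sensor")
  }
  sp <- profile$species
  withr::with_seed(seed, {
    leaf_id <- sprintf("%s_%03d", sp, seq_len(n_leaves))
    true_chl <- stats::runif(n_leaves, profile$chl_min, profile$chl_max)
    texture <- exp(stats::rnorm(n_leaves, 0, profile$leaf_texture_sd))

    # reference disks: noisy per-disk chlorophyll converted to exact
    # absorbance pairs, so the DMF equation inverts them back
    disk_chl <- pmax(
      rep(true_chl, each = 3) +
        stats::rnorm(3 * n_leaves, 0, profile$disk_noise_sd),
      0.1
    )
    conc <- disk_chl * assay$disk_area_cm2 / assay$extract_volume_ml
    a664 <- conc / (0.18 * (20.27 * assay$a_ratio + 7.04))
    references <- tibble::tibble(
      leaf_id = rep(leaf_id, each = 3),
      species = sp,
      disk = rep(1:3, n_leaves),
      a647 = assay$a_ratio * a664,
      a664 = a664
    )

    spectra <- lapply(layouts, function(layout) {
      labels <- channel_labels(layout)
      centers <- layout$channels$center_nm
      p <- length(centers)
      ref <- reference_counts_for(layout)
      meta <- acquisition_meta(layout$name)
      rows <- vector("list", n_leaves * 3)
      spot_basis <- cbind(exp(-((centers - 520) / 130)^2),
                          exp(-((centers - 800) / 130)^2))
      for (i in seq_len(n_leaves)) {
        base <- leaf_reflectance_model(centers, true_chl[i]) * texture[i]
        for (rep_j in 1:3) {
          r <- base
          if (layout$name == "full18") {
            # the three apertures view slightly different leaf areas: the
            # leaf/background coverage is common to the replicate (one leaf
            # placement) with a small per-chip deviation, and each chip
            # additionally sees its own smooth spot-texture perturbation
            chips <- layout$channels$chip_id
            m0 <- if (profile$background_mix_max > 0) {
              stats::runif(1, 0, profile$background_mix_max)
            } else 0
            for (id in unique(chips)) {
              sel <- chips == id
              if (m0 > 0) {
                m <- min(max(m0 * (1 + 0.15 * stats::rnorm(1)), 0), 0.95)
                r[sel] <- (1 - m) * r[sel] + m * 0.04
              }
              if (profile$chip_artifact_sd > 0) {
                z <- stats::rnorm(ncol(spot_basis))
                r[sel] <- r[sel] * exp(profile$chip_artifact_sd *
                  drop(spot_basis[sel, , drop = FALSE] %*% z))
              }
            }
          } else if (profile$background_mix_max > 0) {
            m <- stats::runif(1, 0, profile$background_mix_max)
            r <- (1 - m) * r + m * 0.04
          }
          r <- r * (1 + stats::rnorm(p, 0, profile$replicate_noise_sd))
          r <- pmax(r, 1e-6)
          counts <- r * ref
          if (shot_noise > 0) {
            counts <- counts + shot_noise * sqrt(counts) * stats::rnorm(p)
          }
          rows[[(i - 1) * 3 + rep_j]] <- pmax(counts, 0)
        }
      }
      mat <- do.call(rbind, rows)
      colnames(mat) <- labels
      dplyr::bind_cols(
        tibble::tibble(
          leaf_id = rep(leaf_id, each = 3),
          species = sp,
          sensor = layout$name,
          replicate = rep(1:3, n_leaves),
          led = meta$led,
          integration_ms = meta$integration_ms,
          current_ma = meta$current_ma
        ),
        tibble::as_tibble(mat)
      )
    })
    names(spectra) <- vapply(layouts, function(l) l$name, character(1))

    structure(
      list(
        leaves = tibble::tibble(leaf_id = leaf_id, species = sp,
                                true_chl = true_chl),
        references = references,
        spectra = spectra,
        reference_counts = lapply(layouts, reference_counts_for),
        layouts = layouts,
        assay = assay,
        seed = seed
      ),
      class = "leaf_population"
    )
  })
}

#' @export
print.leaf_population <- function(x, ...) {
  cat(sprintf("<leaf_population> %d leaves, %d species, layouts: %s\n",
              nrow(x$leaves), length(unique(x$leaves$species)),
              paste(names(x$spectra), collapse = ", ")))
  invisible(x)
}

#' Simulate the full multi-species study
#'
#' Runs [simulate_population()] once per profile row with deterministically
#' spawned child seeds and concatenates the results.
#'
#' @param profiles Tibble of species profiles ([default_profiles()]).
#' @param n_leaves Leaves per species.
#' @param layouts Named list of `sensor_layout` objects.
#' @param seed Master seed.
#' @param ... Passed to [simulate_population()].
#' @return A `leaf_population` covering all species.
#' @export
simulate_study <- function(profiles = default_profiles(), n_leaves = 100,
                           layouts = sensor_layouts(), seed = 1, ...) {
  pops <- lapply(seq_len(nrow(profiles)), function(i) {
    simulate_population(profiles[i, ], n_leaves, layouts,
                        seed = spawn_seed(seed, i), ...)
  })
  merged <- pops[[1]]
  merged$leaves <- dplyr::bind_rows(lapply(pops, `[[`, "leaves"))
  merged$references <- dplyr::bind_rows(lapply(pops, `[[`, "references"))
  merged$spectra <- lapply(names(pops[[1]]$spectra), function(nm) {
    dplyr::bind_rows(lapply(pops, function(p) p$spectra[[nm]]))
  })
  names(merged$spectra) <- names(pops[[1]]$spectra)
  merged$seed <- seed
  merged
}

#' Inject gross replicate outliers into a simulated population
#'
#' Corrupts a random subset of (leaf, sensor, replicate) raw readings by
#' adding `magnitude` times the per-channel count SD of that sensor's table,
#' and returns the ground-truth list of corrupted readings for testing
#' outlier-detection power.
#'
#' @param population A `leaf_population`.
#' @param rate Fraction of replicate rows to corrupt per layout, in `[0, 1]`.
#' @param magnitude Perturbation size in channel-SD multiples.
#' @param seed Integer seed.
#' @param sensors Which layouts to corrupt (default: all).
#' @return List with `population` (modified copy) and `truth`, a tibble
#'   `sensor`, `leaf_id`, `replicate` of corrupted readings.
#' @export
inject_spectral_outliers <- function(population, rate, magnitude, seed,
                                     sensors = names(population$spectra)) {
  if (rate < 0 || rate > 1) {
    rlang::abort("`rate` must be in [0, 1].", class = "chlorocal_bad_argument")
  }
  if (nrow(population$leaves) == 0) {
    rlang::abort("Empty population.", class = "chlorocal_bad_argument")
  }
  truth <- list()
  withr::with_seed(seed, {
    for (nm in sensors) {
      tbl <- population$spectra[[nm]]
      labels <- channel_labels(population$layouts[[nm]])
      n <- nrow(tbl)
      n_bad <- round(rate * n)
      if (n_bad == 0) next
      idx <- sample.int(n, n_bad)
      ch_sd <- apply(as.matrix(tbl[labels]), 2, stats::sd)
      # random sign per channel: gross errors corrupt channels incoherently,
      # and a shared direction would let the covariance mask the injection
      signs <- matrix(sample(c(-1, 1), n_bad * length(labels), replace = TRUE),
                      nrow = n_bad)
      pert <- signs * matrix(magnitude * ch_sd, nrow = n_bad,
                             ncol = length(labels), byrow = TRUE)
      corrupted <- pmax(as.matrix(tbl[labels])[idx, , drop = FALSE] + pert, 0)
      tbl[idx, labels] <- tibble::as_tibble(corrupted)
      population$spectra[[nm]] <- tbl
      truth[[nm]] <- tibble::tibble(sensor = nm,
                                    leaf_id = tbl$leaf_id[idx],
                                    replicate = tbl$replicate[idx])
    }
  })
  truth <- if (length(truth) > 0) dplyr::bind_rows(truth) else
    tibble::tibble(sensor = character(), leaf_id = character(),
                   replicate = integer())
  list(population = population, truth = truth)
}
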