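# Shared fixtures, built in code and memoized per test run.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

species_profile <- function(name) {
  prof <- default_profiles()
  prof[prof$species == name, ]
}

tiny_mango <- function() memo("tiny_mango", {
  simulate_population(species_profile("mango"), 30, seed = 11)
})

mango_100 <- function() memo("mango_100", {
  simulate_population(species_profile("mango"), 100, seed = 11)
})

mango_data <- function(sensor = "vis6") memo(paste0("mango_data_", sensor), {
  build_modeling_data(mango_100(), sensor)
})

# Population with a clean spectral structure but two extreme, internally
# consistent low-chlorophyll leaves mixed in ("young leaves"): high visible
# reflectance, depressed NIR (underdeveloped mesophyll), and tightly
# agreeing replicates, so they are far from the population mean without
# any replicate-level error.
mango_with_young <- function() memo("mango_with_young", {
  mature_profile <- species_profile("mango")
  mature_profile$chl_min <- 20
  main <- simulate_population(mature_profile, 58, seed = 21)
  young_profile <- species_profile("mango")
  young_profile$chl_min <- 2
  young_profile$chl_max <- 6
  young_profile$replicate_noise_sd <- 0.004
  young_profile$leaf_texture_sd <- 0.01
  young <- simulate_population(young_profile, 2, seed = 22)
  for (nm in names(young$spectra)) {
    lay <- young$layouts[[nm]]
    nir <- lay$channels$label[lay$channels$center_nm >= 730]
    if (length(nir) > 0) {
      young$spectra[[nm]][nir] <- young$spectra[[nm]][nir] * 0.55
    }
  }
  rename <- function(id) sub("^mango_", "young_", id)
  young$leaves$leaf_id <- rename(young$leaves$leaf_id)
  young$references$leaf_id <- rename(young$references$leaf_id)
  for (nm in names(young$spectra)) {
    young$spectra[[nm]]$leaf_id <- rename(young$spectra[[nm]]$leaf_id)
  }
  merged <- main
  merged$leaves <- dplyr::bind_rows(main$leaves, young$leaves)
  merged$references <- dplyr::bind_rows(main$references, young$references)
  for (nm in names(main$spectra)) {
    merged$spectra[[nm]] <- dplyr::bind_rows(main$spectra[[nm]],
                                             young$spectra[[nm]])
  }
  list(population = merged,
       young_leaves = young$leaves$leaf_id)
})

# Leaf dataset generated from exactly three latent factors with distinct
# variances, so a PLS1 regression needs exactly three components (the
# coefficient vector spans a 3-dimensional Krylov space).
make_factor_data <- function(n_leaves = 100, p = 8, seed = 1,
                             x_noise = 0.05, y_noise = 0.2,
                             score_sd = c(3, 1.5, 0.7)) {
  r <- length(score_sd)
  withr::with_seed(seed, {
    leaf_id <- sprintf("leaf_%03d", seq_len(n_leaves))
    scores <- sweep(matrix(stats::rnorm(n_leaves * r), n_leaves), 2,
                    score_sd, "*")
    loadings <- qr.Q(qr(matrix(stats::rnorm(p * r), p)))
    y_leaf <- drop(scores %*% rep(1, r)) +
      stats::rnorm(n_leaves, 0, y_noise)
    x <- (scores %*% t(loadings))[rep(seq_len(n_leaves), each = 3), ] +
      matrix(stats::rnorm(3 * n_leaves * p, 0, x_noise), 3 * n_leaves)
    colnames(x) <- paste0("f", seq_len(p))
    leaf <- rep(leaf_id, each = 3)
    leaf_chl <- stats::setNames(y_leaf, leaf_id)
    structure(
      list(x = x, y = unname(leaf_chl[leaf]), leaf = leaf,
           leaf_chl = leaf_chl,
           bins = stats::setNames(quantile_bins(leaf_chl), leaf_id),
           layout = NULL, species = "synthetic", outliers = NULL,
           input = "factor"),
      class = "chl_data"
    )
  })
}

# Reflectance tibble for one sensor of a population.
population_reflectance <- function(population, sensor) {
  normalize_spectra(population$spectra[[sensor]],
                    population$reference_counts[[sensor]],
                    population$layouts[[sensor]])
}
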