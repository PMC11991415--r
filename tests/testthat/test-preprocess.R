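test_that("reflectance is the channel-wise ratio to the reference", {
  expect_equal(to_reflectance(c(50, 20), c(100, 80)), c(0.5, 0.25))
  expect_equal(to_reflectance(c(3, 7, 11), c(3, 7, 11)), c(1, 1, 1))
  expect_error(to_reflectance(c(1, 2), c(1, 0)),
               class = "chlorocal_degenerate_reference")
  expect_error(to_reflectance(c(1, 2, 3), c(1, 2)),
               class = "chlorocal_channel_count")
  withr::with_seed(1, {
    for (i in 1:10) {
      m <- runif(6, 0, 5000)
      r <- runif(6, 100, 9000)
      expect_equal(to_reflectance(m, r) * r, m, tolerance = 1e-12)
    }
  })
})

test_that("absorbance is -log10 of reflectance and round-trips", {
  expect_equal(to_absorbance(1), 0)
  expect_equal(to_absorbance(0.1), 1)
  expect_equal(to_absorbance(c(0.01, 100)), c(2, -2))
  expect_error(to_absorbance(0), class = "chlorocal_nonpositive_reflectance")
  expect_error(to_absorbance(c(0.5, -1)),
               class = "chlorocal_nonpositive_reflectance")
  withr::with_seed(2, {
    r <- runif(50, 1e-4, 2)
    expect_equal(10^(-to_absorbance(r)), r, tolerance = 1e-12)
  })
})

test_that("the DMF extract equation matches hand-computed values", {
  expect_equal(total_chlorophyll(0, 0), 0)
  expect_equal(total_chlorophyll(1, 0), 3.6486, tolerance = 1e-9)
  expect_equal(total_chlorophyll(0, 1), 1.2672, tolerance = 1e-9)
  expect_equal(total_chlorophyll(0.5, 0.5), 2.4579, tolerance = 1e-9)
  expect_error(total_chlorophyll(-0.1, 0.2),
               class = "chlorocal_negative_absorbance")
  withr::with_seed(3, {
    for (i in 1:10) {
      a <- runif(2, 0, 2)
      # independent expansion: distribute the path/dilution factor
      expect_equal(total_chlorophyll(a[1], a[2]),
                   0.18 * 20.27 * a[1] + 0.18 * 7.04 * a[2],
                   tolerance = 1e-12)
    }
  })
})

test_that("per-area conversion scales with volume and inversely with area", {
  expect_equal(per_area_chlorophyll(10, 1, 1), 10)
  expect_equal(per_area_chlorophyll(2.4579, 5, 3 * 0.28),
               2.4579 * 5 / 0.84, tolerance = 1e-12)
  expect_equal(per_area_chlorophyll(3, 2, 4), 1.5)
  expect_error(per_area_chlorophyll(1, 0, 1), class = "chlorocal_bad_assay")
  withr::with_seed(4, {
    c0 <- runif(1, 1, 20)
    v <- runif(1, 1, 10)
    a <- runif(1, 0.1, 2)
    expect_equal(per_area_chlorophyll(c0, 2 * v, a),
                 2 * per_area_chlorophyll(c0, v, a))
    expect_equal(per_area_chlorophyll(c0, v, 2 * a),
                 per_area_chlorophyll(c0, v, a) / 2)
  })
})

test_that("Mahalanobis distances satisfy the textbook identities", {
  withr::with_seed(5, {
    for (p in c(2, 6)) {
      n <- 60
      x <- matrix(rnorm(n * p), n)
      d <- mahalanobis_distances(x)
      expect_true(all(d >= 0))
      # sum of squared distances under the sample covariance
      expect_equal(sum(d^2), p * (n - 1), tolerance = 1e-8)
      # the sample mean has distance zero
      x2 <- rbind(x, colMeans(x))
      mu2 <- colMeans(x2)
      d2 <- sqrt(stats::mahalanobis(x2, mu2, stats::cov(x2)))
      expect_lt(abs(mahalanobis_distances(x2)[n + 1] -
                      d2[n + 1]), 1e-10)
      # affine invariance under an invertible channel transform
      a <- matrix(rnorm(p * p), p) + diag(p)
      y <- x %*% a + matrix(rnorm(p), n, p, byrow = TRUE)
      expect_equal(mahalanobis_distances(y), d, tolerance = 1e-8)
    }
  })
})

test_that("uncorrelated standardized channels give root-sum-square z-scores",
{
  withr::with_seed(6, {
    n <- 500
    x <- matrix(rnorm(n * 2), n)
    d <- mahalanobis_distances(x)
    # brute-force with the explicitly inverted diagonal-ish covariance
    s <- stats::cov(x)
    sinv <- solve(s)
    ctr <- sweep(x, 2, colMeans(x))
    d_ref <- sqrt(rowSums((ctr %*% sinv) * ctr))
    expect_equal(d, d_ref, tolerance = 1e-10)
  })
  expect_error(mahalanobis_distances(matrix(1:4, 2)),
               class = "chlorocal_insufficient_rows")
})

test_that("a singular covariance engages the ridge instead of failing", {
  withr::with_seed(7, {
    x <- matrix(rnorm(30), 10, 3)
    x <- cbind(x, x[, 1] + x[, 2]) # exactly collinear channel
    d <- mahalanobis_distances(x)
    expect_true(all(is.finite(d)))
  })
})

test_that("replicate residues subtract the mean of the other replicates", {
  lay <- sensor_layout("vis6")
  tbl <- tibble::tibble(
    leaf_id = rep("a", 3), replicate = 1:3
  )
  tbl[channel_labels(lay)] <-
    as.data.frame(matrix(rep(c(0, 3, 6), 6), 3))
  res <- replicate_residues(tbl, lay)
  expect_equal(unname(as.matrix(res[channel_labels(lay)])[1, ]),
               rep(-4.5, 6))
  # residues of a triplicate always sum to the zero vector
  expect_equal(colSums(as.matrix(res[channel_labels(lay)])),
               setNames(rep(0, 6), channel_labels(lay)))
  # identical triplicate: all-zero residues
  tbl2 <- tbl
  tbl2[channel_labels(lay)] <- as.data.frame(matrix(2, 3, 6))
  expect_true(all(as.matrix(replicate_residues(tbl2,
                                               lay)[channel_labels(lay)]) == 0))
  # wrong replicate count is an explicit error naming the leaf
  expect_error(replicate_residues(tbl[1:2, ], lay),
               regexp = "a", class = "chlorocal_replicate_count")
})

test_that("residue sums vanish on simulated populations", {
  pop <- tiny_mango()
  refl <- population_reflectance(pop, "full18")
  res <- replicate_residues(refl, pop$layouts$full18)
  labels <- channel_labels(pop$layouts$full18)
  sums <- rowsum(as.matrix(res[labels]), res$leaf_id)
  expect_lt(max(abs(sums)), 1e-12)
})

test_that("the 3-sigma rule flags only distances above mean + 3 SD", {
  expect_equal(flag_outliers_3sigma(rep(2, 10)), rep(FALSE, 10))
  d <- c(rep(1, 50), 30)
  flags <- flag_outliers_3sigma(d)
  expect_equal(which(flags), 51L)
  expect_error(flag_outliers_3sigma(c(1, 2)),
               class = "chlorocal_insufficient_rows")
})

test_that("reference disk screening excludes injected deviants only", {
  withr::with_seed(8, {
    n <- 40
    leaf_id <- sprintf("l%02d", seq_len(n))
    chl <- runif(n, 20, 80)
    disks <- tibble::tibble(
      leaf_id = rep(leaf_id, each = 3),
      species = "mango",
      disk = rep(1:3, n),
      chl = rep(chl, each = 3) + rnorm(3 * n, 0, 1.5)
    )
    # one disk pushed ten pooled SDs away
    disks$chl[5] <- disks$chl[5] + 15
    out <- filter_reference_outliers(disks)
    expect_true(out$excluded[5])
    expect_lte(sum(out$excluded), 2)
    means <- leaf_reference_means(out)
    expect_equal(nrow(means), n)
  })
})

test_that("zero within-leaf variance still isolates a single deviant disk", {
  disks <- tibble::tibble(
    leaf_id = rep(sprintf("l%02d", 1:20), each = 3),
    species = "rice",
    disk = rep(1:3, 20),
    chl = rep(50, 60)
  )
  disks$chl[10] <- 58
  out <- filter_reference_outliers(disks)
  expect_equal(which(out$excluded), 10L)
  means <- leaf_reference_means(out)
  expect_true(all(means$mean_chl == 50))
})

test_that("full-spectrum mode flags internally consistent extreme leaves and
           residue mode spares them", {
  fix <- mango_with_young()
  pop <- fix$population
  refl <- population_reflectance(pop, "vis6")
  full <- detect_spectral_outliers(refl, pop$layouts$vis6, mode = "full")
  residue <- detect_spectral_outliers(refl, pop$layouts$vis6,
                                      mode = "residue")
  expect_gt(sum(full$flagged[full$leaf_id %in% fix$young_leaves]), 0)
  expect_equal(sum(residue$flagged[residue$leaf_id %in% fix$young_leaves]), 0)
})
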