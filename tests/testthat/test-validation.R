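test_that("quantile bins are balanced, monotone and deterministic", {
  bins <- quantile_bins(1:100, 10)
  expect_equal(as.integer(table(bins)), rep(10L, 10))
  expect_equal(bins[1], 1L)
  expect_equal(bins[100], 10L)
  expect_true(all(diff(bins[order(1:100)]) >= 0))

  # sizes differ by at most one when counts do not divide evenly
  bins2 <- quantile_bins(rnorm(47), 10)
  expect_lte(diff(range(table(bins2))), 1)

  # ties resolved by stable order: repeated calls identical
  tied <- rep(c(1, 2), each = 10)
  expect_identical(quantile_bins(tied, 4), quantile_bins(tied, 4))
  expect_error(quantile_bins(1:5, 10),
               class = "chlorocal_stratification_error")
})

test_that("stratified group splits hold out equal counts per bin", {
  withr::with_seed(20, {
    leaves <- sprintf("l%03d", 1:100)
    bins <- quantile_bins(runif(100), 10)
    sp <- stratified_group_split(leaves, bins, 20, seed = 1)
    expect_length(sp$heldout, 20)
    expect_length(intersect(sp$heldout, sp$remaining), 0)
    expect_setequal(c(sp$heldout, sp$remaining), leaves)
    held_bins <- bins[match(sp$heldout, leaves)]
    expect_equal(as.integer(table(held_bins)), rep(2L, 10))

    # remainder spread over bins: counts differ by at most one
    sp2 <- stratified_group_split(leaves, bins, 23, seed = 2)
    expect_lte(diff(range(table(bins[match(sp2$heldout, leaves)]))), 1)

    # deterministic in the seed, different across seeds
    expect_identical(stratified_group_split(leaves, bins, 20, seed = 7),
                     stratified_group_split(leaves, bins, 20, seed = 7))
    expect_false(identical(
      stratified_group_split(leaves, bins, 20, seed = 7)$heldout,
      stratified_group_split(leaves, bins, 20, seed = 8)$heldout))

    expect_length(stratified_group_split(leaves, bins, 0, seed = 1)$heldout,
                  0)
    expect_error(stratified_group_split(leaves[1:12], bins[1:12], 12,
                                        seed = 1),
                 class = "chlorocal_stratification_error")
  })
})

test_that("spawned child seeds are deterministic and within integer range", {
  s1 <- vapply(1:50, function(i) spawn_seed(123, i), integer(1))
  s2 <- vapply(1:50, function(i) spawn_seed(123, i), integer(1))
  expect_identical(s1, s2)
  expect_true(all(s1 >= 1 & s1 <= 2147483647))
  expect_gt(length(unique(s1)), 45)
})

test_that("the inner scan recovers the latent dimensionality of factor data",
{
  hits <- vapply(1:20, function(i) {
    d <- make_factor_data(seed = i)
    inner_lv_scan(d, lv_range = 1:6, seed = 1000 + i)$chosen_lv
  }, integer(1))
  expect_gte(mean(hits == 3), 0.8)
})

test_that("a pure-noise response yields no spurious test R2", {
  withr::with_seed(21, {
    d <- make_factor_data(seed = 31)
    d$leaf_chl[] <- rnorm(length(d$leaf_chl), 50, 5)
    d$y <- unname(d$leaf_chl[d$leaf])
    d$bins <- setNames(quantile_bins(d$leaf_chl), names(d$leaf_chl))
    scan <- inner_lv_scan(d, lv_range = 1:6, n_reps = 20, seed = 5)
    expect_true(all(scan$table$mean_r2 <= 2 * scan$table$sd_r2))
  })
})

test_that("a single-value scan chooses that value", {
  d <- make_factor_data(seed = 3)
  scan <- inner_lv_scan(d, lv_range = 4, n_reps = 3, seed = 2)
  expect_equal(scan$chosen_lv, 4)
  expect_error(inner_lv_scan(d, lv_range = 1:20, seed = 1),
               class = "chlorocal_lv_range")
})

test_that("nested cross-validation is leak-free, stratified and
           bit-reproducible", {
  data <- mango_data("vis6")
  leaves <- names(data$leaf_chl)
  for (i in 1:5) {
    rep_seed <- spawn_seed(99, i)
    sp <- stratified_group_split(leaves, data$bins[leaves], 20,
                                 seed = rep_seed)
    expect_length(intersect(sp$heldout, sp$remaining), 0)
    inner <- stratified_group_split(sp$remaining,
                                    data$bins[sp$remaining], 20,
                                    seed = spawn_seed(rep_seed, 1))
    expect_length(intersect(inner$heldout, sp$heldout), 0)
    expect_length(intersect(inner$heldout, inner$remaining), 0)
  }
  cv1 <- nested_cv(data, outer_reps = 4, inner_reps = 4, seed = 77)
  cv2 <- nested_cv(data, outer_reps = 4, inner_reps = 4, seed = 77)
  expect_identical(cv1$records, cv2$records)
  expect_equal(nrow(cv1$records), 4)
  expect_true(all(cv1$records$chosen_lv %in% cv1$lv_range))
})

test_that("noise-free linear data validates perfectly through the nested
           pipeline", {
  d <- make_factor_data(seed = 41, x_noise = 0, y_noise = 0)
  cv <- nested_cv(d, lv_range = 1:4, outer_reps = 3, inner_reps = 5,
                  seed = 13)
  expect_true(all(cv$records$validation_r2 > 1 - 1e-6))
  expect_true(all(cv$records$validation_mae < 1e-3))
})

test_that("learning curves show training optimism and improve with size", {
  # strict optimism on noise-dominated linear data at every size
  fd <- make_factor_data(seed = 50)
  lcf <- learning_curve(fd, n_lv = 3, sizes = c(10, 20, 40, 70),
                        reps = 20, seed = 3)
  expect_true(all(lcf$table$train_mae_mean <=
                    lcf$table$test_mae_mean + 1e-9))
  expect_lte(lcf$table$test_mae_mean[4], lcf$table$test_mae_mean[1])

  # leaf data: optimism where the model is data-limited, and test error
  # non-increasing from the smallest to the largest training set
  data <- mango_data("vis6")
  lc <- learning_curve(data, n_lv = 4, sizes = c(10, 20, 40, 70),
                       reps = 20, seed = 3)
  expect_equal(lc$table$size, c(10, 20, 40, 70))
  expect_true(all(lc$table$train_mae_mean[1:2] <=
                    lc$table$test_mae_mean[1:2] + 1e-9))
  expect_lte(lc$table$test_mae_mean[4], lc$table$test_mae_mean[1])
  expect_true(all(lc$table$test_mae_mean >= 0))
  expect_error(learning_curve(data, 4, sizes = c(40, 20), reps = 2,
                              seed = 1),
               class = "chlorocal_bad_argument")
  expect_error(learning_curve(data, 4, sizes = c(10, 95), reps = 2,
                              seed = 1),
               class = "chlorocal_bad_argument")
})

test_that("modeling datasets keep leaves intact and stratification stable", {
  data <- mango_data("full18")
  expect_equal(sort(unique(data$leaf)), sort(names(data$leaf_chl)))
  expect_true(all(table(data$leaf) <= 3))
  expect_lte(diff(range(table(data$bins))), 1)
  # spectra of one leaf share one reference value
  expect_equal(data$y, unname(data$leaf_chl[data$leaf]))
})

test_that("the calibration report tabulates sensors by species", {
  pop <- simulate_study(default_profiles()[3, ], n_leaves = 60, seed = 4)
  rep_tbl <- calibration_report(pop, sensors = c("vis6", "nir6"),
                                outer_reps = 2, inner_reps = 4, seed = 1)
  expect_equal(nrow(rep_tbl), 2)
  expect_true(all(c("sensor", "species", "modal_lv", "validation_r2",
                    "validation_mae") %in% names(rep_tbl)))
  expect_true(all(rep_tbl$validation_mae > 0))
})
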