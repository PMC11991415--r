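#' Default latent-variable scan range for a layout
#'
#' 1..6 for the 6-channel layouts, 1..16 for the 18-channel layout (selected
#' counts on real data reach into the teens).
#'
#' @param layout A `sensor_layout` or layout name.
#' @return Integer vector of component counts.
#' @export
default_lv_range <- function(layout) {
  name <- if (inherits(layout, "sensor_layout")) layout$name else layout
  if (name == "full18") 1:16 else 1:6
}

# Leaf-level evaluation of a fitted path on a leaf subset: per component
# count, the RSS / MAE / R^2 of leaf-averaged predictions.
eval_path_leaves <- function(model, data, leaves) {
  rows <- data$leaf %in% leaves
  preds <- predict_pls_path(model, data$x[rows, , drop = FALSE])
  leaf <- data$leaf[rows]
  counts <- as.integer(table(leaf))
  leaf_pred <- rowsum(preds, leaf) / counts
  truth <- data$leaf_chl[rownames(leaf_pred)]
  res <- leaf_pred - truth
  rss <- colSums(res^2)
  sstot <- sum((truth - mean(truth))^2)
  list(
    rss = rss,
    mae = colMeans(abs(res)),
    r2 = 1 - rss / sstot,
    n = length(truth)
  )
}

fit_path_on <- function(data, leaves, kmax) {
  rows <- data$leaf %in% leaves
  fit_pls(data$x[rows, , drop = FALSE], data$y[rows], n_lv = kmax)
}

#' Inner cross-validation scan over latent-variable counts
#'
#' Repeatedly splits the supplied leaf pool into stratified inner training
#' and test sets (by default 3:1, i.e. 60/20 leaves out of a pool of 80),
#' fits the PLS path on the inner training spectra, and scores each
#' component count on the inner test leaves using leaf-averaged predictions.
#' The chosen count minimizes the mean AIC (ties broken toward fewer
#' components); AIC uses the number of test leaves as `n`.
#'
#' @param data A `chl_data`.
#' @param leaves Leaf pool to scan over (default: all leaves in `data`).
#' @param lv_range Component counts to scan
#'   (default [default_lv_range()]).
#' @param n_reps Number of inner Monte-Carlo splits (default 20).
#' @param test_size Leaves held out per inner split (default
#'   `round(length(leaves)/4)`).
#' @param seed Integer seed; child seeds are spawned per repetition.
#' @return Object of class `lv_scan`: list with `table` (tibble of `lv`,
#'   `mean_aic`, `sd_aic`, `mean_r2`, `sd_r2`, `mean_mae`, `sd_mae`),
#'   `chosen_lv`, `n_reps`, `test_size`.
#' @export
inner_lv_scan <- function(data, leaves = names(data$leaf_chl),
                          lv_range = default_lv_range(data$layout),
                          n_reps = 20, test_size = NULL, seed = 1) {
  kmax <- max(lv_range)
  if (kmax > ncol(data$x)) {
    rlang::abort("`lv_range` exceeds the number of channels.",
                 class = "chlorocal_lv_range")
  }
  if (is.null(test_size)) test_size <- round(length(leaves) / 4)
  bins <- data$bins[leaves]
  aics <- r2s <- maes <- matrix(NA_real_, n_reps, length(lv_range))
  for (r in seq_len(n_reps)) {
    sp <- stratified_group_split(leaves, bins, test_size,
                                 seed = spawn_seed(seed, r))
    stopifnot(length(intersect(sp$heldout, sp$remaining)) == 0)
    model <- fit_path_on(data, sp$remaining, kmax)
    ev <- eval_path_leaves(model, data, sp$heldout)
    aics[r, ] <- aic_score(ev$rss[lv_range], ev$n, lv_range)
    r2s[r, ] <- ev$r2[lv_range]
    maes[r, ] <- ev$mae[lv_range]
  }
  tab <- tibble::tibble(
    lv = lv_range,
    mean_aic = colMeans(aics), sd_aic = apply(aics, 2, stats::sd),
    mean_r2 = colMeans(r2s), sd_r2 = apply(r2s, 2, stats::sd),
    mean_mae = colMeans(maes), sd_mae = apply(maes, 2, stats::sd)
  )
  structure(
    list(table = tab,
         chosen_lv = lv_range[which.min(tab$mean_aic)],
         n_reps = n_reps, test_size = test_size),
    class = "lv_scan"
  )
}

#' @export
print.lv_scan <- function(x, ...) {
  cat(sprintf("<lv_scan> chosen_lv = %d over %d reps\n",
              x$chosen_lv, x$n_reps))
  print(x$table)
  invisible(x)
}

#' Double-nested group-stratified Monte-Carlo cross-validation
#'
#' Each outer repetition holds out a stratified validation set of leaves
#' (default 20 of 100), runs [inner_lv_scan()] on the remaining training
#' leaves to choose the component count by AIC, refits the PLS model with
#' that count on all training leaves, and records leaf-level R^2 and MAE on
#' the training, inner-test (at the chosen count) and validation sets. At
#' the defaults (50 outer x 20 inner) the inner loop runs 1000 splits per
#' component count.
#'
#' @param data A `chl_data`.
#' @param lv_range Component counts to scan.
#' @param outer_reps Number of outer repetitions (default 50).
#' @param inner_reps Inner splits per outer repetition (default 20).
#' @param validation_size Leaves held out per outer repetition (default
#'   `round(n_leaves/5)`).
#' @param seed Master seed; per-repetition seeds are spawned
#'   deterministically so the run is bit-reproducible.
#' @return Object of class `nested_cv`: list with `records` (one row per
#'   repetition: `rep`, `seed`, `chosen_lv`, `train_r2`, `train_mae`,
#'   `test_r2`, `test_mae`, `validation_r2`, `validation_mae`), `summary`
#'   (means and SDs), `lv_range`, `sizes`, `seed`.
#' @export
nested_cv <- function(data, lv_range = default_lv_range(data$layout),
                      outer_reps = 50, inner_reps = 20,
                      validation_size = NULL, seed = 1) {
  leaves <- names(data$leaf_chl)
  if (is.null(validation_size)) validation_size <- round(length(leaves) / 5)
  records <- vector("list", outer_reps)
  for (i in seq_len(outer_reps)) {
    rep_seed <- spawn_seed(seed, i)
    sp <- stratified_group_split(leaves, data$bins[leaves], validation_size,
                                 seed = rep_seed)
    stopifnot(length(intersect(sp$heldout, sp$remaining)) == 0)
    scan <- inner_lv_scan(data, leaves = sp$remaining, lv_range = lv_range,
                          n_reps = inner_reps, seed = spawn_seed(rep_seed, 1))
    k <- scan$chosen_lv
    model <- fit_path_on(data, sp$remaining, max(lv_range))
    ev_train <- eval_path_leaves(model, data, sp$remaining)
    ev_val <- eval_path_leaves(model, data, sp$heldout)
    row <- scan$table[scan$table$lv == k, ]
    records[[i]] <- tibble::tibble(
      rep = i, seed = rep_seed, chosen_lv = k,
      train_r2 = ev_train$r2[k], train_mae = ev_train$mae[k],
      test_r2 = row$mean_r2, test_mae = row$mean_mae,
      validation_r2 = ev_val$r2[k], validation_mae = ev_val$mae[k]
    )
  }
  records <- dplyr::bind_rows(records)
  num <- c("train_r2", "train_mae", "test_r2", "test_mae",
           "validation_r2", "validation_mae")
  summary <- tibble::tibble(
    metric = num,
    mean = vapply(records[num], mean, numeric(1)),
    sd = vapply(records[num], stats::sd, numeric(1))
  )
  structure(
    list(records = records, summary = summary, lv_range = lv_range,
         sizes = list(n_leaves = length(leaves),
                      validation_size = validation_size,
                      outer_reps = outer_reps, inner_reps = inner_reps),
         seed = seed),
    class = "nested_cv"
  )
}

#' @export
print.nested_cv <- function(x, ...) {
  cat(sprintf(
    "<nested_cv> %d outer x %d inner reps on %d leaves; modal LV = %d\n",
    x$sizes$outer_reps, x$sizes$inner_reps, x$sizes$n_leaves,
    as.integer(names(which.max(table(x$records$chosen_lv))))))
  print(x$summary)
  invisible(x)
}

#' Learning curve over training-set size
#'
#' For each repetition a stratified test set is held out once and shared
#' across all sizes; for each size a stratified sample of that many leaves
#' trains a PLS model with a fixed component count, and train/test MAEs of
#' leaf-averaged predictions are recorded.
#'
#' @param data A `chl_data`.
#' @param n_lv Fixed component count.
#' @param sizes Strictly increasing training-set sizes (leaves).
#' @param reps Number of repetitions (default 20).
#' @param test_size Held-out leaves per repetition (default
#'   `round(n_leaves/5)`).
#' @param seed Master seed.
#' @return Object of class `learning_curve`: list with `table` (tibble of
#'   `size`, `train_mae_mean`, `train_mae_sd`, `test_mae_mean`,
#'   `test_mae_sd`) and `records`.
#' @export
learning_curve <- function(data, n_lv, sizes, reps = 20, test_size = NULL,
                           seed = 1) {
  if (any(diff(sizes) <= 0)) {
    rlang::abort("`sizes` must be strictly increasing.",
                 class = "chlorocal_bad_argument")
  }
  leaves <- names(data$leaf_chl)
  if (is.null(test_size)) test_size <- round(length(leaves) / 5)
  if (max(sizes) > length(leaves) - test_size) {
    rlang::abort("Largest size exceeds the available training pool.",
                 class = "chlorocal_bad_argument")
  }
  recs <- vector("list", reps * length(sizes))
  idx <- 1L
  for (r in seq_len(reps)) {
    rep_seed <- spawn_seed(seed, r)
    sp <- stratified_group_split(leaves, data$bins[leaves], test_size,
                                 seed = rep_seed)
    for (si in seq_along(sizes)) {
      s <- sizes[si]
      samp <- stratified_group_split(sp$remaining, data$bins[sp$remaining],
                                     s, seed = spawn_seed(rep_seed, si))
      train_leaves <- samp$heldout
      stopifnot(length(intersect(train_leaves, sp$heldout)) == 0)
      model <- fit_path_on(data, train_leaves, n_lv)
      ev_tr <- eval_path_leaves(model, data, train_leaves)
      ev_te <- eval_path_leaves(model, data, sp$heldout)
      recs[[idx]] <- tibble::tibble(
        rep = r, size = s,
        train_mae = ev_tr$mae[n_lv], test_mae = ev_te$mae[n_lv]
      )
      idx <- idx + 1L
    }
  }
  records <- dplyr::bind_rows(recs)
  tab <- dplyr::summarise(
    dplyr::group_by(records, size = .data$size),
    train_mae_mean = mean(.data$train_mae),
    train_mae_sd = stats::sd(.data$train_mae),
    test_mae_mean = mean(.data$test_mae),
    test_mae_sd = stats::sd(.data$test_mae),
    .groups = "drop"
  )
  structure(list(table = tab, records = records, n_lv = n_lv, seed = seed),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("<learning_curve> %d sizes, %d LVs\n", nrow(x$table), x$n_lv))
  print(x$table)
  invisible(x)
}
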