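#' Compare single-chip channel subsets with the combined 18-channel sensor
#'
#' Evaluates each chip's six channels with a fixed component count (5 by
#' default, the typical optimum of the 6-channel sensors) and the combined
#' 18-channel design over shared repeated group-stratified train/test
#' splits, scoring leaf-averaged test predictions. The combined design's
#' component count is chosen by an AIC scan inside each split's training
#' pool (never using that split's test leaves), mirroring how the full
#' sensor is tuned in practice; pass `full_lv` to fix it instead. On
#' non-uniform targets the three apertures of the multi-chip sensor
#' disagree, and a single chip can outperform the combined design.
#'
#' @param data A `chl_data` built on the `full18` layout.
#' @param n_lv Component count for each single-chip model (default 5).
#' @param full_lv Fixed component count for the combined design; `NULL`
#'   (default) selects it per split by [inner_lv_scan()] on the training
#'   leaves.
#' @param reps Number of Monte-Carlo splits (default 30).
#' @param inner_reps Inner splits for the per-split AIC scan (default 10).
#' @param test_size Held-out leaves per split (default `round(n/5)`).
#' @param seed Master seed.
#' @return Tibble with one row per condition (`chip` = chip id or
#'   `"full"`): `n_lv` (fixed count, or the modal chosen count for the
#'   combined design), `mean_r2`, `sd_r2`, `mean_mae`, `sd_mae`.
#' @export
compare_chips <- function(data, n_lv = 5, full_lv = NULL, reps = 30,
                          inner_reps = 10, test_size = NULL, seed = 1) {
  if (data$layout$name != "full18") {
    rlang::abort("Chip comparison requires the full18 layout.",
                 class = "chlorocal_unknown_chip")
  }
  leaves <- names(data$leaf_chl)
  if (is.null(test_size)) test_size <- round(length(leaves) / 5)
  map <- chip_map(data$layout)
  conds <- c(names(map), "full")
  r2 <- mae <- matrix(NA_real_, reps, length(conds),
                      dimnames = list(NULL, conds))
  chosen_full <- integer(reps)
  chip_data <- lapply(names(map), function(id) {
    sub <- chip_subset(data$x, data$layout, id)
    d <- data
    d$x <- as.matrix(sub$x)
    d$layout <- sub$layout
    d
  })
  names(chip_data) <- names(map)
  for (r in seq_len(reps)) {
    rep_seed <- spawn_seed(seed, r)
    sp <- stratified_group_split(leaves, data$bins[leaves], test_size,
                                 seed = rep_seed)
    k_full <- if (is.null(full_lv)) {
      inner_lv_scan(data, leaves = sp$remaining,
                    lv_range = default_lv_range(data$layout),
                    n_reps = inner_reps,
                    seed = spawn_seed(rep_seed, 1))$chosen_lv
    } else full_lv
    chosen_full[r] <- k_full
    for (cond in conds) {
      d <- if (cond == "full") data else chip_data[[cond]]
      k <- if (cond == "full") k_full else n_lv
      model <- fit_path_on(d, sp$remaining, k)
      ev <- eval_path_leaves(model, d, sp$heldout)
      r2[r, cond] <- ev$r2[k]
      mae[r, cond] <- ev$mae[k]
    }
  }
  modal_full <- as.integer(names(which.max(table(chosen_full))))
  tibble::tibble(
    chip = conds,
    n_lv = c(rep(n_lv, length(map)), modal_full),
    mean_r2 = colMeans(r2), sd_r2 = apply(r2, 2, stats::sd),
    mean_mae = colMeans(mae), sd_mae = apply(mae, 2, stats::sd)
  )
}
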