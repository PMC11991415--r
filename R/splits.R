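#' Deterministically spawn a child seed
#'
#' Child seeds for repetitions are derived from the master seed by a fixed
#' Lehmer-style rule `(master * 48271 + i * 16807) mod (2^31 - 1) + 1`, so
#' any single repetition is reproducible in isolation.
#'
#' @param master Integer master seed.
#' @param i Repetition index (>= 0).
#' @return Integer seed in `[1, 2^31 - 1]`.
#' @export
spawn_seed <- function(master, i) {
  s <- (as.numeric(master) %% 2147483647) * 48271 + as.numeric(i) * 16807
  as.integer(s %% 2147483647) + 1L
}

#' Assign leaves to chlorophyll quantile bins
#'
#' Leaves are ranked by chlorophyll (stable order on ties) and cut into
#' `n_bins` contiguous groups whose sizes differ by at most one, so the bin
#' index is monotone in chlorophyll.
#'
#' @param leaf_chl Numeric vector of per-leaf chlorophyll values.
#' @param n_bins Number of bins (default 10).
#' @return Integer vector of bin indices (1..n_bins) in the input order.
#' @export
quantile_bins <- function(leaf_chl, n_bins = 10) {
  n <- length(leaf_chl)
  if (n < n_bins) {
    rlang::abort("Need at least as many leaves as bins.",
                 class = "chlorocal_stratification_error")
  }
  sizes <- rep(n %/% n_bins, n_bins) +
    c(rep(1L, n %% n_bins), rep(0L, n_bins - n %% n_bins))
  bins <- integer(n)
  bins[order(leaf_chl)] <- rep(seq_len(n_bins), times = sizes)
  bins
}

#' Group-stratified Monte-Carlo split
#'
#' Holds out `n_out` leaves sampled (nearly) equally across chlorophyll bins:
#' every bin contributes `floor(n_out / n_bins)` leaves and the remainder is
#' spread over a seeded random ordering of the bins, so per-bin held-out
#' counts differ by at most one. Whole leaves move as units (all replicate
#' spectra of a leaf stay on one side), which is what prevents leakage
#' through replicates.
#'
#' @param leaves Character vector of leaf ids.
#' @param bins Integer bin per leaf (e.g. from [quantile_bins()]).
#' @param n_out Number of leaves to hold out (0 <= n_out <= length(leaves)).
#' @param seed Integer seed.
#' @return List with `heldout` and `remaining` (disjoint leaf-id vectors).
#' @export
stratified_group_split <- function(leaves, bins, n_out, seed) {
  stopifnot(length(leaves) == length(bins))
  if (n_out < 0 || n_out > length(leaves)) {
    rlang::abort("`n_out` must be between 0 and the number of leaves.",
                 class = "chlorocal_stratification_error")
  }
  bin_ids <- sort(unique(bins))
  nb <- length(bin_ids)
  base <- n_out %/% nb
  rem <- n_out %% nb
  withr::with_seed(seed, {
    extra_bins <- if (rem > 0) sample(bin_ids)[seq_len(rem)] else integer(0)
    held <- character(0)
    for (b in bin_ids) {
      take <- base + as.integer(b %in% extra_bins)
      pool <- leaves[bins == b]
      if (take > length(pool)) {
        rlang::abort(sprintf(
          "Bin %s has %d leaves but %d are requested.", b, length(pool), take),
          class = "chlorocal_stratification_error")
      }
      if (take > 0) held <- c(held, sample(pool, take))
    }
  })
  list(heldout = held, remaining = setdiff(leaves, held))
}
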