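#' Fit a single-response PLS regression
#'
#' Single-y partial least squares (PLS1) via the NIPALS deflation algorithm.
#' Predictors are mean-centered (optionally unit-variance scaled); the
#' response is mean-centered. Because PLS components nest, the model stores
#' the full coefficient path for 1..`n_lv` latent variables, which the
#' cross-validation scan exploits to evaluate every component count from one
#' fit.
#'
#' @param x Numeric matrix (rows = spectra, columns = channels) or a tibble
#'   containing the channel columns.
#' @param y Numeric response vector (chlorophyll, ug/cm^2).
#' @param n_lv Number of latent variables, `1 <= n_lv <= min(ncol(x),
#'   nrow(x) - 1)`.
#' @param scale Logical; scale predictor columns to unit variance.
#' @return An object of class `pls_model` with elements `coefficients`,
#'   `intercept` (at `n_lv`), `coef_path` (p x n_lv), `intercept_path`,
#'   `n_lv`, `x_center`, `x_scale`, `y_center`, `channels`.
#' @export
fit_pls <- function(x, y, n_lv, scale = FALSE) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) {
    rlang::abort("`y` must have one value per row of `x`.",
                 class = "chlorocal_bad_argument")
  }
  if (n_lv < 1 || n_lv > min(p, n - 1)) {
    rlang::abort("`n_lv` must be between 1 and min(ncol(x), nrow(x) - 1).",
                 class = "chlorocal_lv_range")
  }
  x_center <- colMeans(x)
  x_scale <- rep(1, p)
  if (scale) {
    x_scale <- apply(x, 2, stats::sd)
    x_scale[x_scale == 0] <- 1
  }
  e <- sweep(sweep(x, 2, x_center), 2, x_scale, "/")
  if (all(abs(e) < 1e-12)) {
    rlang::abort("All predictor columns have zero variance.",
                 class = "chlorocal_degenerate_predictors")
  }
  y_center <- mean(y)
  f <- y - y_center

  w_mat <- matrix(0, p, n_lv)
  p_mat <- matrix(0, p, n_lv)
  q_vec <- numeric(n_lv)
  h_eff <- 0L
  for (h in seq_len(n_lv)) {
    w <- crossprod(e, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) break
    w <- w / nw
    t_h <- e %*% w
    tt <- sum(t_h^2)
    if (tt < 1e-12) break
    p_h <- crossprod(e, t_h) / tt
    q_h <- sum(f * t_h) / tt
    e <- e - tcrossprod(t_h, p_h)
    f <- f - q_h * t_h
    w_mat[, h] <- w
    p_mat[, h] <- p_h
    q_vec[h] <- q_h
    h_eff <- h
  }
  if (h_eff == 0L) {
    rlang::abort("Response is uncorrelated with all predictors (degenerate).",
                 class = "chlorocal_degenerate_predictors")
  }
  coef_path <- matrix(0, p, n_lv,
                      dimnames = list(colnames(x), NULL))
  for (k in seq_len(h_eff)) {
    wk <- w_mat[, seq_len(k), drop = FALSE]
    pk <- p_mat[, seq_len(k), drop = FALSE]
    b <- wk %*% solve(crossprod(pk, wk), q_vec[seq_len(k)])
    coef_path[, k] <- b / x_scale
  }
  if (h_eff < n_lv) {
    for (k in (h_eff + 1L):n_lv) coef_path[, k] <- coef_path[, h_eff]
  }
  intercept_path <- y_center - drop(x_center %*% coef_path)
  structure(
    list(
      coefficients = coef_path[, n_lv],
      intercept = intercept_path[n_lv],
      coef_path = coef_path,
      intercept_path = intercept_path,
      n_lv = n_lv,
      n_lv_effective = h_eff,
      x_center = x_center,
      x_scale = x_scale,
      y_center = y_center,
      channels = colnames(x)
    ),
    class = "pls_model"
  )
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %d latent variables over %d channels\n",
              x$n_lv, length(x$coefficients)))
  invisible(x)
}

pls_matrix <- function(model, newdata) {
  x <- as.matrix(if (is.data.frame(newdata) && !is.null(model$channels)) {
    newdata[model$channels]
  } else {
    newdata
  })
  if (ncol(x) != length(model$coefficients)) {
    rlang::abort("New data does not match the model's channel count.",
                 class = "chlorocal_channel_count")
  }
  x
}

#' Predict chlorophyll from spectra
#'
#' Affine prediction `X b + b0`. Negative predictions are reported unclipped.
#'
#' @param object A `pls_model`.
#' @param newdata Matrix or tibble with the model's channels.
#' @param n_lv Optionally predict with a smaller component count from the
#'   stored path.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.pls_model <- function(object, newdata, n_lv = object$n_lv, ...) {
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  x <- pls_matrix(object, newdata)
  drop(x %*% object$coef_path[, n_lv]) + object$intercept_path[n_lv]
}

#' Predictions along the whole component path
#'
#' @param model A `pls_model`.
#' @param newdata Matrix or tibble with the model's channels.
#' @return Matrix (rows x n_lv) of predictions for every component count.
#' @export
predict_pls_path <- function(model, newdata) {
  x <- pls_matrix(model, newdata)
  sweep(x %*% model$coef_path, 2, model$intercept_path, "+")
}

#' Leaf-level predictions
#'
#' The predicted chlorophyll of a leaf is the arithmetic mean of the
#' predictions for its surviving replicate spectra.
#'
#' @param model A `pls_model`.
#' @param newdata Matrix or tibble of replicate spectra.
#' @param leaf_id Character vector of leaf labels, one per row.
#' @return Named numeric vector of per-leaf predictions (sorted by leaf id).
#' @export
predict_leaf <- function(model, newdata, leaf_id) {
  pred <- predict(model, newdata)
  drop(rowsum(pred, leaf_id) / as.integer(table(leaf_id)))
}

#' Akaike Information Criterion for a fitted calibration
#'
#' `AIC = n * ln(RSS / n) + 2k` with `k` the number of latent variables and
#' `n` the number of evaluated observations (leaf-level predictions by
#' default in this package).
#'
#' @param rss Residual sum of squares (> 0); vectorized.
#' @param n Number of observations.
#' @param k Number of latent variables; vectorized with `rss`.
#' @return AIC score(s); lower is better.
#' @export
aic_score <- function(rss, n, k) {
  if (any(rss <= 0)) {
    rlang::abort("AIC is undefined for a perfect fit (RSS must be > 0).",
                 class = "chlorocal_perfect_fit")
  }
  if (n < 1 || any(k < 0)) {
    rlang::abort("`n` must be >= 1 and `k` >= 0.",
                 class = "chlorocal_bad_argument")
  }
  n * log(rss / n) + 2 * k
}

#' Goodness-of-fit summary
#'
#' @param y_true,y_pred Numeric vectors of equal length >= 2.
#' @return One-row tibble with `r2` (1 - SS_res/SS_tot), `mae`, `rss`, `n`.
#' @export
fit_score <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred) || length(y_true) < 2) {
    rlang::abort("Scores need two equal-length vectors of >= 2 values.",
                 class = "chlorocal_bad_argument")
  }
  rss <- sum((y_true - y_pred)^2)
  sstot <- sum((y_true - mean(y_true))^2)
  tibble::tibble(
    r2 = 1 - rss / sstot,
    mae = mean(abs(y_true - y_pred)),
    rss = rss,
    n = length(y_true)
  )
}

#' Restrict an 18-channel design to one chip
#'
#' @param x Matrix or tibble containing the full18 channel columns.
#' @param layout The `full18` `sensor_layout`.
#' @param chip_id Chip label present in the layout's chip map.
#' @return List with `x` (columns restricted to the chip's six channels,
#'   order preserved) and `layout` (a reduced layout of class
#'   `sensor_layout`).
#' @export
chip_subset <- function(x, layout, chip_id) {
  map <- chip_map(layout)
  if (!chip_id %in% names(map)) {
    rlang::abort(paste0("Unknown chip id: ", chip_id),
                 class = "chlorocal_unknown_chip")
  }
  keep <- layout$channels$chip_id == chip_id
  sub_layout <- structure(
    list(name = paste0(layout$name, "_", chip_id),
         channels = layout$channels[keep, , drop = FALSE]),
    class = "sensor_layout"
  )
  labels <- layout$channels$label[keep]
  x_sub <- if (is.data.frame(x)) x[labels] else x[, labels, drop = FALSE]
  list(x = x_sub, layout = sub_layout)
}

#' Export a fitted model to JSON
#'
#' Stores layout name, component count, coefficients and centering
#' statistics so the model can be reapplied to new CSV data.
#'
#' @param model A `pls_model`.
#' @param path Output file path.
#' @param layout_name Optional layout label to record.
#' @export
write_model <- function(model, path, layout_name = NULL) {
  obj <- list(
    layout = layout_name,
    n_lv = model$n_lv,
    channels = model$channels,
    coefficients = unname(model$coefficients),
    intercept = unname(model$intercept),
    x_center = unname(model$x_center),
    x_scale = unname(model$x_scale),
    y_center = model$y_center
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model exported by [write_model()]
#'
#' @param path JSON file path.
#' @return A `pls_model` usable with [predict.pls_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  coefs <- as.numeric(obj$coefficients)
  names(coefs) <- obj$channels
  coef_path <- matrix(coefs, ncol = 1, dimnames = list(obj$channels, NULL))
  structure(
    list(
      coefficients = coefs,
      intercept = as.numeric(obj$intercept),
      coef_path = coef_path,
      intercept_path = as.numeric(obj$intercept),
      n_lv = 1L,
      n_lv_effective = 1L,
      x_center = as.numeric(obj$x_center),
      x_scale = as.numeric(obj$x_scale),
      y_center = as.numeric(obj$y_center),
      channels = obj$channels
    ),
    class = "pls_model"
  )
}
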