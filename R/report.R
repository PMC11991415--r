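#' Sensor-by-species calibration report
#'
#' Runs the full pipeline (preprocessing, nested cross-validation) for every
#' requested sensor x species combination of a population and tabulates
#' validation scores, mirroring the study workflow's R^2/MAE heatmap as a
#' tidy table.
#'
#' @param population A `leaf_population` containing the species of interest.
#' @param sensors Layout names to evaluate (default: all in the population).
#' @param species Species to evaluate (default: all present).
#' @param outer_reps,inner_reps Repetition counts passed to [nested_cv()].
#' @param seed Master seed.
#' @param ... Further arguments to [build_modeling_data()].
#' @return Tibble with one row per sensor x species: modal chosen LV count
#'   and mean/SD of validation R^2 and MAE.
#' @export
calibration_report <- function(population,
                               sensors = names(population$spectra),
                               species = unique(population$leaves$species),
                               outer_reps = 10, inner_reps = 10,
                               seed = 1, ...) {
  rows <- list()
  for (sn in sensors) {
    for (sp in species) {
      data <- build_modeling_data(population, sn, species = sp, ...)
      cv <- nested_cv(data, outer_reps = outer_reps,
                      inner_reps = inner_reps,
                      seed = spawn_seed(seed, length(rows) + 1))
      tab <- table(cv$records$chosen_lv)
      rows[[length(rows) + 1]] <- tibble::tibble(
        sensor = sn, species = sp,
        n_leaves = cv$sizes$n_leaves,
        modal_lv = as.integer(names(which.max(tab))),
        validation_r2 = mean(cv$records$validation_r2),
        validation_r2_sd = stats::sd(cv$records$validation_r2),
        validation_mae = mean(cv$records$validation_mae),
        validation_mae_sd = stats::sd(cv$records$validation_mae)
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Plot an inner LV scan
#'
#' Mean AIC and mean test R^2 against component count, each with a +/- 1 SD
#' ribbon; the AIC minimum is marked.
#'
#' @param scan An `lv_scan`.
#' @return A ggplot object.
#' @export
plot_lv_scan <- function(scan) {
  tab <- scan$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$lv)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean_aic - .data$sd_aic,
                                      ymax = .data$mean_aic + .data$sd_aic),
                         fill = "darkgreen", alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_aic),
                       color = "darkgreen") +
    ggplot2::geom_vline(xintercept = scan$chosen_lv, linetype = "dashed") +
    ggplot2::labs(x = "Latent variables", y = "Mean AIC (test leaves)",
                  title = sprintf("AIC scan: minimum at %d LVs",
                                  scan$chosen_lv)) +
    ggplot2::theme_minimal()
}

#' Plot a learning curve
#'
#' @param curve A `learning_curve`.
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  tab <- tidyr::pivot_longer(
    curve$table, -"size",
    names_to = c("set", ".value"), names_pattern = "(train|test)_mae_(.*)"
  )
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$size, color = .data$set,
                                    fill = .data$set)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, color = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::labs(x = "Training leaves", y = "MAE (ug/cm2)",
                  title = sprintf("Learning curve (%d LVs)", curve$n_lv)) +
    ggplot2::theme_minimal()
}

#' Heatmap-style plot of a calibration report
#'
#' @param report Output of [calibration_report()].
#' @param metric `"validation_r2"` or `"validation_mae"`.
#' @return A ggplot object.
#' @export
plot_score_heatmap <- function(report,
                               metric = c("validation_r2",
                                          "validation_mae")) {
  metric <- rlang::arg_match(metric)
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$sensor, y = .data$species,
                               fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data[[metric]]))) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = metric) +
    ggplot2::theme_minimal()
}
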