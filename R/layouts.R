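#' Sensor channel layouts
#'
#' The three supported sensor layouts mirror the AMS multispectral chips used
#' for leaf measurements: `vis6` (six visible channels, 40 nm FWHM), `nir6`
#' (six red/NIR channels, 20 nm FWHM) and `full18` (eighteen UV--NIR channels
#' on three 6-channel chips, 20 nm FWHM each).
#'
#' For `full18` the mapping of channels to physical chips is configurable
#' because breakout-board documentation and observed intensity patterns
#' disagree on which chip hosts which channel; analyses that depend on the
#' chip map should record the map used (see [chip_map()]).
#'
#' @param name One of `"vis6"`, `"nir6"`, `"full18"`.
#' @param chip_map For `full18` only: a named list of three character vectors
#'   of channel labels (e.g. `"ch_410"`), one per chip, partitioning all 18
#'   channels. Defaults to [default_chip_map()].
#' @return An object of class `sensor_layout`: a list with elements `name`
#'   and `channels`, a tibble with columns `label`, `center_nm`, `fwhm_nm`
#'   and (for `full18`) `chip_id`.
#' @examples
#' sensor_layout("vis6")
#' sensor_layout("full18")$channels
#' @export
sensor_layout <- function(name = c("vis6", "nir6", "full18"), chip_map = NULL) {
  name <- rlang::arg_match(name)
  centers <- switch(name,
    vis6   = c(450, 500, 550, 570, 600, 650),
    nir6   = c(610, 680, 730, 760, 810, 860),
    full18 = c(410, 435, 460, 485, 510, 535, 560, 585, 610, 645, 680, 705,
               730, 760, 810, 860, 900, 940)
  )
  fwhm <- if (name == "vis6") 40 else 20
  channels <- tibble::tibble(
    label = paste0("ch_", centers),
    center_nm = centers,
    fwhm_nm = fwhm
  )
  if (name == "full18") {
    map <- if (is.null(chip_map)) default_chip_map() else chip_map
    validate_chip_map(map, channels$label)
    chip <- rep(NA_character_, nrow(channels))
    for (id in names(map)) chip[channels$label %in% map[[id]]] <- id
    channels$chip_id <- chip
  } else if (!is.null(chip_map)) {
    rlang::abort("`chip_map` is only meaningful for the full18 layout.",
                 class = "chlorocal_unknown_chip")
  }
  structure(list(name = name, channels = channels), class = "sensor_layout")
}

#' Default chip map for the 18-channel layout
#'
#' Chip A holds the six shortest wavelengths, chip C the red/NIR block that
#' coincides with the `nir6` layout, and chip B the remaining six channels.
#'
#' @return Named list of three character vectors of channel labels.
#' @export
default_chip_map <- function() {
  list(
    A = paste0("ch_", c(410, 435, 460, 485, 510, 535)),
    B = paste0("ch_", c(560, 585, 645, 705, 900, 940)),
    C = paste0("ch_", c(610, 680, 730, 760, 810, 860))
  )
}

validate_chip_map <- function(map, labels) {
  if (length(map) != 3 || is.null(names(map)) || anyDuplicated(names(map)) > 0) {
    rlang::abort("A chip map must name exactly three distinct chips.",
                 class = "chlorocal_unknown_chip")
  }
  all_ch <- unlist(map, use.names = FALSE)
  if (length(all_ch) != 18 || !setequal(all_ch, labels) ||
      anyDuplicated(all_ch) > 0 ||
      !all(lengths(map) == 6)) {
    rlang::abort(
      "Chip map must partition the 18 channels into three groups of six.",
      class = "chlorocal_unknown_chip"
    )
  }
  invisible(map)
}

#' All three sensor layouts
#'
#' @param chip_map Optional chip map passed to the `full18` layout.
#' @return Named list of `sensor_layout` objects (`vis6`, `nir6`, `full18`).
#' @export
sensor_layouts <- function(chip_map = NULL) {
  list(
    vis6 = sensor_layout("vis6"),
    nir6 = sensor_layout("nir6"),
    full18 = sensor_layout("full18", chip_map = chip_map)
  )
}

#' Channel column labels of a layout
#'
#' @param layout A `sensor_layout`.
#' @return Character vector like `c("ch_450", ...)` in wavelength order.
#' @export
channel_labels <- function(layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  layout$channels$label
}

#' Chip membership of a full18 layout
#'
#' @param layout A `full18` `sensor_layout`.
#' @return Named list of channel-label vectors, one per chip.
#' @export
chip_map <- function(layout) {
  stopifnot(inherits(layout, "sensor_layout"))
  if (layout$name != "full18") {
    rlang::abort("Chip membership is defined only for the full18 layout.",
                 class = "chlorocal_unknown_chip")
  }
  split(layout$channels$label, layout$channels$chip_id)
}

#' @export
print.sensor_layout <- function(x, ...) {
  cat(sprintf("<sensor_layout> %s: %d channels, %d-%d nm\n", x$name,
              nrow(x$channels), min(x$channels$center_nm),
              max(x$channels$center_nm)))
  invisible(x)
}

#' Read a sensor layout from a YAML configuration file
#'
#' The file must contain a `name` field; for `full18` an optional `chip_map`
#' mapping chip ids to lists of channel labels overrides the default.
#'
#' @param path Path to a YAML file.
#' @return A `sensor_layout`.
#' @export
read_layout_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$name)) {
    rlang::abort("Layout config must contain a `name` field.",
                 class = "chlorocal_config_error")
  }
  map <- if (!is.null(cfg$chip_map)) lapply(cfg$chip_map, unlist) else NULL
  sensor_layout(cfg$name, chip_map = map)
}
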