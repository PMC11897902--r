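#' Default pipeline configuration
#'
#' Builds the full configuration tree used by every pipeline stage. All
#' geometry is expressed in pixels and scales linearly with the image
#' width, so the same relative layout works for full-size (480 x 1440)
#' and reduced fixture images.
#'
#' Sections:
#' \describe{
#'   \item{segmentation}{`threshold` (0-255, green-magenta channel value
#'     below which a pixel counts as plant; default 120) and `min_size`
#'     (connected components smaller than this many pixels are treated
#'     as noise and removed; default 50).}
#'   \item{rois}{three circular tube regions for top-view images:
#'     `center_row`, `center_cols` (length 3) and `radius`.}
#'   \item{side}{side-view tube geometry: `tube_center_cols`,
#'     `tube_half_width` (columns scanned for the mat) and the barcode
#'     `crop_boxes`, one `[row0, col0, row1, col1]` box per position.}
#'   \item{depth}{`row_threshold_frac`: fraction of the tube pixel width
#'     a row's white-pixel count must reach to be counted toward mat
#'     depth (default 0.5, i.e. the culture must span half the tube).}
#'   \item{barcode}{decode search grid: `thresholds` (default
#'     60,80,...,220) and `rotations` in degrees (default 0, +-3, +-6,
#'     +-9, +-12, zero first).}
#'   \item{cameras}{`view` maps camera id 1-4 to "top"/"side";
#'     `pairs` lists top/side camera pairings; `pair_tolerance_s` is the
#'     maximum timestamp gap (seconds) when matching the two views.}
#'   \item{filter}{viability rule: `min_area_px` (default 1000) and
#'     `min_days` (default 15), plus `mode` = "span" (calendar span of a
#'     consecutive-observation run) or "count" (number of observations).}
#'   \item{rgr}{`window_days` (default 10) and `min_fit` (minimum
#'     adjusted R-squared, default 0.8).}
#'   \item{dose_response}{`n_boot` (default 500) and `baseline_mode`
#'     ("observed" = mean measured RGR at dose 0; "fitted" = upper
#'     asymptote d).}
#' }
#'
#' @param image_width,image_height pixel dimensions of the tube images
#'   the geometry should be laid out for.
#' @param seed master seed recorded in the config.
#' @return nested named list.
#' @export
default_config <- function(image_width = 1440L, image_height = 480L,
                           seed = 1L) {
  s <- image_width / 1440
  centers <- round(image_width * c(1, 3, 5) / 6)
  half <- round(150 * s)
  # barcode label band sits in the lower part of the side view
  box_r0 <- round(image_height * 0.58)
  box_r1 <- round(image_height * 0.92)
  crop_boxes <- lapply(centers, function(cc) {
    c(box_r0, max(1, cc - round(220 * s)), box_r1,
      min(image_width, cc + round(220 * s)))
  })
  list(
    image = list(width = as.integer(image_width),
                 height = as.integer(image_height)),
    segmentation = list(threshold = 120, min_size = 50),
    rois = list(center_row = round(image_height / 2),
                center_cols = centers,
                radius = round(150 * s)),
    side = list(tube_center_cols = centers,
                tube_half_width = half,
                waterline_row = round(image_height * 0.28),
                crop_boxes = crop_boxes),
    depth = list(row_threshold_frac = 0.5),
    barcode = list(thresholds = seq(60, 220, by = 20),
                   rotations = c(0, -3, 3, -6, 6, -9, 9, -12, 12)),
    cameras = list(view = c(`1` = "top", `2` = "side",
                            `3` = "top", `4` = "side"),
                   pairs = list(c(top = 1L, side = 2L),
                                c(top = 3L, side = 4L)),
                   pair_tolerance_s = 600),
    filter = list(min_area_px = 1000, min_days = 15, mode = "span"),
    rgr = list(window_days = 10, min_fit = 0.8),
    dose_response = list(n_boot = 500L, baseline_mode = "observed"),
    seed = as.integer(seed)
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations round-trip losslessly through YAML. Values absent from
#' the file fall back to [default_config()] defaults.
#'
#' @param path YAML file path.
#' @param config configuration list as returned by [default_config()].
#' @return `read_config()` returns the merged configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  w <- user$image$width %||% 1440L
  h <- user$image$height %||% 480L
  base <- default_config(w, h, seed = user$seed %||% 1L)
  cfg <- modify_list_deep(base, user)
  validate_config(cfg)
  cfg
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# recursive modifyList that replaces leaves but merges named lists
modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      base[[nm]] <- modify_list_deep(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$segmentation$threshold >= 0, cfg$segmentation$threshold <= 255,
    cfg$segmentation$min_size >= 0,
    length(cfg$rois$center_cols) == 3L,
    cfg$depth$row_threshold_frac > 0, cfg$depth$row_threshold_frac <= 1,
    all(cfg$barcode$thresholds >= 0 & cfg$barcode$thresholds <= 255),
    cfg$filter$min_area_px >= 0, cfg$filter$min_days >= 0,
    cfg$rgr$window_days > 0,
    cfg$rgr$min_fit <= 1,
    cfg$dose_response$n_boot >= 1
  )
  invisible(cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
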