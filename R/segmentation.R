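#' Green-magenta (a*) channel extraction
#'
#' Converts an RGB tube image to CIE LAB (sRGB primaries, D65 white
#' point) and returns the a* (green-magenta) channel rescaled to 0-255
#' by the 8-bit convention `a* + 128`, clipped. Plant material is green,
#' i.e. strongly negative a*, so plants map to LOW values and the
#' downstream binary threshold uses dark polarity.
#'
#' @param image a [tube_image()] or an H x W x 3 RGB array (0-255).
#' @return H x W numeric matrix with values in 0-255.
#' @export
to_greenmagenta <- function(image) {
  px <- if (inherits(image, "tube_image")) image$pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("expected an H x W x 3 RGB array")
  d <- dim(px)
  flat <- matrix(px, ncol = 3L) / 255
  lab <- grDevices::convertColor(flat, from = "sRGB", to = "Lab")
  a <- pmin(pmax(round(lab[, 2] + 128), 0), 255)
  matrix(a, nrow = d[1], ncol = d[2])
}

#' Binary thresholding of a grayscale channel
#'
#' @param gray H x W numeric matrix (0-255).
#' @param threshold cut value in 0-255.
#' @param polarity "dark" marks pixels strictly below the threshold as
#'   plant (the a*-channel convention); "light" marks pixels above it.
#' @return binary 0/1 integer matrix of the same shape.
#' @export
threshold_binary <- function(gray, threshold,
                             polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  if (threshold < 0 || threshold > 255)
    stop("threshold must be in [0, 255]")
  m <- if (polarity == "dark") gray < threshold else gray > threshold
  mask <- matrix(as.integer(m), nrow = nrow(gray))
  mask
}

#' Remove small connected components from a binary mask
#'
#' Noise speckles are removed by deleting every white 4-connected
#' component with fewer than `min_size` pixels; larger components are
#' left untouched. Idempotent.
#'
#' @param mask binary 0/1 matrix.
#' @param min_size minimum component pixel count to keep.
#' @return filtered binary mask.
#' @export
fill_noise <- function(mask, min_size) {
  stopifnot(min_size >= 0)
  if (min_size <= 1 || !any(mask == 1L)) return(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  drop <- which(sizes < min_size)
  if (length(drop)) mask[lab %in% drop] <- 0L
  mask
}

#' Lay out the three circular tube regions of interest
#'
#' @param image_shape `c(height, width)` in pixels.
#' @param config pipeline configuration; uses `rois$center_row`,
#'   `rois$center_cols`, `rois$radius`.
#' @return object of class `roi_set`: list with `centers` (3 x 2 matrix
#'   of row, col) and `radius`.
#' @export
partition_rois <- function(image_shape, config = default_config()) {
  r <- config$rois$radius
  row0 <- config$rois$center_row
  cols <- config$rois$center_cols
  if (length(cols) != 3L) stop("configuration error: need 3 ROI centers")
  centers <- cbind(row = rep(row0, 3L), col = cols)
  ok <- centers[, 1] - r >= 1 & centers[, 1] + r <= image_shape[1] &
        centers[, 2] - r >= 1 & centers[, 2] + r <= image_shape[2]
  if (!all(ok))
    stop("configuration error: ROI circle outside image bounds")
  if (any(diff(sort(cols)) < 2 * r))
    stop("configuration error: ROI circles overlap")
  structure(list(centers = centers, radius = r), class = "roi_set")
}

#' Per-tube plant area from a binary mask
#'
#' White 4-connected components are assigned to the ROI containing
#' their centroid; a component's full pixel area counts toward exactly
#' one ROI (components whose centroid falls in no ROI are discarded).
#'
#' @param mask binary 0/1 matrix.
#' @param rois a `roi_set` from [partition_rois()].
#' @return tibble with `roi_index` (0-2) and `area_px`.
#' @export
measure_areas <- function(mask, rois) {
  out <- tibble::tibble(roi_index = 0:2, area_px = 0L)
  if (!any(mask == 1L)) return(out)
  lab <- EBImage::bwlabel(mask)
  idx <- which(lab > 0, arr.ind = TRUE)
  comp <- lab[lab > 0]
  sizes <- tabulate(comp)
  cen_r <- tapply(idx[, 1], comp, mean)
  cen_c <- tapply(idx[, 2], comp, mean)
  r2 <- rois$radius^2
  areas <- integer(3)
  for (k in seq_along(sizes)) {
    d2 <- (cen_r[[k]] - rois$centers[, 1])^2 +
          (cen_c[[k]] - rois$centers[, 2])^2
    hit <- which(d2 <= r2)
    if (length(hit) == 1L) areas[hit] <- areas[hit] + sizes[k]
  }
  out$area_px <- areas
  out
}

#' Quantify one top-view image
#'
#' Full top-view workflow: green-magenta extraction, binary threshold
#' (dark polarity), speckle removal, circular ROI partition and
#' per-tube area measurement.
#'
#' @param image a [tube_image()] with `view == "top"`.
#' @param config pipeline configuration.
#' @return tibble with one row per tube position: `image_name`,
#'   `camera_id`, `timestamp`, `position` (0-2), `area_px`.
#' @export
quantify_top_image <- function(image, config = default_config()) {
  gray <- to_greenmagenta(image)
  mask <- threshold_binary(gray, config$segmentation$threshold, "dark")
  mask <- fill_noise(mask, config$segmentation$min_size)
  rois <- partition_rois(dim(gray), config)
  areas <- measure_areas(mask, rois)
  tibble::tibble(
    image_name = basename(if (is.na(image$path)) "" else image$path),
    camera_id = image$camera_id,
    timestamp = image$timestamp,
    position = areas$roi_index,
    area_px = areas$area_px
  )
}
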