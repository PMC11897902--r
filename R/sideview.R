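#' Floating-mat depth from a binary mask
#'
#' Scans every pixel row of the mask and counts its white pixels; a row
#' is included in the depth whenever that count reaches
#' `row_threshold`. Rows need not be contiguous; the threshold
#' suppresses sparse artifacts so depth is only accumulated where the
#' culture is dense enough to span the tube.
#'
#' @param mask binary 0/1 matrix (typically the tube's column range of
#'   the side-view mask).
#' @param row_threshold minimum white pixels per row (>= 1).
#' @return list with `depth_rows` and `row_threshold`.
#' @export
measure_mat_depth <- function(mask, row_threshold) {
  stopifnot(row_threshold >= 1)
  depth <- sum(rowSums(mask == 1L) >= row_threshold)
  list(depth_rows = as.integer(depth),
       row_threshold = row_threshold)
}

#' Crop the barcode label region and convert to grayscale
#'
#' @param image a [tube_image()] (side view).
#' @param crop_box `c(row0, col0, row1, col1)`, 1-based inclusive.
#' @return grayscale matrix (0-255, Rec.601 luma).
#' @export
crop_barcode_region <- function(image, crop_box) {
  px <- image$pixels
  d <- dim(px)
  b <- as.integer(round(crop_box))
  if (length(b) != 4L || b[1] < 1L || b[2] < 1L || b[3] > d[1] ||
      b[4] > d[2] || b[1] > b[3] || b[2] > b[4])
    stop("configuration error: crop box outside image bounds")
  sub <- px[b[1]:b[3], b[2]:b[4], , drop = FALSE]
  0.299 * sub[, , 1] + 0.587 * sub[, , 2] + 0.114 * sub[, , 3]
}

# Nearest-neighbour rotation about the matrix centre; angle in degrees,
# counter-clockwise positive. Pixels mapped from outside fill with
# `fill`. Nearest-neighbour keeps bar edges crisp at small angles.
rotate_nn <- function(mat, angle, fill = 255) {
  if (angle == 0) return(mat)
  h <- nrow(mat); w <- ncol(mat)
  th <- angle * pi / 180
  cr <- (h + 1) / 2; cc <- (w + 1) / 2
  out_r <- matrix(seq_len(h), h, w) - cr
  out_c <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  # inverse map: rotate output coords by -angle to find the source
  src_r <- round(cos(th) * out_r + sin(th) * out_c + cr)
  src_c <- round(-sin(th) * out_r + cos(th) * out_c + cc)
  ok <- src_r >= 1 & src_r <= h & src_c >= 1 & src_c <= w
  out <- matrix(fill, h, w)
  out[ok] <- mat[cbind(src_r[ok], src_c[ok])]
  out
}

#' Decode a barcode with a threshold/rotation retry search
#'
#' Tube labels vary in exposure and sit at slightly different angles,
#' so a single binarisation often fails. The search cycles candidate
#' rotations (outer loop, 0 degrees first) and binarisation thresholds
#' (inner loop), attempting a Code128 decode on several scanlines of
#' each variant, and returns the first success.
#'
#' @param region grayscale matrix (0-255) containing the label.
#' @param thresholds candidate binarisation cut values.
#' @param rotations candidate correction angles in degrees.
#' @return list with `payload` (string or `NA`), `attempts`,
#'   `winning_threshold` and `winning_rotation` (`NA` when undecoded).
#' @export
decode_barcode_robust <- function(region,
                                  thresholds = default_config()$barcode$thresholds,
                                  rotations = default_config()$barcode$rotations) {
  stopifnot(length(thresholds) >= 1L, length(rotations) >= 1L)
  attempts <- 0L
  h <- nrow(region)
  scan_rows <- unique(pmax(1L, pmin(h, round(h * c(0.5, 0.35, 0.65)))))
  for (rot in rotations) {
    rotated <- rotate_nn(region, rot, fill = 255)
    for (th in thresholds) {
      attempts <- attempts + 1L
      bin <- matrix(as.integer(rotated < th), nrow = h)
      for (sr in scan_rows) {
        payload <- code128_decode_line(bin[sr, ])
        if (!is.null(payload) && nchar(payload) > 0L) {
          return(list(payload = payload, attempts = attempts,
                      winning_threshold = th, winning_rotation = rot))
        }
      }
    }
  }
  list(payload = NA_character_, attempts = attempts,
       winning_threshold = NA_real_, winning_rotation = NA_real_)
}

#' Quantify one side-view image
#'
#' Per tube position: green-magenta segmentation of the tube's column
#' range, mat-depth measurement with the row-threshold rule, then
#' barcode crop and robust decode. Depth and barcode are independent:
#' an empty tube still gets its barcode read, and an undecodable
#' barcode still yields a depth (with a warning; record joining will
#' drop it).
#'
#' @param image a [tube_image()] with `view == "side"`.
#' @param config pipeline configuration.
#' @return tibble with one row per position: `image_name`, `camera_id`,
#'   `timestamp`, `position`, `depth_rows`, `barcode` (NA if
#'   undecoded), `decode_attempts`.
#' @export
quantify_side_image <- function(image, config = default_config()) {
  gray <- to_greenmagenta(image)
  mask <- threshold_binary(gray, config$segmentation$threshold, "dark")
  mask <- fill_noise(mask, config$segmentation$min_size)
  half <- config$side$tube_half_width
  row_thr <- max(1L, round(config$depth$row_threshold_frac * 2 * half))
  rows <- lapply(0:2, function(i) {
    cc <- config$side$tube_center_cols[i + 1L]
    c0 <- max(1L, cc - half); c1 <- min(ncol(mask), cc + half)
    depth <- measure_mat_depth(mask[, c0:c1, drop = FALSE], row_thr)
    region <- crop_barcode_region(image, config$side$crop_boxes[[i + 1L]])
    bc <- decode_barcode_robust(region, config$barcode$thresholds,
                                config$barcode$rotations)
    if (is.na(bc$payload))
      warning("barcode undecoded at position ", i, " in ",
              basename(if (is.na(image$path)) "<memory>" else image$path),
              call. = FALSE)
    tibble::tibble(
      image_name = basename(if (is.na(image$path)) "" else image$path),
      camera_id = image$camera_id,
      timestamp = image$timestamp,
      position = i,
      depth_rows = depth$depth_rows,
      barcode = bc$payload,
      decode_attempts = bc$attempts
    )
  })
  dplyr::bind_rows(rows)
}
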