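#' Tube image container
#'
#' A `tube_image` wraps one photograph of three culture tubes together
#' with its acquisition metadata: the view ("top" or "side"), the
#' timestamp and the camera id (1-4) parsed from the filename.
#'
#' @param pixels H x W x 3 numeric array of 8-bit RGB values (0-255).
#' @param view "top" or "side".
#' @param timestamp `POSIXct` acquisition time.
#' @param camera_id integer 1-4.
#' @param path source file path (optional).
#' @return object of class `tube_image`.
#' @export
tube_image <- function(pixels, view, timestamp = Sys.time(),
                       camera_id = 1L, path = NA_character_) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("pixels must be an H x W x 3 RGB array")
  view <- match.arg(view, c("top", "side"))
  camera_id <- as.integer(camera_id)
  if (!camera_id %in% 1:4) stop("camera_id must be in 1..4")
  structure(list(pixels = pixels, view = view,
                 timestamp = as.POSIXct(timestamp, tz = "UTC"),
                 camera_id = camera_id, path = path),
            class = "tube_image")
}

#' @export
print.tube_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<tube_image %dx%d %s cam%d %s>\n", d[1], d[2], x$view,
              x$camera_id, format(x$timestamp, "%Y-%m-%d %H:%M:%S")))
  invisible(x)
}

#' Parse an image filename into acquisition metadata
#'
#' Filenames follow `<YYYYMMDD-HHMMSS>_cam<N>.<ext>` as written by the
#' imaging rig and by [simulate_trial_images()]. The parser is kept
#' separate so other filename dialects can be added.
#'
#' @param path file path or bare filename.
#' @return list with `timestamp` (POSIXct, UTC) and `camera_id`, or
#'   `NULL` if the name does not match the pattern.
#' @export
parse_image_filename <- function(path) {
  nm <- basename(path)
  m <- regmatches(nm, regexec(
    "^(\\d{8})-(\\d{6})_cam([1-4])\\.(png|jpg|jpeg)$", nm,
    ignore.case = TRUE))[[1]]
  if (length(m) == 0L) return(NULL)
  ts <- as.POSIXct(paste0(m[2], m[3]), format = "%Y%m%d%H%M%S",
                   tz = "UTC")
  list(timestamp = ts, camera_id = as.integer(m[4]))
}

#' Read a tube image from disk
#'
#' PNG is read with \pkg{png}; JPEG falls back to
#' `EBImage::readImage()`. The view is derived from the camera id via
#' the config's camera->view map.
#'
#' @param path image file; name must parse via [parse_image_filename()].
#' @param config pipeline configuration ([default_config()]).
#' @return a [tube_image()].
#' @export
read_tube_image <- function(path, config = default_config()) {
  meta <- parse_image_filename(path)
  if (is.null(meta))
    stop("filename does not match <YYYYMMDD-HHMMSS>_cam<N>.<ext>: ",
         basename(path))
  ext <- tolower(tools::file_ext(path))
  px <- if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    a[, , 1:3, drop = FALSE] * 255
  } else {
    img <- EBImage::readImage(path)
    a <- EBImage::imageData(img)              # x,y[,c] = col,row
    if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
    aperm(a[, , 1:3, drop = FALSE], c(2, 1, 3)) * 255
  }
  view <- unname(config$cameras$view[[as.character(meta$camera_id)]])
  tube_image(px, view = view, timestamp = meta$timestamp,
             camera_id = meta$camera_id, path = path)
}

#' Write a tube image as PNG
#' @param image a [tube_image()].
#' @param path output path (`.png`).
#' @export
write_tube_image <- function(image, path) {
  png::writePNG(image$pixels / 255, path)
  invisible(path)
}

#' List parseable tube images in a directory
#'
#' @param dir directory to scan (non-recursive).
#' @return tibble with `path`, `timestamp`, `camera_id`, sorted by
#'   timestamp then camera.
#' @export
discover_images <- function(dir) {
  files <- list.files(dir, pattern = "\\.(png|jpg|jpeg)$",
                      ignore.case = TRUE, full.names = TRUE)
  rows <- lapply(files, function(f) {
    meta <- parse_image_filename(f)
    if (is.null(meta)) return(NULL)
    tibble::tibble(path = f, timestamp = meta$timestamp,
                   camera_id = meta$camera_id)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L)
    return(tibble::tibble(path = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          camera_id = integer()))
  dplyr::arrange(out, .data$timestamp, .data$camera_id)
}
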