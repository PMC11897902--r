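#' Join top-view and side-view records
#'
#' A top-view tube shows no barcode, so identity is carried by its
#' side-view partner: each top camera is paired with a fixed side
#' camera (config `cameras$pairs`), tubes keep their position index
#' across the pair, and the two exposures of one imaging pass are
#' matched by nearest timestamp within a tolerance window. The side
#' record contributes barcode and depth; the top record contributes
#' area and names the merged record.
#'
#' @param top_records tibble from [quantify_top_image()] batches.
#' @param side_records tibble from [quantify_side_image()] batches.
#' @param config pipeline configuration (`cameras$pairs`,
#'   `cameras$pair_tolerance_s`).
#' @return tibble of merged records: `image_name`, `camera_id`,
#'   `timestamp`, `area_px`, `barcode`, `depth_rows`. Side records with
#'   an undecoded barcode and top records with no side partner within
#'   tolerance are dropped with a warning.
#' @export
pair_views <- function(top_records, side_records,
                       config = default_config()) {
  tol <- config$cameras$pair_tolerance_s
  out <- list()
  n_nobc <- sum(is.na(side_records$barcode))
  if (n_nobc > 0L)
    warning(n_nobc, " side record(s) without decoded barcode dropped",
            call. = FALSE)
  side_ok <- side_records[!is.na(side_records$barcode), , drop = FALSE]
  n_unmatched <- 0L
  for (pair in config$cameras$pairs) {
    top_p <- top_records[top_records$camera_id == pair[["top"]], ,
                         drop = FALSE]
    side_p <- side_ok[side_ok$camera_id == pair[["side"]], ,
                      drop = FALSE]
    if (nrow(top_p) == 0L) next
    for (i in seq_len(nrow(top_p))) {
      cand <- side_p[side_p$position == top_p$position[i], ,
                     drop = FALSE]
      if (nrow(cand) == 0L) { n_unmatched <- n_unmatched + 1L; next }
      dt <- abs(as.numeric(difftime(cand$timestamp, top_p$timestamp[i],
                                    units = "secs")))
      j <- which.min(dt)
      if (dt[j] > tol) { n_unmatched <- n_unmatched + 1L; next }
      out[[length(out) + 1L]] <- tibble::tibble(
        image_name = top_p$image_name[i],
        camera_id = top_p$camera_id[i],
        timestamp = top_p$timestamp[i],
        area_px = top_p$area_px[i],
        barcode = cand$barcode[j],
        depth_rows = cand$depth_rows[j]
      )
    }
  }
  if (n_unmatched > 0L)
    warning(n_unmatched, " top record(s) without side partner dropped",
            call. = FALSE)
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L)
    return(tibble::tibble(image_name = character(),
                          camera_id = integer(),
                          timestamp = as.POSIXct(character(), tz = "UTC"),
                          area_px = integer(), barcode = character(),
                          depth_rows = integer()))
  dplyr::arrange(res, .data$barcode, .data$timestamp)
}

#' Read the barcode-to-sample map
#'
#' CSV with header `barcode,clone,condition_mM,replicate` linking each
#' tube label to its clone, added-sodium dose and replicate number.
#'
#' @param path CSV file.
#' @return tibble; barcodes are checked for uniqueness.
#' @export
read_barcode_map <- function(path) {
  if (!file.exists(path)) stop("barcode map not found: ", path)
  map <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(map) <- tolower(names(map))
  need <- c("barcode", "clone", "condition_mm", "replicate")
  if (!all(need %in% names(map)))
    stop("barcode map must have columns barcode, clone, condition_mM, replicate")
  if (anyDuplicated(map$barcode))
    stop("duplicate barcodes in map")
  tibble::tibble(barcode = as.character(map$barcode),
                 clone = as.character(map$clone),
                 condition_mM = as.numeric(map$condition_mm),
                 replicate = as.integer(map$replicate))
}

#' Assemble per-sample growth curves
#'
#' Groups merged records by barcode, sorts each group by timestamp,
#' converts timestamps to days elapsed since the sample's first
#' observation, and attaches clone/dose/replicate metadata from the
#' barcode map. Duplicate observations of one barcode within the same
#' imaging pass keep the later timestamp.
#'
#' @param records merged records from [pair_views()].
#' @param barcode_map tibble from [read_barcode_map()], or `NULL` to
#'   leave metadata empty.
#' @return long tibble (one row per observation): `barcode`,
#'   `elapsed_days`, `area_px`, `depth_rows`, `clone`, `condition_mM`,
#'   `replicate`, plus the source `timestamp`.
#' @export
assemble_curves <- function(records, barcode_map = NULL) {
  if (nrow(records) == 0L)
    return(tibble::tibble(barcode = character(),
                          elapsed_days = numeric(), area_px = integer(),
                          depth_rows = integer(), clone = character(),
                          condition_mM = numeric(), replicate = integer(),
                          timestamp = as.POSIXct(character(), tz = "UTC")))
  recs <- dplyr::arrange(records, .data$barcode, .data$timestamp)
  # collapse duplicate (barcode, pass): passes closer than 1h collapse
  # to the later timestamp
  recs <- dplyr::group_by(recs, .data$barcode)
  recs <- dplyr::mutate(recs, .pass = cumsum(
    c(1, diff(as.numeric(.data$timestamp)) > 3600)))
  dup <- dplyr::filter(dplyr::count(recs, .data$.pass), .data$n > 1L)
  if (nrow(dup) > 0L)
    warning(sum(dup$n) - nrow(dup),
            " duplicate observation(s) collapsed to later timestamp",
            call. = FALSE)
  recs <- dplyr::slice_tail(dplyr::group_by(recs, .data$barcode,
                                            .data$.pass), n = 1L)
  recs <- dplyr::group_by(recs, .data$barcode)
  recs <- dplyr::mutate(recs, elapsed_days =
    as.numeric(difftime(.data$timestamp, min(.data$timestamp),
                        units = "days")))
  recs <- dplyr::ungroup(recs)
  recs$.pass <- NULL
  if (!is.null(barcode_map)) {
    missing <- setdiff(unique(recs$barcode), barcode_map$barcode)
    if (length(missing) > 0L)
      warning(length(missing),
              " barcode(s) absent from map; metadata left empty",
              call. = FALSE)
    recs <- dplyr::left_join(recs, barcode_map, by = "barcode")
  } else {
    recs$clone <- NA_character_
    recs$condition_mM <- NA_real_
    recs$replicate <- NA_integer_
  }
  dplyr::select(recs, "barcode", "elapsed_days", "area_px",
                "depth_rows", "clone", "condition_mM", "replicate",
                "timestamp")
}

#' Write / read quantification records as CSV
#'
#' Schema (one row per tube per image pass):
#' `image_name,camera,timestamp,area,barcode,depth` with ISO-8601 UTC
#' timestamps. The reader tolerates case differences and the common
#' aliases `camera_number`/`camera_id`, `area_px`, `depth_rows`;
#' malformed rows are skipped with a warning naming the line.
#'
#' @param records merged records ([pair_views()] output).
#' @param path CSV path.
#' @return `read_records_csv()` returns the records tibble.
#' @export
write_records_csv <- function(records, path) {
  df <- data.frame(
    image_name = records$image_name,
    camera = records$camera_id,
    timestamp = format(records$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                       tz = "UTC"),
    area = records$area_px,
    barcode = records$barcode,
    depth = records$depth_rows
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  if (!file.exists(path)) stop("records file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  alias <- c(camera_number = "camera", camera_id = "camera",
             area_px = "area", depth_rows = "depth",
             image = "image_name", imagename = "image_name")
  for (a in names(alias))
    if (a %in% names(raw) && !(alias[[a]] %in% names(raw)))
      names(raw)[names(raw) == a] <- alias[[a]]
  need <- c("image_name", "camera", "timestamp", "area", "barcode",
            "depth")
  if (!all(need %in% names(raw)))
    stop("records CSV missing columns: ",
         paste(setdiff(need, names(raw)), collapse = ", "))
  ts <- as.POSIXct(raw$timestamp, format = "%Y-%m-%dT%H:%M:%S",
                   tz = "UTC")
  # fall back for space-separated timestamps; unparseable stay NA
  bad_ts <- is.na(ts)
  if (any(bad_ts))
    ts[bad_ts] <- as.POSIXct(raw$timestamp[bad_ts],
                             format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  area <- suppressWarnings(as.integer(raw$area))
  depth <- suppressWarnings(as.integer(raw$depth))
  ok <- !is.na(ts) & !is.na(area) & !is.na(depth) &
        !is.na(raw$barcode) & nzchar(raw$barcode)
  if (any(!ok))
    warning("skipped malformed row(s) at line(s): ",
            paste(which(!ok) + 1L, collapse = ", "), call. = FALSE)
  tibble::tibble(
    image_name = as.character(raw$image_name[ok]),
    camera_id = as.integer(raw$camera[ok]),
    timestamp = ts[ok],
    area_px = area[ok],
    barcode = as.character(raw$barcode[ok]),
    depth_rows = depth[ok]
  )
}

#' Write assembled curves as long-format CSV
#'
#' Columns: `barcode,elapsed_days,area_px,depth_rows,clone,
#' condition_mM,replicate`.
#'
#' @param curves tibble from [assemble_curves()].
#' @param path CSV path.
#' @export
write_curves_csv <- function(curves, path) {
  df <- curves[, c("barcode", "elapsed_days", "area_px", "depth_rows",
                   "clone", "condition_mM", "replicate")]
  utils::write.csv(as.data.frame(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) {
  if (!file.exists(path)) stop("curves file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(raw) <- sub("^condition_mm$", "condition_mM", tolower(names(raw)))
  tibble::as_tibble(raw)
}
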