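# Synthetic fixture generation: ground-truthed tube images and
# trial-scale growth tables emulating a salinity screen (6 clones x 6
# added-sodium doses x 6 replicates, imaged 5 days/week for 4 weeks).
# All generators are pure functions of (parameters, seed); rendered
# ground truth is counted from the drawn pixels, never from geometry
# formulas.

#' Salinity trial design
#'
#' Describes one screening trial: the clone panel with its true
#' dose-response parameters, the added-sodium doses, replication,
#' imaging schedule and growth/noise model. Defaults reproduce the
#' trial the package is calibrated for: 6 clones x doses
#' 0/50/100/200/300/400 mM x 6 replicates = 216 cultures, imaged 5
#' days a week for 4 weeks (20 imaging days), with every dose at or
#' above 200 mM lethal. Each clone's true growth rate at dose x is the
#' five-parameter log-logistic `ll5(x, b, 0, d, e, f)`; the most
#' tolerant clone ("Kashmir", d = 0.27 day^-1, e = 141.3 mM) grows at
#' 0.19 day^-1 (70% of optimum) under 100 mM.
#'
#' @param clones tibble with `clone`, `b`, `d`, `e`, `f` (true LL5
#'   parameters, lower asymptote fixed at 0).
#' @param doses_mM added-sodium doses.
#' @param replicates replicates per clone x dose.
#' @param lethal_dose_mM doses at or above this kill the culture.
#' @param start_date first imaging day (a Monday keeps the 5-of-7
#'   schedule aligned).
#' @param weeks,days_per_week imaging schedule.
#' @param A0 initial colony area (px).
#' @param carrying_capacity area ceiling (px).
#' @param lag_days growth lag after transplanting.
#' @param decay_rate area decay rate (day^-1) of lethal samples.
#' @param sigma lognormal measurement noise SD on areas.
#' @param barcode_fmt sprintf format for sample barcodes (short
#'   payloads render wider bars in reduced images).
#' @param seed generator seed.
#' @return object of class `trial_design`.
#' @export
trial_design <- function(clones = NULL,
                         doses_mM = c(0, 50, 100, 200, 300, 400),
                         replicates = 6L,
                         lethal_dose_mM = 200,
                         start_date = as.Date("2024-06-03"),
                         weeks = 4L, days_per_week = 5L,
                         A0 = 1500, carrying_capacity = 60000,
                         lag_days = 0, decay_rate = 0.5,
                         sigma = 0.05, barcode_fmt = "LG-%04d",
                         seed = 1L) {
  if (is.null(clones)) {
    clones <- tibble::tibble(
      clone = c("France", "Germany", "Greece", "Israel", "Kashmir",
                "Saudi"),
      b = 2.5,
      d = c(0.24, 0.28, 0.30, 0.26, 0.27, 0.25),
      e = c(105, 125, 118, 135, 141.3, 120),
      f = 1)
  }
  stopifnot(all(c("clone", "b", "d", "e", "f") %in% names(clones)))
  structure(list(clones = clones, doses_mM = doses_mM,
                 replicates = as.integer(replicates),
                 lethal_dose_mM = lethal_dose_mM,
                 start_date = start_date, weeks = as.integer(weeks),
                 days_per_week = as.integer(days_per_week),
                 A0 = A0, carrying_capacity = carrying_capacity,
                 lag_days = lag_days, decay_rate = decay_rate,
                 sigma = sigma, barcode_fmt = barcode_fmt,
                 seed = as.integer(seed)),
            class = "trial_design")
}

#' Reduced design for fast end-to-end runs
#'
#' One clone over a five-dose panel with two replicates, same
#' schedule, sized for rendered-image pipelines (smaller starting area
#' so growth stays within a reduced tube).
#' @param seed generator seed.
#' @param sigma lognormal noise SD.
#' @export
mini_design <- function(seed = 1L, sigma = 0.02) {
  trial_design(
    clones = tibble::tibble(clone = "Kashmir", b = 2.5, d = 0.27,
                            e = 141.3, f = 1),
    doses_mM = c(0, 50, 100, 150, 200),
    replicates = 2L, lethal_dose_mM = Inf,
    A0 = 500, carrying_capacity = 7000,
    sigma = sigma, barcode_fmt = "S%02d", seed = seed)
}

#' Imaging dates of a design
#' @param design a [trial_design()].
#' @return Date vector (weekdays only, `weeks * days_per_week` days).
#' @export
imaging_dates <- function(design) {
  all_days <- design$start_date + seq_len(7L * design$weeks) - 1L
  wd <- as.integer(format(all_days, "%u"))
  weekdays_only <- all_days[wd <= design$days_per_week]
  utils::head(weekdays_only, design$weeks * design$days_per_week)
}

#' True EC50 of a design clone
#'
#' Analytic inverse of the clone's generating LL5 curve at half its
#' optimal (dose 0) rate: `e * ((2^(1/f) - 1))^(1/b)` scaled from the
#' log form.
#' @param design a [trial_design()].
#' @return tibble with `clone` and `true_ec50_mM`.
#' @export
true_ec50 <- function(design) {
  cl <- design$clones
  tibble::tibble(clone = cl$clone,
                 true_ec50_mM = cl$e * exp(log(2^(1 / cl$f) - 1) / cl$b))
}

#' Simulate trial growth curves
#'
#' Each sample follows `area(t) = A0 * exp(r * max(0, t - lag))`
#' capped at the carrying capacity and multiplied by lognormal noise
#' `exp(N(0, sigma^2))`; the true rate r is the clone's LL5 response
#' at its dose. Lethal samples decay exponentially instead. Areas are
#' sampled on the weekday imaging schedule.
#'
#' @param design a [trial_design()].
#' @return list with `curves` (long tibble compatible with
#'   [assemble_curves()] output), `truth` (per-sample true rates and
#'   lethality) and `barcode_map`.
#' @export
simulate_trial_curves <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  dates <- imaging_dates(design)
  tdays <- as.numeric(dates - dates[1])
  grid <- expand.grid(replicate = seq_len(design$replicates),
                      condition_mM = design$doses_mM,
                      clone = design$clones$clone,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$clone, grid$condition_mM, grid$replicate), ]
  grid$barcode <- sprintf(design$barcode_fmt, seq_len(nrow(grid)))
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed)
  curves <- list(); truth <- list()
  for (i in seq_len(nrow(grid))) {
    cl <- design$clones[design$clones$clone == grid$clone[i], ]
    dose <- grid$condition_mM[i]
    lethal <- dose >= design$lethal_dose_mM
    r <- ll5(dose, cl$b, 0, cl$d, cl$e, cl$f)
    mu <- if (lethal) {
      design$A0 * exp(-design$decay_rate * tdays)
    } else {
      pmin(design$carrying_capacity,
           design$A0 * exp(r * pmax(0, tdays - design$lag_days)))
    }
    # areas stay real-valued here; pixel quantisation is an imaging
    # effect applied when scenes are rasterised
    area <- pmax(0, mu * exp(stats::rnorm(length(mu), 0, design$sigma)))
    curves[[i]] <- tibble::tibble(
      barcode = grid$barcode[i], elapsed_days = tdays,
      area_px = area, depth_rows = NA_integer_,
      clone = grid$clone[i], condition_mM = dose,
      replicate = grid$replicate[i],
      timestamp = as.POSIXct(paste(dates, "10:00:00"), tz = "UTC"))
    truth[[i]] <- tibble::tibble(
      barcode = grid$barcode[i], clone = grid$clone[i],
      condition_mM = dose, replicate = grid$replicate[i],
      true_rgr = if (lethal) NA_real_ else r, lethal = lethal)
  }
  list(curves = dplyr::bind_rows(curves),
       truth = dplyr::bind_rows(truth),
       barcode_map = tibble::tibble(
         barcode = grid$barcode, clone = grid$clone,
         condition_mM = grid$condition_mM,
         replicate = grid$replicate))
}

# ---------------------------------------------------------------- #
# Scene rendering                                                   #
# ---------------------------------------------------------------- #

# pixel membership of an axis-aligned ellipse clipped to the tube circle
ellipse_pixels <- function(center, semi_r, semi_c, tube_center,
                           tube_radius, H, W) {
  r0 <- max(1L, floor(center[1] - semi_r)); r1 <- min(H, ceiling(center[1] + semi_r))
  c0 <- max(1L, floor(center[2] - semi_c)); c1 <- min(W, ceiling(center[2] + semi_c))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), ncol = 2))
  rr <- r0:r1; cc <- c0:c1
  R <- matrix(rr, length(rr), length(cc))
  C <- matrix(cc, length(rr), length(cc), byrow = TRUE)
  inside <- ((R - center[1]) / semi_r)^2 + ((C - center[2]) / semi_c)^2 <= 1
  inside <- inside & ((R - tube_center[1])^2 + (C - tube_center[2])^2
                      <= tube_radius^2)
  cbind(R[inside], C[inside])
}

disk_pixels <- function(center, radius, H, W) {
  ellipse_pixels(center, radius, radius, center, radius + 1, H, W)
}

#' Build a scene manifest for one three-tube image pair
#'
#' @param areas_px length-3 target plant areas (top view).
#' @param depth_rows length-3 mat depths (side view).
#' @param payloads length-3 barcode payloads.
#' @param rotations_deg length-3 label rotations (degrees).
#' @param contrast list of 3 `c(lo, hi)` gray ranges for the label.
#' @param config pipeline configuration giving the geometry.
#' @return list of class `scene_manifest`.
#' @export
scene_manifest <- function(areas_px, depth_rows, payloads,
                           rotations_deg = c(0, 0, 0),
                           contrast = rep(list(c(40, 215)), 3),
                           config = default_config()) {
  stopifnot(length(areas_px) == 3L, length(depth_rows) == 3L,
            length(payloads) == 3L)
  structure(list(areas_px = areas_px, depth_rows = depth_rows,
                 payloads = payloads, rotations_deg = rotations_deg,
                 contrast = contrast, config = config,
                 rendered_area_px = rep(NA_integer_, 3L)),
            class = "scene_manifest")
}

#' Render a top-view tube image
#'
#' Draws three circular tube openings on a neutral background and one
#' green elliptical colony per tube sized to the manifest's target
#' area (plant-like RGB near (60, 140, 60) with per-pixel jitter),
#' plus small glare speckles kept off the colonies. The manifest is
#' returned with `rendered_area_px` set to the exact pixel count of
#' each drawn colony, which is the segmentation ground truth.
#'
#' @param manifest a [scene_manifest()].
#' @param seed RNG seed (placement jitter, colour jitter, glare).
#' @return list with `image` (a [tube_image()]) and `manifest`.
#' @export
render_top_image <- function(manifest, seed = 1L) {
  cfg <- manifest$config
  H <- cfg$image$height; W <- cfg$image$width
  rois <- partition_rois(c(H, W), cfg)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- 184; px[, , 2] <- 184; px[, , 3] <- 189
  colony_mask <- matrix(FALSE, H, W)
  for (i in 1:3) {
    ctr <- rois$centers[i, ]; rad <- rois$radius
    rim <- disk_pixels(ctr, rad, H, W)
    water <- disk_pixels(ctr, rad - max(2, round(rad * 0.04)), H, W)
    for (ch in 1:3) {
      px[cbind(rim, ch)] <- c(120, 120, 124)[ch]
      px[cbind(water, ch)] <- c(160, 161, 168)[ch]
    }
    area <- manifest$areas_px[i]
    if (is.na(area) || area < 1) next
    rho <- stats::runif(1, 0.7, 1)
    a <- sqrt(area / (pi * rho))
    amax <- 0.9 * rad
    if (a > amax) a <- amax
    b <- min(area / (pi * a), amax)
    room <- max(0, 0.92 * rad - max(a, b))
    off <- stats::runif(2, -room / 2, room / 2)
    pts <- ellipse_pixels(ctr + off, a, b, ctr, rad - 1, H, W)
    if (nrow(pts) == 0L) next
    jit <- matrix(stats::rnorm(nrow(pts) * 3, 0, 8), ncol = 3)
    base <- c(60, 140, 60)
    for (ch in 1:3)
      px[cbind(pts, ch)] <- pmin(255, pmax(0, base[ch] + jit[, ch]))
    colony_mask[pts] <- TRUE
    manifest$rendered_area_px[i] <- nrow(pts)
  }
  # glare speckles inside tubes, never on a colony
  for (i in 1:3) {
    for (k in seq_len(3L)) {
      ctr <- rois$centers[i, ]
      ang <- stats::runif(1, 0, 2 * pi)
      rr <- stats::runif(1, 0.3, 0.85) * rois$radius
      p <- c(ctr[1] + rr * sin(ang), ctr[2] + rr * cos(ang))
      spk <- disk_pixels(p, stats::runif(1, 2, 4), H, W)
      if (nrow(spk) == 0L || any(colony_mask[spk])) next
      for (ch in 1:3) px[cbind(spk, ch)] <- 244
    }
  }
  manifest$rendered_area_px[is.na(manifest$areas_px) |
                            manifest$areas_px < 1] <- 0L
  list(image = tube_image(px, "top"), manifest = manifest)
}

# grayscale label matrix carrying a Code128 barcode; module width is
# fitted to the available box width
render_label <- function(payload, box_w, box_h, lo, hi) {
  bits <- code128_encode(payload)
  quiet <- 10L
  modules <- length(bits) + 2L * quiet
  mw <- max(1L, floor(0.9 * box_w / modules))
  line <- rep(c(rep(0L, quiet), bits, rep(0L, quiet)), each = mw)
  bar_h <- max(8L, round(box_h * 0.6))
  lab_w <- length(line)
  lab <- matrix(hi, nrow = bar_h, ncol = lab_w)
  lab[, line == 1L] <- lo
  pad_r <- max(2L, round((box_h - bar_h) / 2))
  rbind(matrix(hi, pad_r, lab_w), lab, matrix(hi, pad_r, lab_w))
}

#' Render a side-view tube image
#'
#' Per tube: a green mat band of exactly the manifest's row depth
#' spanning the tube's width at the waterline, and a Code128 label
#' rendered at the manifest's rotation and contrast inside the
#' position's barcode crop box.
#'
#' @param manifest a [scene_manifest()].
#' @param seed RNG seed (colour jitter).
#' @return list with `image` (a [tube_image()]) and `manifest`.
#' @export
render_side_image <- function(manifest, seed = 1L) {
  cfg <- manifest$config
  H <- cfg$image$height; W <- cfg$image$width
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  px <- array(0, c(H, W, 3))
  px[, , 1] <- 184; px[, , 2] <- 184; px[, , 3] <- 189
  half <- cfg$side$tube_half_width
  wl <- cfg$side$waterline_row
  for (i in 1:3) {
    cc <- cfg$side$tube_center_cols[i]
    c0 <- max(1L, cc - half); c1 <- min(W, cc + half)
    # tube body slightly darker than background
    px[, c0:c1, 1] <- 168; px[, c0:c1, 2] <- 169; px[, c0:c1, 3] <- 175
    depth <- manifest$depth_rows[i]
    box <- cfg$side$crop_boxes[[i]]
    max_depth <- box[1] - wl - 4L
    if (!is.na(depth) && depth > 0) {
      if (depth > max_depth)
        stop("generation error: mat band taller than tube (",
             depth, " > ", max_depth, " rows)")
      rows <- wl:(wl + depth - 1L)
      n <- length(rows) * (c1 - c0 + 1L)
      jit <- matrix(stats::rnorm(n * 3, 0, 8), ncol = 3)
      base <- c(60, 140, 60)
      grid_idx <- as.matrix(expand.grid(rows, c0:c1))
      for (ch in 1:3)
        px[cbind(grid_idx, ch)] <-
          pmin(255, pmax(0, base[ch] + jit[, ch]))
    }
    # barcode label
    ctr <- c(mean(c(box[1], box[3])), mean(c(box[2], box[4])))
    lohi <- manifest$contrast[[i]]
    lab <- render_label(manifest$payloads[i],
                        box[4] - box[2] + 1L, box[3] - box[1] + 1L,
                        lohi[1], lohi[2])
    rot <- manifest$rotations_deg[i]
    if (rot != 0) {
      # rotate inside a square canvas so corners are preserved
      side <- ceiling(sqrt(nrow(lab)^2 + ncol(lab)^2))
      canvas <- matrix(NA_real_, side, side)
      r_off <- floor((side - nrow(lab)) / 2)
      c_off <- floor((side - ncol(lab)) / 2)
      canvas[r_off + seq_len(nrow(lab)),
             c_off + seq_len(ncol(lab))] <- lab
      lab <- rotate_nn(canvas, rot, fill = NA_real_)
    }
    lr0 <- round(ctr[1] - nrow(lab) / 2); lc0 <- round(ctr[2] - ncol(lab) / 2)
    rr <- lr0 + seq_len(nrow(lab)) - 1L
    ccg <- lc0 + seq_len(ncol(lab)) - 1L
    keep_r <- rr >= 1L & rr <= H; keep_c <- ccg >= 1L & ccg <= W
    sub <- lab[keep_r, keep_c, drop = FALSE]
    tgt_r <- rr[keep_r]; tgt_c <- ccg[keep_c]
    def <- !is.na(sub)
    idx <- which(def, arr.ind = TRUE)
    coords <- cbind(tgt_r[idx[, 1]], tgt_c[idx[, 2]])
    for (ch in 1:3) px[cbind(coords, ch)] <- sub[def]
  }
  list(image = tube_image(px, "side"), manifest = manifest)
}

#' Render a full trial as an image directory
#'
#' Composes [simulate_trial_curves()] with the two renderers: every
#' sample/day becomes one tube slot in paired top and side three-tube
#' images with consistent camera-pair and position assignment,
#' timestamped filenames (`<YYYYMMDD-HHMMSS>_cam<N>.png`), a
#' `Barcode_Sample_Map.csv` and a truth table holding the exact
#' rendered areas.
#'
#' @param design a [trial_design()]; for rendered trials the areas
#'   must stay within the tube, so cap/A0 should be sized to the image
#'   geometry (see [mini_design()]).
#' @param out_dir output directory (created).
#' @param config pipeline configuration defining image geometry; the
#'   same config should be used to quantify the rendered images.
#' @return list with `dir`, `map_path`, `truth` (per sample/day:
#'   barcode, elapsed_days, area_px target, rendered_area_px,
#'   depth_rows), `curves` (the generating curves) and `n_images`.
#' @export
simulate_trial_images <- function(design, out_dir,
                                  config = default_config()) {
  sim <- simulate_trial_curves(design)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dates <- imaging_dates(design)
  samples <- sim$barcode_map$barcode
  n_groups <- ceiling(length(samples) / 3L)
  half <- config$side$tube_half_width
  box1 <- config$side$crop_boxes[[1]]
  max_depth <- box1[1] - config$side$waterline_row - 4L
  cap_area <- 0.8 * pi * config$rois$radius^2
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(design$seed + 211L)
  rot_grid <- c(0, -3, 3, -6, 6, -9, 9)
  rows <- list(); n_images <- 0L
  for (di in seq_along(dates)) {
    day_curves <- sim$curves[sim$curves$timestamp ==
      as.POSIXct(paste(dates[di], "10:00:00"), tz = "UTC"), ]
    for (g in seq_len(n_groups)) {
      idx <- ((g - 1L) * 3L + 1L):min(g * 3L, length(samples))
      bcs <- samples[idx]
      slot <- match(bcs, day_curves$barcode)
      areas <- round(pmin(day_curves$area_px[slot], cap_area))
      depths <- pmin(max_depth,
                     pmax(0L, round(areas / (2 * half))))
      pair <- config$cameras$pairs[[(g - 1L) %% length(config$cameras$pairs) + 1L]]
      ts_top <- as.POSIXct(paste(dates[di], "10:00:00"), tz = "UTC") +
        (g - 1L) * 40
      ts_side <- ts_top + 5
      pads <- function(v, fill) { length(v) <- 3L; v[is.na(v)] <- fill; v }
      man <- scene_manifest(
        areas_px = pads(areas, 0),
        depth_rows = pads(depths, 0),
        payloads = pads(bcs, "VOID"),
        rotations_deg = sample(rot_grid, 3L, replace = TRUE),
        contrast = replicate(3L, c(stats::runif(1, 30, 90),
                                   stats::runif(1, 150, 225)),
                             simplify = FALSE),
        config = config)
      seed_g <- design$seed + 1000L * di + g
      top <- render_top_image(man, seed = seed_g)
      side <- render_side_image(top$manifest, seed = seed_g + 1L)
      fn <- function(ts, cam) file.path(out_dir, sprintf(
        "%s_cam%d.png", format(ts, "%Y%m%d-%H%M%S", tz = "UTC"), cam))
      top$image$timestamp <- ts_top
      top$image$camera_id <- pair[["top"]]
      side$image$timestamp <- ts_side
      side$image$camera_id <- pair[["side"]]
      write_tube_image(top$image, fn(ts_top, pair[["top"]]))
      write_tube_image(side$image, fn(ts_side, pair[["side"]]))
      n_images <- n_images + 2L
      rows[[length(rows) + 1L]] <- tibble::tibble(
        barcode = bcs, elapsed_days = as.numeric(dates[di] - dates[1]),
        area_px = areas[seq_along(bcs)],
        rendered_area_px = top$manifest$rendered_area_px[seq_along(bcs)],
        depth_rows = depths[seq_along(bcs)])
    }
  }
  map_path <- file.path(out_dir, "Barcode_Sample_Map.csv")
  utils::write.csv(as.data.frame(sim$barcode_map), map_path,
                   row.names = FALSE, quote = FALSE)
  list(dir = out_dir, map_path = map_path,
       truth = dplyr::bind_rows(rows), curves = sim$curves,
       truth_rgr = sim$truth, n_images = n_images)
}
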