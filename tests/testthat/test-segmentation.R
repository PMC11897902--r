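# Top-view segmentation: a* channel, thresholding, noise removal,
# ROI partition and per-tube area measurement.

solid_rgb <- function(h, w, rgb) {
  px <- array(0, c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  px
}

test_that("green-magenta channel maps green low, magenta high, gray mid", {
  # reference a* values computed with an independent sRGB->Lab
  # implementation (scikit-image 0.26): green -86.18, magenta +98.23,
  # gray ~0; the 8-bit convention adds 128 and clips
  g <- to_greenmagenta(solid_rgb(2, 2, c(0, 255, 0)))
  m <- to_greenmagenta(solid_rgb(2, 2, c(255, 0, 255)))
  n <- to_greenmagenta(solid_rgb(2, 2, c(128, 128, 128)))
  expect_true(all(g < 128))
  expect_equal(unique(as.vector(g)), -86 + 128, tolerance = 0.02)
  expect_true(all(m > 128))
  expect_equal(unique(as.vector(m)), 98 + 128, tolerance = 0.02)
  expect_true(all(n == 128))
  expect_error(to_greenmagenta(matrix(0, 4, 4)), "RGB")
})

test_that("binary threshold counts exactly the sub-threshold pixels", {
  u <- matrix(200, 20, 20)
  expect_equal(sum(threshold_binary(u, 120, "dark")), 0)
  img <- matrix(220, 40, 40)
  img[11:20, 21:30] <- 40
  mask <- threshold_binary(img, 120, "dark")
  expect_equal(sum(mask), 100)
  expect_setequal(unique(as.vector(mask)), c(0L, 1L))
  expect_error(threshold_binary(u, 300, "dark"), "0, 255")
})

test_that("fill_noise removes exactly the sub-size components", {
  m <- matrix(0L, 30, 30)
  m[2:3, 2:3] <- 1L                      # 4 px
  m[10:19, 10:14] <- 1L                  # 50 px
  expect_equal(sum(fill_noise(m, 10)), 50)
  expect_equal(fill_noise(m, 0), m)
  # all-singleton speckle field vanishes at min_size 2
  set.seed(41)
  sp <- matrix(0L, 40, 40)
  sp[cbind(seq(2, 38, by = 4), seq(2, 38, by = 4))] <- 1L
  lab <- bfs_label(sp)
  expect_true(all(tabulate(lab[lab > 0]) == 1L))
  expect_equal(sum(fill_noise(sp, 2)), 0)
})

test_that("fill_noise is idempotent and monotone in min_size", {
  set.seed(7)
  for (k in 1:10) {
    m <- random_mask(48, 48, 0.35)
    f1 <- fill_noise(m, 5)
    expect_identical(fill_noise(f1, 5), f1)
    expect_lte(sum(fill_noise(m, 12)), sum(f1))
  }
})

test_that("ROI partition validates geometry", {
  cfg <- default_config()
  rois <- partition_rois(c(480, 1440), cfg)
  expect_equal(nrow(rois$centers), 3)
  expect_equal(rois$centers[, 2], c(240, 720, 1200))
  bad <- cfg; bad$rois$radius <- 400
  expect_error(partition_rois(c(480, 1440), bad), "configuration")
  narrow <- cfg; narrow$rois$center_cols <- c(200, 300, 400)
  expect_error(partition_rois(c(480, 1440), narrow), "configuration")
})

test_that("per-ROI areas match ground truth and the labelling oracle", {
  cfg <- default_config()
  rois <- partition_rois(c(480, 1440), cfg)
  mask <- matrix(0L, 480, 1440)
  expect_equal(measure_areas(mask, rois)$area_px, c(0L, 0L, 0L))
  # one disk of radius 30 centred in ROI 1 (index 0): ~ pi * 30^2
  ctr <- rois$centers[1, ]
  for (i in (ctr[1] - 31):(ctr[1] + 31)) for (j in (ctr[2] - 31):(ctr[2] + 31))
    if ((i - ctr[1])^2 + (j - ctr[2])^2 <= 30^2) mask[i, j] <- 1L
  a <- measure_areas(mask, rois)
  expect_equal(a$area_px[1], sum(mask))
  expect_equal(a$area_px[1], pi * 30^2, tolerance = 0.02)
  # three rectangles of known size, one per ROI, measured exactly
  mask <- matrix(0L, 480, 1440)
  sizes <- c(120, 450, 900)
  dims <- list(c(10, 12), c(18, 25), c(30, 30))
  for (r in 1:3) {
    ctr <- rois$centers[r, ]
    mask[ctr[1] + seq_len(dims[[r]][1]) - 5, ctr[2] + seq_len(dims[[r]][2]) - 5] <- 1L
  }
  expect_equal(measure_areas(mask, rois)$area_px, sizes)
})

test_that("measure_areas agrees exactly with the brute-force oracle", {
  set.seed(11)
  centers <- cbind(row = c(20, 20, 20), col = c(12, 32, 52))
  rois <- structure(list(centers = centers, radius = 9),
                    class = "roi_set")
  for (k in 1:25) {
    m <- random_mask(40, 64, runif(1, 0.1, 0.5))
    got <- measure_areas(m, rois)$area_px
    expect_identical(as.integer(got),
                     as.integer(areas_oracle(m, centers, 9)))
    # area conservation: assigned areas never exceed mask total
    expect_lte(sum(got), sum(m))
  }
})

test_that("raising the dark threshold never shrinks the mask or tube areas", {
  # mask-level monotonicity holds unconditionally
  set.seed(5)
  gray <- matrix(runif(64 * 64, 0, 255), 64, 64)
  prev <- 0L
  for (th in c(60, 120, 180, 240)) {
    cur <- sum(threshold_binary(gray, th, "dark"))
    expect_gte(cur, prev)
    prev <- cur
  }
  # per-tube areas are monotone on separated scenes (one graded blob
  # per ROI); component merging across ROIs cannot occur here
  cfg <- default_config()
  rois <- partition_rois(c(480, 1440), cfg)
  gray <- matrix(230, 480, 1440)
  for (r in 1:3) {
    ctr <- rois$centers[r, ]
    for (i in -40:40) for (j in -40:40) {
      d <- sqrt(i^2 + j^2)
      if (d <= 40) gray[ctr[1] + i, ctr[2] + j] <- 40 + d * 3
    }
  }
  prev <- c(0L, 0L, 0L)
  for (th in c(60, 100, 140, 180)) {
    cur <- measure_areas(threshold_binary(gray, th, "dark"), rois)$area_px
    expect_true(all(cur >= prev))
    prev <- cur
  }
})

test_that("rendered colonies are quantified to their exact pixel truth", {
  cfg <- default_config()
  man <- scene_manifest(areas_px = c(2827, 0, 520),
                        depth_rows = c(0, 0, 0),
                        payloads = c("A1", "A2", "A3"), config = cfg)
  top <- render_top_image(man, seed = 9)
  out <- quantify_top_image(top$image, cfg)
  expect_equal(out$area_px, top$manifest$rendered_area_px)
  expect_equal(out$area_px, man$areas_px, tolerance = 0.05)
  # all-background scene
  blank <- render_top_image(scene_manifest(c(0, 0, 0), c(0, 0, 0),
                                           c("B1", "B2", "B3"),
                                           config = cfg), seed = 2)
  expect_equal(quantify_top_image(blank$image, cfg)$area_px, c(0L, 0L, 0L))
})
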