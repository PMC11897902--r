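# Viability filtering, sliding-window RGR and lethal-dose handling.

weekday_times <- function(weeks = 4) {
  d <- imaging_dates(trial_design(weeks = weeks))
  as.numeric(d - d[1])
}

test_that("viability depends on a sustained consecutive run", {
  t <- weekday_times()
  all_big <- tibble::tibble(elapsed_days = t, area_px = 2000L)
  v <- viability_filter(all_big)
  expect_true(v$viable)
  expect_equal(v$longest_run_days, 25)
  none <- tibble::tibble(elapsed_days = t, area_px = 900L)
  v0 <- viability_filter(none)
  expect_false(v0$viable)
  expect_equal(v0$longest_run_days, 0)
  # a 10-day qualifying stretch is too short for the 15-day rule
  a <- rep(500L, length(t))
  a[t >= 5 & t <= 15] <- 1500L
  short <- tibble::tibble(elapsed_days = t, area_px = a)
  expect_false(viability_filter(short)$viable)
})

test_that("viability agrees with brute-force run enumeration", {
  set.seed(31)
  t <- weekday_times()
  for (k in 1:40) {
    a <- as.integer(ifelse(runif(length(t)) < 0.6, 2000, 500))
    cv <- tibble::tibble(elapsed_days = t, area_px = a)
    got <- viability_filter(cv, 1000, 15)
    want <- viability_oracle(t, a, 1000, 15)
    expect_equal(got$viable, want$viable)
    expect_equal(got$longest_run_days, want$span)
  }
})

test_that("count mode requires consecutive observations instead", {
  t <- 0:19
  a <- c(rep(2000L, 14), 500L, rep(2000L, 5))
  cv <- tibble::tibble(elapsed_days = t, area_px = a)
  expect_false(viability_filter(cv, 1000, 15, mode = "count")$viable)
  expect_true(viability_filter(cv, 1000, 14, mode = "count")$viable)
})

test_that("noiseless exponentials give exact window slopes", {
  t <- weekday_times()
  for (r in c(-0.1, 0, 0.05, 0.2, 0.4)) {
    cv <- tibble::tibble(elapsed_days = t,
                         area_px = 5000 * exp(r * t))
    w <- window_rgr(cv)
    expect_gt(nrow(w), 10)
    expect_true(all(abs(w$rgr_per_day - r) < 1e-9))
    if (r != 0) expect_true(all(w$adj_r2 > 1 - 1e-9))
  }
  const <- tibble::tibble(elapsed_days = t, area_px = 500)
  expect_true(all(abs(window_rgr(const)$rgr_per_day) < 1e-12))
})

test_that("window fits match the closed-form OLS oracle", {
  set.seed(13)
  t <- weekday_times()
  a <- 300 * exp(0.15 * t) * exp(rnorm(length(t), 0, 0.05))
  cv <- tibble::tibble(elapsed_days = t, area_px = a)
  w <- window_rgr(cv, window_days = 10)
  for (i in seq_len(nrow(w))) {
    sel <- t >= w$window_start_day[i] & t <= w$window_start_day[i] + 10
    o <- ols_oracle(t[sel], log(a[sel]))
    expect_equal(w$rgr_per_day[i], o$slope, tolerance = 1e-10)
    expect_equal(w$adj_r2[i], o$adj_r2, tolerance = 1e-10)
    expect_equal(w$n_points[i], sum(sel))
  }
})

test_that("windows containing zero areas are skipped", {
  t <- 0:12
  a <- c(100, 150, 0, rep(400, 10))
  w <- window_rgr(tibble::tibble(elapsed_days = t, area_px = a),
                  window_days = 5)
  # every window starting at t <= 2 includes the zero point
  expect_true(all(w$window_start_day > 2))
})

test_that("RGR selection applies the fitness gate and tie rules", {
  res <- tibble::tibble(window_start_day = c(0, 3, 6),
                        rgr_per_day = c(0.15, 0.22, 0.30),
                        adj_r2 = c(0.95, 0.85, 0.60),
                        n_points = 8L)
  sel <- select_rgr(res)
  expect_equal(sel$rgr_per_day, 0.22)
  expect_true(sel$selected)
  # all below the gate -> sentinel
  low <- dplyr::mutate(res, adj_r2 = 0.5)
  expect_false(select_rgr(low)$selected)
  # ties resolve to the earliest window
  tie <- tibble::tibble(window_start_day = c(7, 2),
                        rgr_per_day = 0.2, adj_r2 = 0.9,
                        n_points = 8L)
  expect_equal(select_rgr(tie)$window_start_day, 2)
  # order invariance
  set.seed(2)
  expect_equal(select_rgr(res[sample(3), ]), sel)
})

test_that("selected RGR bias shrinks as measurement noise does", {
  t <- weekday_times()
  bias <- sapply(c(0.2, 0.1, 0.05, 0.01), function(sg) {
    errs <- sapply(1:12, function(s) {
      set.seed(1000 + s * 7 + round(sg * 1000))
      a <- 1500 * exp(0.2 * t) * exp(rnorm(length(t), 0, sg))
      cv <- tibble::tibble(elapsed_days = t, area_px = a)
      sel <- select_rgr(window_rgr(cv))
      if (!sel$selected) NA else sel$rgr_per_day - 0.2
    })
    mean(abs(errs), na.rm = TRUE)
  })
  expect_true(all(diff(bias) < 0))
})

test_that("zero substitution targets the lowest fully lethal dose", {
  design <- expand.grid(clone = c("A", "B"), condition_mM = c(0, 50, 100, 200, 300),
                        replicate = 1:2, stringsAsFactors = FALSE)
  tab <- tibble::tibble(
    barcode = sprintf("X%02d", seq_len(nrow(design))),
    clone = design$clone, condition_mM = design$condition_mM,
    replicate = design$replicate,
    viable = design$condition_mM < 200,
    rgr_per_day = ifelse(design$condition_mM < 200, 0.2, NA),
    adj_r2 = 0.9, window_start_day = 0,
    selected = design$condition_mM < 200)
  out <- substitute_lethal(tab, design)
  expect_setequal(unique(out$condition_mM), c(0, 50, 100, 200))
  z <- out[out$condition_mM == 200, ]
  expect_equal(nrow(z), 4)            # every designed replicate
  expect_true(all(z$rgr_per_day == 0))
  expect_false(300 %in% out$condition_mM)
  # all doses viable -> table unchanged in content
  alive <- dplyr::mutate(tab, viable = TRUE, rgr_per_day = 0.2,
                         selected = TRUE)
  out2 <- substitute_lethal(alive, design)
  expect_equal(nrow(out2), nrow(design))
  expect_true(all(out2$rgr_per_day == 0.2))
})

test_that("simulated lethal doses fail viability and get zeroed", {
  des <- trial_design(replicates = 2L, lethal_dose_mM = 100)
  sim <- simulate_trial_curves(des)
  rgr <- sample_rgr_table(sim$curves)
  lethal <- rgr[rgr$condition_mM >= 100, ]
  expect_true(all(!lethal$viable))
  out <- substitute_lethal(rgr)
  expect_equal(max(out$condition_mM), 100)
  expect_true(all(out$rgr_per_day[out$condition_mM == 100] == 0))
  expect_equal(sum(out$condition_mM == 100), 2 * 6)
})
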