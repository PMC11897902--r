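# Five-parameter log-logistic fitting, EC50 solving and the bootstrap.

test_that("ll5 closed forms and the dose-zero limit", {
  expect_equal(ll5(80, b = 3, c = 0, d = 0.2, e = 80, f = 1), 0.1)
  expect_equal(ll5(80, b = 3, c = 0, d = 0.2, e = 80, f = 2), 0.05)
  expect_equal(ll5(0, b = 3, c = 0, d = 0.25, e = 90, f = 1), 0.25)
  expect_equal(ll5(0, b = -3, c = 0.1, d = 0.25, e = 90, f = 1), 0.1)
  expect_error(ll5(10, 1, 0, 1, -5, 1), "parameter error")
  expect_error(ll5(10, 1, 0, 1, 5, 0), "parameter error")
  # monotone non-increasing when b, f > 0
  x <- seq(0, 400, by = 1)
  y <- ll5(x, 2.5, 0, 0.27, 140, 1.3)
  expect_true(all(diff(y) <= 0))
})

test_that("noiseless LL5 data recovers its generating parameters", {
  doses <- rep(c(0, 50, 100, 150, 200), each = 6)
  y <- ll5(doses, b = 2.5, c = 0, d = 0.25, e = 90, f = 1.5)
  fit <- fit_ll5(doses, y)
  expect_true(fit$converged)
  expect_equal(fit$b, 2.5, tolerance = 1e-4)
  expect_equal(fit$c, 0, tolerance = 1e-4 * 0.25)
  expect_equal(fit$d, 0.25, tolerance = 1e-4)
  expect_equal(fit$e, 90, tolerance = 1e-4)
  expect_equal(fit$f, 1.5, tolerance = 1e-4)
})

test_that("residual noise floor is recovered under gaussian noise", {
  set.seed(77)
  doses <- rep(c(0, 50, 100, 150, 200), each = 6)
  sigma <- 0.01
  y <- ll5(doses, 2.5, 0, 0.25, 90, 1.5) + rnorm(length(doses), 0, sigma)
  fit <- fit_ll5(doses, y)
  n <- length(doses)
  expect_gt(fit$sse, 0.5 * n * sigma^2)
  expect_lt(fit$sse, 1.5 * n * sigma^2)
})

test_that("degenerate flat data fits flat without error", {
  doses <- rep(c(0, 50, 100), each = 2)
  fit <- fit_ll5(doses, rep(0.2, 6))
  expect_true(fit$converged)
  expect_equal(fit$c, fit$d)
  expect_equal(fit$sse, 0)
  expect_error(fit_ll5(c(0, 50), c(1, 2)), ">= 5 points")
})

test_that("ec50 solves the half-baseline crossing", {
  doses <- rep(c(0, 40, 80, 160, 320), each = 2)
  y <- ll5(doses, 3, 0, 0.2, 80, 1)
  fit <- fit_ll5(doses, y)
  # symmetric case: baseline = d, f = 1, c = 0 -> ec50 = e
  e <- ec50(fit, baseline_rgr = 0.2)
  expect_equal(e$ec50_mM, 80, tolerance = 1e-4)
  expect_false(e$extrapolated)
  # no crossing -> flagged absent
  high <- ec50(fit, baseline_rgr = 1e6)
  expect_false(high$found)
  expect_true(is.na(high$ec50_mM))
})

test_that("ec50 matches the brute-force grid oracle", {
  set.seed(15)
  for (k in 1:5) {
    doses <- rep(c(0, 50, 100, 150, 200), each = 4)
    y <- ll5(doses, runif(1, 1.5, 3.5), 0, runif(1, 0.2, 0.3),
             runif(1, 70, 150), runif(1, 0.8, 2)) +
      rnorm(length(doses), 0, 0.005)
    fit <- fit_ll5(doses, y)
    if (!fit$converged) next
    baseline <- mean(y[doses == 0])
    got <- ec50(fit, baseline)
    if (!got$found) next
    want <- ec50_grid_oracle(fit, baseline, max(doses))
    expect_equal(got$ec50_mM, want, tolerance = 1e-3 / want)
  }
})

test_that("asymmetric half-response matches analytic inversion", {
  # c = 0, f = 2, b = 3, d = 0.2, e = 80, baseline = 0.2:
  # solve (1 + exp(3 (ln x - ln 80)))^2 = 2
  doses <- rep(c(0, 40, 80, 160, 320), each = 2)
  y <- ll5(doses, 3, 0, 0.2, 80, 2)
  fit <- fit_ll5(doses, y)
  analytic <- 80 * (2^(1 / 2) - 1)^(1 / 3)
  got <- ec50(fit, 0.2)
  expect_equal(got$ec50_mM, analytic, tolerance = 1e-4)
})

test_that("bootstrap is deterministic, order-invariant, degenerate on exact data", {
  doses <- rep(c(0, 50, 100, 150, 200), each = 4)
  y <- ll5(doses, 2.5, 0, 0.27, 141.3, 1)
  tab <- tibble::tibble(condition_mM = doses, rgr_per_day = y)
  b1 <- bootstrap_ec50(tab, n_boot = 30, seed = 42)
  b2 <- bootstrap_ec50(tab, n_boot = 30, seed = 42)
  expect_identical(b1$sd_mM, b2$sd_mM)
  expect_identical(b1$boots, b2$boots)
  # zero-noise data: every resample is the same dataset
  expect_lt(b1$sd_mM, 1e-6)
  expect_equal(b1$n_boot_effective, 30)
  expect_true(b1$reliable)
  # replicate ordering within doses does not change the stream
  set.seed(9)
  perm <- unlist(lapply(split(seq_along(doses), doses), sample))
  b3 <- bootstrap_ec50(tab[perm, ], n_boot = 30, seed = 42)
  expect_equal(b3$sd_mM, b1$sd_mM, tolerance = 1e-12)
})

test_that("bootstrap sd tracks the sampling spread of the estimator", {
  # compare against the empirical sd of the EC50 over independently
  # regenerated datasets with the same noise
  gen <- function(s) {
    set.seed(s)
    doses <- rep(c(0, 50, 100, 150, 200), each = 6)
    tibble::tibble(condition_mM = doses,
                   rgr_per_day = ll5(doses, 2.5, 0, 0.27, 141.3, 1) +
                     rnorm(length(doses), 0, 0.02))
  }
  emp <- sapply(1:60, function(s) {
    tab <- gen(s)
    fit <- fit_ll5(tab$condition_mM, tab$rgr_per_day)
    e <- ec50(fit, mean(tab$rgr_per_day[tab$condition_mM == 0]))
    e$ec50_mM
  })
  emp_sd <- sd(emp, na.rm = TRUE)
  bs <- bootstrap_ec50(gen(101), n_boot = 120, seed = 5)
  expect_gt(bs$sd_mM, emp_sd / 2)
  expect_lt(bs$sd_mM, emp_sd * 2)
})

test_that("clone panel fits every clone and preserves tolerance ranks", {
  des <- trial_design(replicates = 4L, sigma = 0.02)
  sim <- simulate_trial_curves(des)
  dr <- substitute_lethal(sample_rgr_table(sim$curves))
  panel <- clone_panel(dr, n_boot = 20, seed = 3)
  expect_equal(nrow(panel$ec50), 6)
  expect_equal(nrow(panel$fits), 6)
  # the clone generated most tolerant (largest e) estimates highest,
  # the least tolerant lowest
  expect_equal(panel$ec50$clone[which.max(panel$ec50$ec50_mM)],
               "Kashmir")
  expect_equal(panel$ec50$clone[which.min(panel$ec50$ec50_mM)],
               "France")
  # plot builders return ggplot objects without evaluation errors
  expect_s3_class(plot_dose_response(panel), "ggplot")
  expect_s3_class(plot_ec50(panel), "ggplot")
  # empty input
  empty <- dr[0, ]
  pe <- suppressWarnings(clone_panel(empty, n_boot = 5, seed = 1))
  expect_equal(nrow(pe$ec50), 0)
})
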