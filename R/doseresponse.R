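#' Five-parameter log-logistic dose-response function
#'
#' `ll5(x) = c + (d - c) / (1 + exp(b * (ln x - ln e)))^f` with lower
#' asymptote `c`, upper asymptote `d`, slope `b`, inflection dose `e`
#' and asymmetry `f`. At `x = 0` the analytic limit is used: `d` when
#' `b > 0` (response decays with dose), `c` when `b < 0`, and the
#' midpoint `c + (d - c)/2^f` when `b = 0`. Dose zero is never handled
#' by offsetting `x`.
#'
#' @param x dose (mM), vectorised, `x >= 0`.
#' @param b,c,d,e,f model parameters; `e > 0`, `f > 0`.
#' @return response (day^-1).
#' @export
ll5 <- function(x, b, c, d, e, f) {
  if (e <= 0 || f <= 0) stop("parameter error: require e > 0 and f > 0")
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- c + (d - c) / (1 + exp(b * (log(x[pos]) - log(e))))^f
  if (any(!pos)) {
    lim0 <- if (b > 0) d else if (b < 0) c else c + (d - c) / 2^f
    out[!pos] <- lim0
  }
  out
}

#' Fit the five-parameter log-logistic model
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' `minpack.lm::nls.lm` on the residual function) of response on dose
#' under the LL5 family.
#' Starting values: `c0` = min response, `d0` = max response, `e0` =
#' geometric mean of the positive doses, `f0 = 1`, with a multi-start
#' over `b0` in {0.5, 1, 2} (the best-SSE converged fit wins). Flat
#' data (zero response variance) short-circuits to the degenerate fit
#' `c = d = mean` with `converged = TRUE`.
#'
#' @param doses numeric vector of doses (mM, may include 0).
#' @param responses numeric vector of responses (day^-1).
#' @return object of class `ll5_fit`: list with `b`, `c`, `d`, `e`,
#'   `f`, `sse`, `converged`, and the data used.
#' @export
fit_ll5 <- function(doses, responses) {
  stopifnot(length(doses) == length(responses))
  keep <- !is.na(doses) & !is.na(responses)
  doses <- doses[keep]; responses <- responses[keep]
  if (length(doses) < 5L || length(unique(doses)) < 3L)
    stop("need >= 5 points over >= 3 distinct doses")
  mkfit <- function(p, sse, conv)
    structure(list(b = p[["b"]], c = p[["c"]], d = p[["d"]],
                   e = p[["e"]], f = p[["f"]], sse = sse,
                   converged = conv, doses = doses,
                   responses = responses),
              class = "ll5_fit")
  if (stats::var(responses) == 0) {
    m <- mean(responses)
    return(mkfit(c(b = 1, c = m, d = m, e = max(doses[doses > 0],
                                                1), f = 1), 0, TRUE))
  }
  c0 <- min(responses); d0 <- max(responses)
  e0 <- exp(mean(log(doses[doses > 0])))
  resid_fn <- function(p)
    responses - ll5(doses, p[1], p[2], p[3], p[4], p[5])
  lm_once <- function(start) {
    tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = resid_fn,
        lower = c(-Inf, -Inf, -Inf, 1e-9, 1e-9),
        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL, warning = function(w) NULL)
  }
  runs <- list()
  for (b0 in c(0.5, 1, 2)) {
    fit <- lm_once(c(b = b0, c = c0, d = d0, e = e0, f = 1))
    if (is.null(fit) || fit$info < 1L) next
    runs[[length(runs) + 1L]] <- fit
  }
  if (length(runs) == 0L) {
    # non-convergence everywhere: best-effort start parameters
    return(mkfit(c(b = 1, c = c0, d = d0, e = e0, f = 1),
                 sum((responses - ll5(doses, 1, c0, d0, e0, 1))^2),
                 FALSE))
  }
  sses <- vapply(runs, function(r) r$deviance, numeric(1))
  best <- runs[[which.min(sses)]]
  # warm restart to polish; overparameterized fits can stall on a flat
  # (e, f) ridge at the SSE floor with the iteration cap reached
  polish <- lm_once(best$par)
  if (!is.null(polish) && polish$info >= 1L &&
      polish$deviance <= best$deviance) best <- polish
  # converged when the optimizer reports a tolerance stop, or when
  # independent starts agree on the SSE floor (ridge case)
  agree <- sum(sses <= best$deviance * 1.01)
  converged <- best$info %in% 1:4 || agree >= 2L
  mkfit(best$par, best$deviance, converged)
}

#' @export
print.ll5_fit <- function(x, ...) {
  cat(sprintf(
    "<ll5_fit b=%.3g c=%.3g d=%.3g e=%.3g f=%.3g sse=%.3g %s>\n",
    x$b, x$c, x$d, x$e, x$f, x$sse,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
predict.ll5_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$doses else newdata
  ll5(x, object$b, object$c, object$d, object$e, object$f)
}

#' EC50 from a fitted dose-response curve
#'
#' The EC50 is the dose at which the fitted response equals 50% of the
#' optimal (0 mM) growth rate. It is found by bracketed root finding
#' of `ll5(x) - 0.5 * baseline_rgr` on `(0, 2 * max dose]` to 1e-6
#' relative tolerance. If the curve never crosses the half-response in
#' that bracket the estimate is flagged absent.
#'
#' @param fit an `ll5_fit`.
#' @param baseline_rgr the 0 mM reference growth rate (day^-1, > 0);
#'   typically the observed mean RGR at dose 0.
#' @return list with `ec50_mM` (NA when no root), `baseline_rgr`,
#'   `extrapolated` (root above the tested dose range) and `found`.
#' @export
ec50 <- function(fit, baseline_rgr) {
  stopifnot(inherits(fit, "ll5_fit"), baseline_rgr > 0)
  target <- 0.5 * baseline_rgr
  hi <- 2 * max(fit$doses)
  g <- function(x) predict(fit, x) - target
  lo <- 1e-9 * hi
  if (g(lo) * g(hi) > 0)
    return(list(ec50_mM = NA_real_, baseline_rgr = baseline_rgr,
                extrapolated = NA, found = FALSE))
  root <- stats::uniroot(g, c(lo, hi), tol = 1e-6 * hi)$root
  list(ec50_mM = root, baseline_rgr = baseline_rgr,
       extrapolated = root > max(fit$doses), found = TRUE)
}

#' Bootstrap standard deviation of the EC50
#'
#' Within each dose the replicates are resampled with replacement to
#' their original count, the LL5 model is refitted, the baseline is
#' recomputed from the resample and the EC50 re-solved; the standard
#' deviation over successful iterations estimates the EC50's
#' uncertainty. Failed refits or absent roots are dropped (not
#' imputed) and counted out of `n_boot_effective`.
#'
#' @param samples tibble with `condition_mM` and `rgr_per_day` for one
#'   clone (one row per replicate, including substituted zeros).
#' @param n_boot bootstrap iterations (default 500).
#' @param seed RNG seed; the whole resampling stream is determined by
#'   it.
#' @param baseline_mode "observed" (mean resampled RGR at dose 0) or
#'   "fitted" (upper asymptote d of the refit).
#' @return list with `ec50_mM` (point estimate on the full data),
#'   `sd_mM`, `n_boot_effective`, `reliable` (FALSE when more than half
#'   the iterations failed), `baseline_rgr`, `fit`.
#' @export
bootstrap_ec50 <- function(samples, n_boot = 500L, seed = 1L,
                           baseline_mode = c("observed", "fitted")) {
  baseline_mode <- match.arg(baseline_mode)
  stopifnot(all(c("condition_mM", "rgr_per_day") %in% names(samples)))
  fit <- fit_ll5(samples$condition_mM, samples$rgr_per_day)
  baseline <- if (baseline_mode == "observed") {
    mean(samples$rgr_per_day[samples$condition_mM == 0])
  } else fit$d
  point <- ec50(fit, baseline)
  groups <- split(seq_len(nrow(samples)), samples$condition_mM)
  boots <- rep(NA_real_, n_boot)
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (i in seq_len(n_boot)) {
    idx <- unlist(lapply(groups, function(g)
      g[sample.int(length(g), length(g), replace = TRUE)]))
    res <- tryCatch({
      bfit <- fit_ll5(samples$condition_mM[idx],
                      samples$rgr_per_day[idx])
      if (!bfit$converged) stop("refit did not converge")
      bbase <- if (baseline_mode == "observed") {
        mean(samples$rgr_per_day[idx][samples$condition_mM[idx] == 0])
      } else bfit$d
      if (!is.finite(bbase) || bbase <= 0) stop("bad baseline")
      e <- ec50(bfit, bbase)
      if (!e$found) stop("no root")
      e$ec50_mM
    }, error = function(e) NA_real_)
    boots[i] <- res
  }
  ok <- boots[!is.na(boots)]
  list(ec50_mM = point$ec50_mM,
       sd_mM = if (length(ok) >= 2L) stats::sd(ok) else NA_real_,
       n_boot_effective = length(ok),
       reliable = length(ok) > n_boot / 2,
       baseline_rgr = baseline,
       boots = ok,
       fit = fit)
}

#' Per-clone dose-response panel
#'
#' For each clone: per-dose mean and SD of the replicate growth rates,
#' the LL5 fit on the pooled replicates, and the EC50 with its
#' bootstrap SD. Clones with fewer than 3 surviving doses are skipped
#' with a warning.
#'
#' @param rgr_table dose-response table from [substitute_lethal()]
#'   (`clone`, `condition_mM`, `replicate`, `rgr_per_day`).
#' @param n_boot bootstrap iterations per clone.
#' @param seed master seed; each clone gets a deterministic derived
#'   stream.
#' @param baseline_mode see [bootstrap_ec50()].
#' @return list with `ec50` (tibble: clone, ec50_mM, sd_mM,
#'   baseline_rgr, n_boot_effective), `fits` (tibble: clone, b, c, d,
#'   e, f, sse, converged), `summary` (tibble: clone, condition_mM,
#'   mean_rgr, sd_rgr, n) and `fit_objects` (named list).
#' @export
clone_panel <- function(rgr_table, n_boot = 500L, seed = 1L,
                        baseline_mode = c("observed", "fitted")) {
  baseline_mode <- match.arg(baseline_mode)
  clones <- sort(unique(rgr_table$clone))
  ec_rows <- list(); fit_rows <- list(); fit_objs <- list()
  for (k in seq_along(clones)) {
    cl <- clones[k]
    tab <- rgr_table[rgr_table$clone == cl, , drop = FALSE]
    if (length(unique(tab$condition_mM)) < 3L) {
      warning("clone ", cl, " skipped: fewer than 3 surviving doses",
              call. = FALSE)
      next
    }
    bs <- bootstrap_ec50(tab, n_boot = n_boot,
                         seed = seed + 7919L * k,
                         baseline_mode = baseline_mode)
    ec_rows[[cl]] <- tibble::tibble(
      clone = cl, ec50_mM = bs$ec50_mM, sd_mM = bs$sd_mM,
      baseline_rgr = bs$baseline_rgr,
      n_boot_effective = bs$n_boot_effective)
    fit_rows[[cl]] <- tibble::tibble(
      clone = cl, b = bs$fit$b, c = bs$fit$c, d = bs$fit$d,
      e = bs$fit$e, f = bs$fit$f, sse = bs$fit$sse,
      converged = bs$fit$converged)
    fit_objs[[cl]] <- bs$fit
  }
  summary <- dplyr::summarise(
    dplyr::group_by(rgr_table, .data$clone, .data$condition_mM),
    mean_rgr = mean(.data$rgr_per_day),
    sd_rgr = stats::sd(.data$rgr_per_day),
    n = dplyr::n(), .groups = "drop")
  list(ec50 = dplyr::bind_rows(ec_rows),
       fits = dplyr::bind_rows(fit_rows),
       summary = summary,
       fit_objects = fit_objs)
}

#' Dose-response and EC50 figures
#'
#' `plot_dose_response()` draws per-clone mean +- SD growth rates
#' against dose with the fitted LL5 curves; `plot_ec50()` draws the
#' per-clone EC50 bar plot with bootstrap SD error bars.
#'
#' @param panel result of [clone_panel()].
#' @return a ggplot object.
#' @export
plot_dose_response <- function(panel) {
  grid <- dplyr::bind_rows(lapply(names(panel$fit_objects), function(cl) {
    f <- panel$fit_objects[[cl]]
    x <- seq(0, max(f$doses), length.out = 200)
    tibble::tibble(clone = cl, condition_mM = x,
                   mean_rgr = predict(f, x))
  }))
  ggplot2::ggplot(panel$summary,
                  ggplot2::aes(x = .data$condition_mM,
                               y = .data$mean_rgr)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_rgr - .data$sd_rgr,
      ymax = .data$mean_rgr + .data$sd_rgr)) +
    ggplot2::facet_wrap(~clone) +
    ggplot2::labs(x = "Added sodium (mM)",
                  y = expression(RGR ~ (day^-1))) +
    ggplot2::theme_bw()
}

#' @rdname plot_dose_response
#' @export
plot_ec50 <- function(panel) {
  ggplot2::ggplot(panel$ec50,
                  ggplot2::aes(x = .data$clone, y = .data$ec50_mM)) +
    ggplot2::geom_col(fill = "seagreen") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$ec50_mM - .data$sd_mM,
      ymax = .data$ec50_mM + .data$sd_mM), width = 0.3) +
    ggplot2::labs(x = NULL, y = "EC50 (mM added sodium)") +
    ggplot2::theme_bw()
}
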