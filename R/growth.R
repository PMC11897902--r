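#' Viability filter for a growth curve
#'
#' A sample counts as viable when it sustained at least `min_area_px`
#' of plant area over at least `min_days` consecutive days, which
#' removes cultures that never grew or died after transplanting. With
#' a 5-days-per-week imaging schedule "consecutive days" is read as a
#' run of consecutive observations whose calendar span reaches
#' `min_days` (`mode = "span"`); `mode = "count"` instead requires
#' `min_days` consecutive observations.
#'
#' @param curve tibble with `elapsed_days` and `area_px` for one
#'   sample, time-ordered or not (it is sorted internally).
#' @param min_area_px area threshold in pixels (default 1000).
#' @param min_days required span in days (or observation count).
#' @param mode "span" or "count".
#' @return list with `viable` and `longest_run_days` (span of the
#'   longest qualifying run, in days; 0 when no observation qualifies).
#' @export
viability_filter <- function(curve, min_area_px = 1000,
                             min_days = 15, mode = c("span", "count")) {
  mode <- match.arg(mode)
  stopifnot(nrow(curve) >= 1L)
  o <- order(curve$elapsed_days)
  t <- curve$elapsed_days[o]
  ok <- curve$area_px[o] >= min_area_px
  best_span <- 0
  best_len <- 0L
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k]) next
    span <- t[ends[k]] - t[starts[k]]
    if (span > best_span) best_span <- span
    if (r$lengths[k] > best_len) best_len <- r$lengths[k]
  }
  viable <- if (mode == "span") best_span >= min_days
            else best_len >= min_days
  list(viable = viable, longest_run_days = best_span)
}

#' Sliding-window relative growth rates
#'
#' For each observation time t the points falling in the closed window
#' [t, t + window_days] are fitted by ordinary least squares of
#' ln(area) on elapsed days; the slope is the relative growth rate
#' (day^-1) and the window's adjusted R-squared is returned as its
#' model fitness. Windows with fewer than 3 points, or containing a
#' zero/negative area (ln undefined), are skipped.
#'
#' @param curve tibble with `elapsed_days` and `area_px` for one
#'   sample.
#' @param window_days window length in days (default 10).
#' @return tibble with one row per fitted window: `window_start_day`,
#'   `rgr_per_day`, `adj_r2`, `n_points`.
#' @export
window_rgr <- function(curve, window_days = 10) {
  o <- order(curve$elapsed_days)
  t <- curve$elapsed_days[o]
  a <- curve$area_px[o]
  rows <- list()
  for (i in seq_along(t)) {
    sel <- which(t >= t[i] & t <= t[i] + window_days)
    if (length(sel) < 3L) next
    if (any(a[sel] <= 0)) next
    y <- log(a[sel])
    fit <- stats::lm(y ~ t[sel])
    n <- length(sel)
    tss <- sum((y - mean(y))^2)
    # zero-variance windows (constant area) have undefined R^2; their
    # slope is 0 and they are reported with adj_r2 = NaN
    r2 <- 1 - sum(stats::residuals(fit)^2) / tss
    rows[[length(rows) + 1L]] <- tibble::tibble(
      window_start_day = t[i],
      rgr_per_day = unname(stats::coef(fit)[2]),
      adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
      n_points = n
    )
  }
  if (length(rows) == 0L)
    return(tibble::tibble(window_start_day = numeric(),
                          rgr_per_day = numeric(), adj_r2 = numeric(),
                          n_points = integer()))
  dplyr::bind_rows(rows)
}

#' Select a sample's representative growth rate
#'
#' Among windows with adjusted R-squared of at least `min_fit`, the
#' maximum growth rate is taken as the sample's RGR (ties broken by
#' the earliest window start). When no window passes the gate, a
#' non-selected sentinel is returned.
#'
#' @param results tibble from [window_rgr()].
#' @param min_fit minimum adjusted R-squared (default 0.8).
#' @return one-row tibble: `rgr_per_day`, `window_start_day`,
#'   `adj_r2`, `n_points`, `selected`.
#' @export
select_rgr <- function(results, min_fit = 0.8) {
  sentinel <- tibble::tibble(rgr_per_day = NA_real_,
                             window_start_day = NA_real_,
                             adj_r2 = NA_real_, n_points = NA_integer_,
                             selected = FALSE)
  if (nrow(results) == 0L) return(sentinel)
  cand <- results[!is.na(results$adj_r2) & results$adj_r2 >= min_fit, ,
                  drop = FALSE]
  if (nrow(cand) == 0L) return(sentinel)
  best <- max(cand$rgr_per_day)
  hits <- cand[cand$rgr_per_day == best, , drop = FALSE]
  hit <- hits[which.min(hits$window_start_day), , drop = FALSE]
  tibble::tibble(rgr_per_day = hit$rgr_per_day,
                 window_start_day = hit$window_start_day,
                 adj_r2 = hit$adj_r2, n_points = hit$n_points,
                 selected = TRUE)
}

#' Per-sample RGR table for a whole trial
#'
#' Runs the viability filter, sliding-window fits and RGR selection on
#' every sample of a long-format curve table.
#'
#' @param curves tibble from [assemble_curves()] /
#'   [read_curves_csv()].
#' @param config pipeline configuration (sections `filter` and `rgr`).
#' @return tibble with one row per barcode: `barcode`, `clone`,
#'   `condition_mM`, `replicate`, `viable`, `rgr_per_day`, `adj_r2`,
#'   `window_start_day`, `selected`.
#' @export
sample_rgr_table <- function(curves, config = default_config()) {
  f <- config$filter; g <- config$rgr
  split_curves <- split(curves, curves$barcode)
  rows <- lapply(split_curves, function(cv) {
    meta <- cv[1L, c("barcode", "clone", "condition_mM", "replicate")]
    v <- viability_filter(cv, f$min_area_px, f$min_days, f$mode)
    if (!v$viable) {
      return(dplyr::bind_cols(meta, tibble::tibble(
        viable = FALSE, rgr_per_day = NA_real_, adj_r2 = NA_real_,
        window_start_day = NA_real_, selected = FALSE)))
    }
    sel <- select_rgr(window_rgr(cv, g$window_days), g$min_fit)
    dplyr::bind_cols(meta, tibble::tibble(
      viable = TRUE, rgr_per_day = sel$rgr_per_day,
      adj_r2 = sel$adj_r2, window_start_day = sel$window_start_day,
      selected = sel$selected))
  })
  dplyr::bind_rows(rows)
}

#' Zero-substitution at the lethal dose
#'
#' When a dose kills every culture in the trial, its samples carry no
#' measurable growth rate yet the dose-response fit needs the
#' information that growth there is zero. For the LOWEST dose at which
#' no sample of any clone is viable, an RGR of 0 is inserted for every
#' designed replicate; all strictly higher doses are removed from the
#' table. With `per_clone = TRUE` the rule is applied within each
#' clone instead of trial-wide.
#'
#' @param rgr_table tibble from [sample_rgr_table()].
#' @param design tibble of the designed samples (`clone`,
#'   `condition_mM`, `replicate`); defaults to the combinations present
#'   in `rgr_table`.
#' @param per_clone apply the lethality rule per clone.
#' @return dose-response table: `clone`, `condition_mM`, `replicate`,
#'   `rgr_per_day` (selected samples plus substituted zeros).
#' @export
substitute_lethal <- function(rgr_table, design = NULL,
                              per_clone = FALSE) {
  if (is.null(design))
    design <- dplyr::distinct(rgr_table[, c("clone", "condition_mM",
                                            "replicate")])
  apply_rule <- function(tab, des) {
    us <- tab[tab$selected %in% TRUE & !is.na(tab$rgr_per_day), ,
              drop = FALSE]
    out <- tibble::tibble(clone = us$clone,
                          condition_mM = us$condition_mM,
                          replicate = us$replicate,
                          rgr_per_day = us$rgr_per_day)
    doses <- sort(unique(des$condition_mM))
    viable_doses <- unique(tab$condition_mM[tab$viable %in% TRUE])
    dead <- doses[!doses %in% viable_doses]
    if (length(dead) == 0L) return(out)
    lethal <- min(dead)
    zeros <- des[des$condition_mM == lethal, , drop = FALSE]
    out <- out[out$condition_mM < lethal, , drop = FALSE]
    dplyr::bind_rows(out, tibble::tibble(
      clone = zeros$clone, condition_mM = zeros$condition_mM,
      replicate = zeros$replicate, rgr_per_day = 0))
  }
  res <- if (per_clone) {
    dplyr::bind_rows(lapply(split(design, design$clone), function(des)
      apply_rule(rgr_table[rgr_table$clone %in% des$clone[1], ,
                           drop = FALSE], des)))
  } else {
    apply_rule(rgr_table, design)
  }
  dplyr::arrange(res, .data$clone, .data$condition_mM, .data$replicate)
}
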