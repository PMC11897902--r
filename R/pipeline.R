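# Pipeline stage drivers behind the command-line interface. Each
# writes its tabular outputs plus a provenance sidecar (config hash,
# seed, package version) so runs are attributable and reproducible.

write_provenance <- function(out_dir, config, extra = list()) {
  prov <- c(list(
    package = "duckquant",
    version = as.character(utils::packageVersion("duckquant")),
    config_hash = substr(rlang::hash(config), 1, 16),
    seed = config$seed,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
    extra)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Quantify a directory of tube images
#'
#' Processes every parseable image in `image_dir` (top views through
#' [quantify_top_image()], side views through
#' [quantify_side_image()]), joins the two views into merged sample
#' records, and writes a JSON record stream (`records.ndjson`), the
#' records CSV and a provenance sidecar. Unreadable images are skipped
#' with a logged warning; the batch continues.
#'
#' @param image_dir directory of `<YYYYMMDD-HHMMSS>_cam<N>.png` files.
#' @param config pipeline configuration.
#' @param out_dir output directory (created).
#' @return invisibly, a list with `records` (merged tibble), `top`,
#'   `side` (raw per-view tibbles), and counts `n_images`,
#'   `n_skipped`, `n_decoded`, `n_undecoded`.
#' @export
run_quantify <- function(image_dir, config = default_config(),
                         out_dir = image_dir) {
  found <- discover_images(image_dir)
  if (nrow(found) == 0L)
    stop("no parseable images in ", image_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  top <- list(); side <- list(); n_skip <- 0L
  for (i in seq_len(nrow(found))) {
    rec <- tryCatch({
      img <- read_tube_image(found$path[i], config)
      if (img$view == "top") {
        list(top = quantify_top_image(img, config))
      } else {
        list(side = suppressWarnings(quantify_side_image(img, config)))
      }
    }, error = function(e) {
      message("skipping unreadable image ", basename(found$path[i]),
              ": ", conditionMessage(e))
      NULL
    })
    if (is.null(rec)) { n_skip <- n_skip + 1L; next }
    if (!is.null(rec$top)) top[[length(top) + 1L]] <- rec$top
    if (!is.null(rec$side)) side[[length(side) + 1L]] <- rec$side
  }
  top <- dplyr::bind_rows(top); side <- dplyr::bind_rows(side)
  records <- suppressWarnings(pair_views(top, side, config))
  # JSON record stream: one object per line, then the friendlier CSV
  ndjson <- file.path(out_dir, "records.ndjson")
  con <- file(ndjson, "w")
  if (nrow(records) > 0L) {
    for (i in seq_len(nrow(records))) {
      writeLines(jsonlite::toJSON(as.list(records[i, ]),
                                  auto_unbox = TRUE,
                                  POSIXt = "ISO8601"), con)
    }
  }
  close(con)
  write_records_csv(records, file.path(out_dir, "records.csv"))
  n_undecoded <- if (nrow(side)) sum(is.na(side$barcode)) else 0L
  write_provenance(out_dir, config, list(
    stage = "quantify", n_images = nrow(found) - n_skip,
    n_skipped = n_skip,
    n_barcodes_decoded = if (nrow(side)) sum(!is.na(side$barcode)) else 0L,
    n_barcodes_failed = n_undecoded))
  message(sprintf(
    "quantified %d image(s) (%d skipped); %d record(s), %d barcode failure(s)",
    nrow(found) - n_skip, n_skip, nrow(records), n_undecoded))
  invisible(list(records = records, top = top, side = side,
                 n_images = nrow(found) - n_skip, n_skipped = n_skip,
                 n_undecoded = n_undecoded))
}

#' Assemble growth curves from quantification records
#'
#' @param records_csv records CSV from [run_quantify()].
#' @param barcode_map_csv barcode map CSV
#'   (`barcode,clone,condition_mM,replicate`).
#' @param out_csv output curves CSV path.
#' @return invisibly, the curves tibble.
#' @export
run_curves <- function(records_csv, barcode_map_csv, out_csv) {
  records <- read_records_csv(records_csv)
  map <- read_barcode_map(barcode_map_csv)
  curves <- assemble_curves(records, map)
  dir.create(dirname(out_csv), recursive = TRUE, showWarnings = FALSE)
  write_curves_csv(curves, out_csv)
  message(sprintf("assembled %d curve(s) from %d record(s)",
                  length(unique(curves$barcode)), nrow(records)))
  invisible(curves)
}

#' Growth-rate and dose-response analysis
#'
#' Runs the viability filter, sliding-window RGR extraction,
#' lethal-dose zero substitution, per-clone LL5 dose-response fits and
#' bootstrap EC50s; writes `rgr.csv`, `dose_response.csv`, `fits.csv`,
#' `ec50.csv` and the two figures.
#'
#' @param curves_csv curves CSV from [run_curves()].
#' @param config pipeline configuration (sections `filter`, `rgr`,
#'   `dose_response`, `seed`).
#' @param out_dir output directory (created).
#' @param figures write PNG figures (default TRUE).
#' @return invisibly, a list with `rgr_table`, `dr_table`, `panel`.
#' @export
run_analyze <- function(curves_csv, config = default_config(),
                        out_dir = ".", figures = TRUE) {
  curves <- read_curves_csv(curves_csv)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  unmapped <- unique(curves$barcode[is.na(curves$condition_mM) |
                                    is.na(curves$clone)])
  if (length(unmapped) > 0L) {
    message(length(unmapped),
            " curve(s) without sample metadata excluded from analysis")
    curves <- curves[!curves$barcode %in% unmapped, , drop = FALSE]
  }
  rgr_table <- sample_rgr_table(curves, config)
  utils::write.csv(as.data.frame(rgr_table),
                   file.path(out_dir, "rgr.csv"), row.names = FALSE)
  dr_table <- substitute_lethal(rgr_table)
  utils::write.csv(as.data.frame(dr_table),
                   file.path(out_dir, "dose_response.csv"),
                   row.names = FALSE)
  if (nrow(dr_table) == 0L ||
      sum(dr_table$rgr_per_day > 0, na.rm = TRUE) == 0L) {
    warning("no viable growth anywhere; EC50 analysis skipped",
            call. = FALSE)
    empty <- tibble::tibble(clone = character(), ec50_mM = numeric(),
                            sd_mM = numeric(), baseline_rgr = numeric(),
                            n_boot_effective = integer())
    utils::write.csv(as.data.frame(empty),
                     file.path(out_dir, "ec50.csv"), row.names = FALSE)
    write_provenance(out_dir, config, list(stage = "analyze"))
    return(invisible(list(rgr_table = rgr_table, dr_table = dr_table,
                          panel = NULL)))
  }
  panel <- withCallingHandlers(
    clone_panel(dr_table, n_boot = config$dose_response$n_boot,
                seed = config$seed,
                baseline_mode = config$dose_response$baseline_mode),
    warning = function(w) { message(conditionMessage(w))
                            invokeRestart("muffleWarning") })
  utils::write.csv(as.data.frame(panel$fits),
                   file.path(out_dir, "fits.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(panel$ec50),
                   file.path(out_dir, "ec50.csv"), row.names = FALSE)
  if (figures && nrow(panel$ec50) > 0L) {
    ggplot2::ggsave(file.path(out_dir, "dose_response.png"),
                    plot_dose_response(panel), width = 8, height = 6,
                    dpi = 120)
    ggplot2::ggsave(file.path(out_dir, "ec50.png"), plot_ec50(panel),
                    width = 6, height = 4, dpi = 120)
  }
  write_provenance(out_dir, config, list(stage = "analyze",
                                         n_clones = nrow(panel$ec50)))
  message(sprintf("analysed %d sample(s); %d clone EC50(s)",
                  nrow(rgr_table), nrow(panel$ec50)))
  invisible(list(rgr_table = rgr_table, dr_table = dr_table,
                 panel = panel))
}

#' Generate a synthetic trial fixture directory
#'
#' @param design a [trial_design()].
#' @param out_dir output directory.
#' @param config pipeline configuration sized to the rendered images.
#' @param images render image files (TRUE) or write only the simulated
#'   curve/truth tables (FALSE).
#' @return invisibly, the [simulate_trial_images()] /
#'   [simulate_trial_curves()] result.
#' @export
run_simulate <- function(design = trial_design(), out_dir,
                         config = default_config(), images = TRUE) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (images) {
    sim <- simulate_trial_images(design, out_dir, config)
    utils::write.csv(as.data.frame(sim$truth),
                     file.path(out_dir, "truth_areas.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(sim$truth_rgr),
                     file.path(out_dir, "truth_rgr.csv"),
                     row.names = FALSE)
    message(sprintf("rendered %d image(s) for %d sample(s)",
                    sim$n_images, nrow(sim$truth_rgr)))
  } else {
    sim <- simulate_trial_curves(design)
    write_curves_csv(sim$curves, file.path(out_dir, "curves.csv"))
    utils::write.csv(as.data.frame(sim$barcode_map),
                     file.path(out_dir, "Barcode_Sample_Map.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(sim$truth),
                     file.path(out_dir, "truth_rgr.csv"),
                     row.names = FALSE)
    message(sprintf("simulated %d curve(s)",
                    length(unique(sim$curves$barcode))))
  }
  write_provenance(out_dir, config, list(stage = "simulate",
                                         design_seed = design$seed))
  invisible(sim)
}
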