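#' Analyse a FLIM plate end to end
#'
#' Runs the analysis chain on an in-memory plate: reference calibration,
#' per-FOV segmentation (on the total-intensity image), pixel-wise
#' mono-exponential fitting above the photon threshold, membrane-ROI binned
#' fitting, well aggregation for both readouts, and assay metrics (Z' from
#' the control columns for each readout, plus a dose-response table with
#' EC50 when the layout carries a dilution series).
#'
#' @param plate A [generate_plate()] result (or an equivalent object built
#'   from read-in stacks).
#' @param seg_params A [segmentation_params()].
#' @param threshold Photon threshold for pixel-wise fitting (default 200).
#' @param aggregate Aggregation method, see [well_aggregate()].
#' @param dose_fit Fit the Hill curve in the dose-response table?
#'
#' @return An object of class `plate_analysis`: per-FOV tibble `fovs`
#'   (with segmentation and fits in list-columns), `wells_pixel` and
#'   `wells_membrane` aggregates, `metrics` (Z' objects and, when
#'   available, the dose-response tables), and the calibrated reference.
#' @export
analyze_plate <- function(plate, seg_params = segmentation_params(),
                          threshold = 200,
                          aggregate = "pixel_pooled", dose_fit = TRUE) {
  stopifnot(inherits(plate, "flim_plate"))
  cal <- calibrate_reference(plate$reference)

  fov_res <- purrr::map(seq_len(nrow(plate$fovs)), function(i) {
    stack <- plate$fovs$stack[[i]]
    seg <- segment_cells(intensity_image(stack), seg_params)
    li <- fit_pixelwise(stack, cal, threshold = threshold)
    mem_fits <- if (seg$no_cells) list() else
      purrr::map(seg$membrane_masks, function(m)
        fit_roi_binned(stack, cal, m))
    list(seg = seg, lifetime = li, membrane_fits = mem_fits)
  })
  fovs <- plate$fovs |>
    dplyr::select(-dplyr::any_of(c("field", "stack"))) |>
    dplyr::mutate(
      segmentation = purrr::map(fov_res, "seg"),
      lifetime = purrr::map(fov_res, "lifetime"),
      membrane_fits = purrr::map(fov_res, "membrane_fits"))

  pixel_values <- purrr::map_dfr(seq_len(nrow(fovs)), function(i) {
    tau <- fov_res[[i]]$lifetime$tau_ps
    tibble(well = fovs$well[i], fov = fovs$fov[i],
           value = as.vector(tau[is.finite(tau)]) %0% NA_real_)
  })
  membrane_values <- purrr::map_dfr(seq_len(nrow(fovs)), function(i) {
    f <- fov_res[[i]]$membrane_fits
    taus <- purrr::map_dbl(f, "tau_ps")
    tibble(well = fovs$well[i], fov = fovs$fov[i],
           value = taus[is.finite(taus)] %0% NA_real_)
  })
  wells_pixel <- well_aggregate(pixel_values, aggregate)
  wells_membrane <- well_aggregate(membrane_values, aggregate)

  metrics <- list()
  lay <- as_tibble(plate$layout)
  arm <- function(wells, role) {
    wells$mean_tau[wells$well %in% lay$well[lay$role == role] &
                     !wells$no_cells]
  }
  zp <- function(wells) {
    pos <- arm(wells, "positive_control"); neg <- arm(wells, "negative_control")
    if (length(pos) >= 2 && length(neg) >= 2) z_prime(pos, neg) else NULL
  }
  metrics$z_prime_pixel <- zp(wells_pixel)
  metrics$z_prime_membrane <- zp(wells_membrane)
  if (sum(!is.na(unique(lay$dose_uM[lay$role == "dose"]))) >= 2) {
    metrics$dose_response_pixel <- dose_response_table(
      wells_pixel, plate$layout, fit = dose_fit, seed = plate$seed)
    metrics$dose_response_membrane <- dose_response_table(
      wells_membrane, plate$layout, fit = dose_fit, seed = plate$seed)
  }
  structure(list(fovs = fovs, wells_pixel = wells_pixel,
                 wells_membrane = wells_membrane,
                 metrics = metrics, calibration = cal,
                 layout = plate$layout, threshold = threshold,
                 seg_params = seg_params),
            class = "plate_analysis")
}

# empty-to-NA helper so wells with no defined values keep one flagged row
`%0%` <- function(x, fill) if (length(x)) x else fill

#' @export
print.plate_analysis <- function(x, ...) {
  cat("<plate_analysis>\n")
  if (!is.null(x$metrics$z_prime_pixel))
    cat(sprintf("  Z' (pixel-wise):   %.3f\n",
                x$metrics$z_prime_pixel$z_prime))
  if (!is.null(x$metrics$z_prime_membrane))
    cat(sprintf("  Z' (membrane ROI): %.3f\n",
                x$metrics$z_prime_membrane$z_prime))
  invisible(x)
}

#' Pool membrane-ROI decays of a plate by condition
#'
#' Sums the gated counts over the membrane-ROI pixels of every FOV,
#' grouped by a condition key (by default the dose), yielding the pooled
#' decays that feed [fit_global_binned()]. The plate row is carried as the
#' `replicate` column so the shared FRET lifetime can be refit across
#' replicate rows.
#'
#' @param plate A [generate_plate()] result.
#' @param analysis The matching [analyze_plate()] result (for the masks).
#' @param by Grouping column of the layout: `"dose_uM"` (default),
#'   `"condition"` or `"well"`.
#' @param roles Layout roles to include.
#' @return A tibble with `condition`, `replicate` and a `counts`
#'   list-column, ready for [fit_global_binned()].
#' @export
pool_membrane_decays <- function(plate, analysis, by = "dose_uM",
                                 roles = c("dose", "negative_control")) {
  stopifnot(inherits(plate, "flim_plate"),
            inherits(analysis, "plate_analysis"))
  rows <- which(plate$fovs$role %in% roles)
  out <- purrr::map_dfr(rows, function(i) {
    seg <- analysis$fovs$segmentation[[i]]
    if (seg$no_cells) return(NULL)
    stack <- plate$fovs$stack[[i]]
    d <- dim(stack$counts)
    mask <- Reduce(`|`, seg$membrane_masks)
    Y <- matrix(stack$counts, nrow = d[1])[, which(mask), drop = FALSE]
    tibble(condition = as.character(plate$fovs[[by]][i]),
           replicate = plate$fovs$row[i],
           counts = list(rowSums(Y)))
  })
  out
}

#' Run the full pipeline and write its artifact tree
#'
#' `simulate -> segment -> fit -> report` driven by a [run_config()]:
#' generates the plate, analyses it, and writes per-well CSVs, plate-map
#' CSV, metrics JSON and a provenance record (config hash, package version,
#' seed) under `out_dir`. Identical seeds produce identical artifacts.
#'
#' @param rc A [run_config()] (or path to its YAML).
#' @param out_dir Output directory.
#' @param write_stacks Also write every simulated stack as TIFF?
#'
#' @return The [analyze_plate()] result, invisibly, with the artifact paths
#'   in attribute `paths`.
#' @export
run_pipeline <- function(rc, out_dir, write_stacks = FALSE) {
  if (is.character(rc)) rc <- read_run_config(rc)
  stopifnot(inherits(rc, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  layout <- switch(rc$layout_kind,
    dose_response = plate_layout_dose_response(rows = rc$config$rows,
                                               cols = rc$config$cols),
    characterisation = plate_layout_characterisation(
      rc$char_doses %||% setNames(dose_at_effect(c(0.2, 0.5, 0.8), rc$model),
                                  c("low", "medium", "high")),
      rows = rc$config$rows, cols = rc$config$cols),
    abort(sprintf("unknown layout kind `%s`", rc$layout_kind)))
  plate <- generate_plate(layout, rc$config, rc$model, seed = rc$seed,
                          out_dir = if (write_stacks)
                            file.path(out_dir, "stacks") else NULL)
  an <- analyze_plate(plate, rc$seg_params, threshold = rc$threshold)

  paths <- list(
    wells_pixel = file.path(out_dir, "wells_pixelwise.csv"),
    wells_membrane = file.path(out_dir, "wells_membrane.csv"),
    plate_map = file.path(out_dir, "plate_map.csv"),
    metrics = file.path(out_dir, "metrics.json"),
    provenance = file.path(out_dir, "provenance.json"))
  utils::write.csv(an$wells_pixel, paths$wells_pixel, row.names = FALSE)
  utils::write.csv(an$wells_membrane, paths$wells_membrane, row.names = FALSE)
  pm <- plate_map(an$wells_pixel, layout)
  utils::write.csv(as.data.frame(pm), paths$plate_map, row.names = FALSE)

  metr <- list()
  if (!is.null(an$metrics$z_prime_pixel))
    metr$z_prime_pixel <- an$metrics$z_prime_pixel$z_prime
  if (!is.null(an$metrics$z_prime_membrane))
    metr$z_prime_membrane <- an$metrics$z_prime_membrane$z_prime
  drp <- an$metrics$dose_response_pixel
  if (!is.null(drp)) {
    hf <- attr(drp, "hill_fit")
    if (!is.null(hf) && !isTRUE(hf$unidentifiable))
      metr$ec50_uM <- hf$ec50_uM
    metr$dose_response <- as.data.frame(drp)
  }
  jsonlite::write_json(metr, paths$metrics, auto_unbox = TRUE, digits = NA)

  cfg_file <- file.path(out_dir, "run_config.yaml")
  write_run_config(rc, cfg_file)
  jsonlite::write_json(list(
    package = "flimplate",
    version = as.character(utils::packageVersion("flimplate")),
    seed = rc$seed,
    config_md5 = unname(tools::md5sum(cfg_file))),
    paths$provenance, auto_unbox = TRUE)
  attr(an, "paths") <- paths
  invisible(an)
}
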