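# On-disk formats: gated stacks as multi-page 16-bit TIFF (one page per
# gate) with a JSON sidecar holding gate timing and provenance; lifetime
# images as 32-bit float TIFF (values scaled into [0,1] by a recorded
# factor); references and metrics as JSON; layouts as CSV; configs as YAML.

sidecar_path <- function(path) paste0(tools::file_path_sans_ext(path), ".json")

#' Write / read a gated stack as multi-page TIFF with JSON sidecar
#'
#' Counts are stored as 16-bit unsigned integers, one page per gate; the
#' sidecar records `gate_delays_ps`, `gate_width_ps` and any extra metadata
#' (well, fov, seed). Writing the same stack twice produces byte-identical
#' files; `read_gated_stack(write_gated_stack(x))` is the identity on counts
#' and gate metadata.
#'
#' @param stack A [gated_stack()].
#' @param path TIFF file path (`.tif`); the sidecar goes to the same path
#'   with extension `.json`.
#' @param meta Named list of extra metadata for the sidecar.
#' @return `write_gated_stack()` returns `path` invisibly;
#'   `read_gated_stack()` returns a [gated_stack()] with attribute `meta`.
#' @export
write_gated_stack <- function(stack, path, meta = list()) {
  stopifnot(inherits(stack, "gated_stack"))
  if (max(stack$counts) > 65535)
    abort("counts exceed the 16-bit range")
  pages <- lapply(seq_len(dim(stack$counts)[1]),
                  function(g) stack$counts[g, , ] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- c(list(gate_delays_ps = stack$gate_delays_ps,
                 gate_width_ps = stack$gate_width_ps), meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_gated_stack
#' @export
read_gated_stack <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("missing sidecar: expected metadata file `%s`", sp))
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(side$gate_delays_ps))
    abort(sprintf("gate count mismatch: %d TIFF pages but %d gate delays",
                  length(pages), length(side$gate_delays_ps)))
  counts <- array(0, c(length(pages), dim(pages[[1]])))
  for (g in seq_along(pages)) counts[g, , ] <- round(pages[[g]] * 65535)
  stack <- gated_stack(counts, side$gate_delays_ps, side$gate_width_ps)
  attr(stack, "meta") <- side[setdiff(names(side),
                                      c("gate_delays_ps", "gate_width_ps"))]
  stack
}

#' Write / read a reference decay as JSON
#'
#' @param reference A [reference_decay()].
#' @param path JSON file path.
#' @return The path (write, invisibly) or a [reference_decay()] (read).
#' @export
write_reference <- function(reference, path) {
  stopifnot(inherits(reference, "reference_decay"))
  jsonlite::write_json(unclass(reference), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  reference_decay(x$counts, x$gate_delays_ps, x$gate_width_ps, x$tau_ref_ps)
}

#' Write / read a lifetime image as 32-bit float TIFF
#'
#' Lifetimes (ps) are scaled by `1/scale_ps` into `[0, 1]` for storage; the
#' sidecar records the scale, the photon threshold and undefined pixels
#' (stored as 0 with a mask page semantics: NA pixels round-trip as NA).
#'
#' @param img A `lifetime_image` from [fit_pixelwise()].
#' @param path TIFF file path.
#' @param scale_ps Full-scale lifetime (default 10000 ps).
#' @return The path (write, invisibly) or a `lifetime_image` (read).
#' @export
write_lifetime_image <- function(img, path, scale_ps = 10000) {
  stopifnot(inherits(img, "lifetime_image"))
  tau <- img$tau_ps
  defined <- is.finite(tau)
  tau_page <- ifelse(defined, pmin(tau / scale_ps, 1), 0)
  tiff::writeTIFF(list(tau_page, defined * 1),
                  path, bits.per.sample = 32L, compression = "none")
  jsonlite::write_json(
    list(scale_ps = scale_ps, threshold = img$threshold,
         no_pixels = img$no_pixels),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lifetime_image
#' @export
read_lifetime_image <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp))
    abort(sprintf("missing sidecar: expected metadata file `%s`", sp))
  side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  tau <- pages[[1]] * side$scale_ps
  tau[pages[[2]] < 0.5] <- NA_real_
  structure(list(tau_ps = tau, se_tau_ps = NULL, chi2_reduced = NULL,
                 n_photons = NULL, threshold = side$threshold,
                 no_pixels = isTRUE(side$no_pixels)),
            class = "lifetime_image")
}

#' Write a generated plate to disk
#'
#' One TIFF + JSON sidecar per FOV (named `well_fov.tif`), the reference as
#' `reference.json`, the ground-truth manifest as `manifest.json` and the
#' layout as `layout.csv`.
#'
#' @param plate A [generate_plate()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_plate <- function(plate, dir) {
  stopifnot(inherits(plate, "flim_plate"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_len(nrow(plate$fovs))) {
    rec <- plate$fovs[i, ]
    write_gated_stack(
      rec$stack[[1]],
      file.path(dir, sprintf("%s_fov%d.tif", rec$well, rec$fov)),
      meta = list(well = rec$well, fov = rec$fov, seed = plate$seed))
  }
  write_reference(plate$reference, file.path(dir, "reference.json"))
  jsonlite::write_json(plate$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  write_plate_layout(plate$layout, file.path(dir, "layout.csv"))
  invisible(dir)
}

#' Pipeline run configuration
#'
#' Bundles the stage parameters, paths and seed of a full
#' simulate-segment-fit-report run; round-trips losslessly through YAML.
#'
#' @param config A [simulation_config()].
#' @param model A [dose_response_model()].
#' @param seg_params A [segmentation_params()].
#' @param threshold Photon threshold for pixel-wise fitting.
#' @param seed Integer seed for all randomness in the run.
#' @param layout_kind `"dose_response"` or `"characterisation"`.
#' @param char_doses Dose triple for the characterisation layout.
#' @return A list of class `run_config`.
#' @export
run_config <- function(config = simulation_config(),
                       model = dose_response_model(),
                       seg_params = segmentation_params(),
                       threshold = 200, seed = 1L,
                       layout_kind = "dose_response",
                       char_doses = NULL) {
  structure(list(config = config, model = model, seg_params = seg_params,
                 threshold = threshold, seed = as.integer(seed),
                 layout_kind = layout_kind, char_doses = char_doses),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(rc, path) {
  stopifnot(inherits(rc, "run_config"))
  yaml::write_yaml(list(
    simulation = unclass(rc$config),
    dose_response = unclass(rc$model),
    segmentation = unclass(rc$seg_params),
    threshold = rc$threshold, seed = rc$seed,
    layout_kind = rc$layout_kind, char_doses = rc$char_doses), path)
  invisible(path)
}

#' @rdname run_config
#' @param rc A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- do.call(simulation_config, x$simulation)
  mdl <- do.call(dose_response_model, x$dose_response)
  seg <- do.call(segmentation_params, x$segmentation)
  run_config(cfg, mdl, seg, threshold = x$threshold, seed = x$seed,
             layout_kind = x$layout_kind,
             char_doses = if (is.null(x$char_doses)) NULL else
               unlist(x$char_doses))
}
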