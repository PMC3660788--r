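#' Generate a synthetic FLIM plate
#'
#' Simulates one gated image stack per field of view per non-empty well,
#' together with a matching reference-dye measurement and a ground-truth
#' manifest. The membrane FRETing fraction of each well follows the Hill
#' dose-response model: positive-control wells sit at `f_min` (no membrane
#' aggregation), vehicle wells at `f_max`, dosed wells at
#' [fret_fraction_at_dose()]. The cytoplasm carries the residual
#' dimerisation fraction, and FRETing debris is scattered on the background
#' in proportion to the well's FRETing fraction.
#'
#' @param layout A [plate_layout()].
#' @param config A [simulation_config()].
#' @param model A [dose_response_model()].
#' @param seed Integer seed; every stack derives its own sub-seed from it,
#'   so identical seeds give bit-identical plates.
#' @param out_dir Optional directory; when given, stacks, reference and
#'   manifest are also written to disk (see [write_plate()]).
#'
#' @return An object of class `flim_plate`: a list with `fovs` (a tibble
#'   with one row per FOV and the stack in a list-column), `reference`,
#'   `manifest` (per-well ground truth), `layout`, `config`, `model`, `seed`.
#' @export
generate_plate <- function(layout, config, model, seed = 1L, out_dir = NULL) {
  stopifnot(inherits(layout, "plate_layout"),
            inherits(config, "simulation_config"),
            inherits(model, "dose_response_model"))
  seed <- as.integer(seed)
  reference <- simulate_reference(config, seed = seed)

  active <- dplyr::filter(as_tibble(layout), .data$role != "excluded")
  # wells the automated cell finder will fail on, chosen reproducibly
  no_cells_wells <- character(0)
  if (config$no_cell_fraction > 0 && nrow(active) > 0) {
    n_fail <- round(config$no_cell_fraction * nrow(active))
    no_cells_wells <- with_seed_maybe(seed + 1L,
      sample(active$well, n_fail))
  }

  fov_rows <- list()
  manifest <- list()
  i <- 0L
  for (w in seq_len(nrow(active))) {
    rec <- active[w, ]
    f_mem <- switch(rec$role,
      positive_control = model$f_min,
      negative_control = model$f_max,
      dose = fret_fraction_at_dose(rec$dose_uM, model))
    mixtures <- well_mixtures(f_mem, config)
    no_cells <- rec$well %in% no_cells_wells
    n_debris <- if (no_cells) 0L else
      as.integer(round(config$debris_rate * f_mem / max(model$f_max, 1e-12)))
    manifest[[w]] <- tibble(
      well = rec$well, row = rec$row, col = rec$col,
      condition = rec$condition, dose_uM = rec$dose_uM, role = rec$role,
      f_membrane = f_mem,
      f_cytoplasm = min(1, config$cytoplasm_fret_scale * f_mem),
      n_debris_per_fov = n_debris, no_cells = no_cells)
    for (fov in seq_len(config$fovs_per_well)) {
      i <- i + 1L
      # independent, reproducible sub-seed per FOV
      sub_seed <- (seed + 7919L * ((rec$row - 1L) * 101L + rec$col) +
                     131L * fov) %% .Machine$integer.max
      field <- render_cell_field(
        n_cells = if (no_cells) 0L else config$cells_per_fov,
        frame_dim = config$frame_dim,
        axes = config$cell_axes_px, axes_jitter = config$cell_axes_jitter_px,
        membrane_width = config$membrane_width_px,
        n_debris = n_debris, debris_radius = config$debris_radius_px,
        seed = sub_seed)
      stack <- simulate_gated_stack(field, mixtures, config,
                                    seed = sub_seed + 1L)
      fov_rows[[i]] <- tibble(
        well = rec$well, row = rec$row, col = rec$col,
        condition = rec$condition, dose_uM = rec$dose_uM, role = rec$role,
        fov = fov, no_cells = no_cells,
        field = list(field), stack = list(stack))
    }
  }
  fovs <- if (i) dplyr::bind_rows(fov_rows) else tibble(
    well = character(), row = integer(), col = integer(),
    condition = character(), dose_uM = numeric(), role = character(),
    fov = integer(), no_cells = logical(), field = list(), stack = list())
  plate <- structure(
    list(fovs = fovs, reference = reference,
         manifest = if (length(manifest)) dplyr::bind_rows(manifest) else
           tibble(),
         layout = layout, config = config, model = model, seed = seed),
    class = "flim_plate")
  if (!is.null(out_dir)) write_plate(plate, out_dir)
  plate
}

#' @export
print.flim_plate <- function(x, ...) {
  cat(sprintf("<flim_plate> %d FOVs over %d wells, seed %d\n",
              nrow(x$fovs), length(unique(x$fovs$well)), x$seed))
  invisible(x)
}
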