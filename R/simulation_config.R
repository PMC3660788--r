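#' Configuration for the synthetic plate generator
#'
#' Collects every tunable of the simulated instrument and sample. Defaults
#' describe a scaled-down 96-well Gag-aggregation assay: a CFP-like donor
#' (2950 ps), a FRET-shortened donor (766 ps), a DASPI-like reference dye
#' (50 ps), a Gaussian instrument response of 150 ps FWHM, and sixteen
#' contiguous time gates spanning 0-8000 ps.
#'
#' @param rows,cols Plate geometry (default 8 x 12, a 96-well plate).
#' @param fovs_per_well Fields of view imaged per well.
#' @param frame_dim Image height and width in pixels.
#' @param gate_delays_ps Gate opening delays (ps), strictly increasing.
#' @param gate_width_ps Gate width (ps). The default makes gates contiguous.
#' @param tau_donor_ps Non-FRETing donor lifetime (ps).
#' @param tau_fret_ps FRET-shortened donor lifetime (ps).
#' @param tau_ref_ps Reference dye lifetime (ps).
#' @param irf_fwhm_ps Instrument response FWHM (ps), Gaussian.
#' @param irf_center_ps Arrival time of the excitation pulse (ps) relative to
#'   the first gate delay.
#' @param irf_grid_ps Internal fine time grid step (ps) for gate integration.
#' @param photon_budget Expected total photons per membrane pixel over the
#'   full gate schedule.
#' @param cytoplasm_brightness Cytoplasm brightness as a fraction of
#'   `photon_budget`.
#' @param background_photons Expected background photons per pixel.
#' @param cells_per_fov Target number of cells per field of view.
#' @param cell_axes_px Mean ellipse semi-axes (pixels), `c(major, minor)`.
#' @param cell_axes_jitter_px Half-range of uniform jitter on each semi-axis.
#' @param membrane_width_px Width of the plasma-membrane ring (pixels).
#' @param debris_rate Expected number of FRETing debris blobs per FOV at the
#'   maximal FRETing fraction; the realised rate scales with the well's
#'   FRETing fraction, mimicking debris shed by budding virus-like particles.
#' @param debris_radius_px Range of debris blob radii (pixels).
#' @param cytoplasm_fret_scale Cytoplasmic FRETing fraction as a multiple of
#'   the membrane fraction (residual dimerisation in the cytoplasm).
#' @param reference_photons Total photons in the reference measurement.
#' @param no_cell_fraction Fraction of non-empty wells that yield no cells
#'   (emulating wells the automated cell finder fails on).
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(rows = 8L, cols = 12L, fovs_per_well = 1L,
                              frame_dim = c(64L, 64L),
                              gate_delays_ps = seq(0, 8000, length.out = 16),
                              gate_width_ps = 8000 / 15,
                              tau_donor_ps = 2950, tau_fret_ps = 766,
                              tau_ref_ps = 50,
                              irf_fwhm_ps = 150, irf_center_ps = 500,
                              irf_grid_ps = 10,
                              photon_budget = 800,
                              cytoplasm_brightness = 0.4,
                              background_photons = 2,
                              cells_per_fov = 4L,
                              cell_axes_px = c(9, 7),
                              cell_axes_jitter_px = 1,
                              membrane_width_px = 3L,
                              debris_rate = 12,
                              debris_radius_px = c(2L, 4L),
                              cytoplasm_fret_scale = 0.25,
                              reference_photons = 1e7,
                              no_cell_fraction = 0) {
  cfg <- list(
    rows = as.integer(rows), cols = as.integer(cols),
    fovs_per_well = as.integer(fovs_per_well),
    frame_dim = as.integer(frame_dim),
    gate_delays_ps = as.numeric(gate_delays_ps),
    gate_width_ps = as.numeric(gate_width_ps),
    tau_donor_ps = tau_donor_ps, tau_fret_ps = tau_fret_ps,
    tau_ref_ps = tau_ref_ps,
    irf_fwhm_ps = irf_fwhm_ps, irf_center_ps = irf_center_ps,
    irf_grid_ps = irf_grid_ps,
    photon_budget = photon_budget,
    cytoplasm_brightness = cytoplasm_brightness,
    background_photons = background_photons,
    cells_per_fov = as.integer(cells_per_fov),
    cell_axes_px = as.numeric(cell_axes_px),
    cell_axes_jitter_px = cell_axes_jitter_px,
    membrane_width_px = as.integer(membrane_width_px),
    debris_rate = debris_rate,
    debris_radius_px = as.integer(debris_radius_px),
    cytoplasm_fret_scale = cytoplasm_fret_scale,
    reference_photons = reference_photons,
    no_cell_fraction = no_cell_fraction)
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (length(gate_delays_ps) < 2 || any(diff(gate_delays_ps) <= 0))
      abort("gate delays must be strictly increasing (>= 2 gates)")
    if (gate_width_ps <= 0) abort("gate width must be > 0")
    for (nm in c("tau_donor_ps", "tau_fret_ps", "tau_ref_ps"))
      if (cfg[[nm]] <= 0) abort(paste0("`", nm, "` must be > 0"))
    if (photon_budget < 0) abort("photon budget must be >= 0")
    if (irf_fwhm_ps <= 0 || irf_grid_ps <= 0)
      abort("IRF width and grid step must be > 0")
    if (no_cell_fraction < 0 || no_cell_fraction > 1)
      abort("`no_cell_fraction` must lie in [0, 1]")
    if (length(frame_dim) != 2 || any(frame_dim < 8))
      abort("`frame_dim` must give height and width >= 8 px")
  })
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(
    paste0("<simulation_config> %dx%d plate, %d FOV/well, %dx%d px, ",
           "%d gates %g-%g ps (width %g)\n  tau_D %g ps, tau_F %g ps, ",
           "tau_ref %g ps, IRF %g ps FWHM @ %g ps, budget %g photons/px\n"),
    x$rows, x$cols, x$fovs_per_well, x$frame_dim[1], x$frame_dim[2],
    length(x$gate_delays_ps), min(x$gate_delays_ps), max(x$gate_delays_ps),
    x$gate_width_ps, x$tau_donor_ps, x$tau_fret_ps, x$tau_ref_ps,
    x$irf_fwhm_ps, x$irf_center_ps, x$photon_budget))
  invisible(x)
}
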