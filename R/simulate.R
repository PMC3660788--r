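#' Decay mixture specification
#'
#' A set of exponential components given as photon fractions and lifetimes,
#' plus a per-pixel brightness (expected total photons over the full gate
#' schedule). Fractions must sum to 1.
#'
#' @param fractions Photon fractions, summing to 1 (tolerance 1e-6).
#' @param lifetimes_ps Component lifetimes (ps), > 0.
#' @param brightness Expected photons per pixel over the gate schedule.
#' @return A list of class `decay_mixture`.
#' @export
decay_mixture <- function(fractions, lifetimes_ps, brightness) {
  if (length(fractions) != length(lifetimes_ps))
    abort("`fractions` and `lifetimes_ps` must have equal length")
  if (abs(sum(fractions) - 1) > 1e-6)
    abort("mixture fractions must sum to 1")
  if (any(fractions < -1e-12) || any(lifetimes_ps <= 0))
    abort("fractions must be >= 0 and lifetimes > 0")
  if (brightness < 0) abort("brightness must be >= 0")
  structure(list(fractions = as.numeric(fractions),
                 lifetimes_ps = as.numeric(lifetimes_ps),
                 brightness = brightness),
            class = "decay_mixture")
}

#' Simulate a time-gated image stack
#'
#' For each compartment in a label image, the expected counts per pixel per
#' gate are the gate-integrals of the instrument response convolved with the
#' compartment's exponential mixture, normalised over the gate schedule so
#' that the expected total photons per pixel equal the mixture's brightness.
#' Realised counts are Poisson draws.
#'
#' @param labels Integer matrix of compartment labels, or a
#'   [render_cell_field()] result (its `compartment` matrix is used).
#' @param mixtures Named list of [decay_mixture()]s, one per compartment
#'   label present; names are the label values as character (e.g. `"0"` for
#'   background) or the convenience names `"background"`, `"cytoplasm"`,
#'   `"membrane"`, `"debris"` for labels 0-3.
#' @param config A [simulation_config()] (supplies the gate schedule and the
#'   instrument response).
#' @param seed Optional RNG seed.
#'
#' @return A [gated_stack()].
#' @export
simulate_gated_stack <- function(labels, mixtures, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (inherits(labels, "cell_field")) labels <- labels$compartment
  stopifnot(is.matrix(labels))
  expected <- expected_stack(labels, mixtures, config)
  counts <- with_seed_maybe(seed, {
    array(rpois(length(expected), expected), dim = dim(expected))
  })
  gated_stack(counts, config$gate_delays_ps, config$gate_width_ps)
}

# expected (noise-free) gate x row x col array for a label image; mixture
# names may be label values as character or the standard compartment names
expected_stack <- function(labels, mixtures, config) {
  comp_names <- c(background = "0", cytoplasm = "1", membrane = "2",
                  debris = "3")
  nm <- names(mixtures)
  named <- nm %in% names(comp_names)
  nm[named] <- comp_names[nm[named]]
  names(mixtures) <- nm
  n_gate <- length(config$gate_delays_ps)
  nr <- nrow(labels); nc <- ncol(labels)
  expected <- array(0, dim = c(n_gate, nr, nc))
  for (lab in unique(as.vector(labels))) {
    mix <- mixtures[[as.character(lab)]]
    if (is.null(mix))
      abort(sprintf("no decay mixture supplied for compartment label %s", lab))
    stopifnot(inherits(mix, "decay_mixture"))
    if (mix$brightness == 0) next
    shape <- mixture_gate_shape(mix$fractions, mix$lifetimes_ps, config)
    idx <- which(labels == lab)
    per_gate <- shape * mix$brightness
    for (g in seq_len(n_gate))
      expected[g, , ][idx] <- per_gate[g]
  }
  expected
}

#' Simulate a reference-dye measurement
#'
#' Generates the gated decay of a mono-exponential short-lifetime standard
#' under the same instrument response and gate schedule as the samples, with
#' Poisson counting noise, and stores the known reference lifetime alongside
#' the counts.
#'
#' @param config A [simulation_config()]; `tau_ref_ps` and
#'   `reference_photons` set the dye lifetime and the photon budget.
#' @param seed Optional RNG seed.
#' @param photons Total expected photons (defaults to
#'   `config$reference_photons`).
#'
#' @return A [reference_decay()].
#' @export
simulate_reference <- function(config, seed = NULL,
                               photons = config$reference_photons) {
  stopifnot(inherits(config, "simulation_config"))
  shape <- mixture_gate_shape(1, config$tau_ref_ps, config)
  expected <- shape * photons
  counts <- with_seed_maybe(seed, rpois(length(expected), expected))
  reference_decay(counts, config$gate_delays_ps, config$gate_width_ps,
                  config$tau_ref_ps)
}

# Build the compartment mixtures for a well given its membrane FRETing
# (amplitude) fraction. Amplitude fractions are converted to the photon
# fractions the generator consumes; cytoplasm carries a scaled-down fraction
# (residual dimerisation); debris is pure FRET decay at membrane brightness.
well_mixtures <- function(f_membrane, config) {
  taus <- c(config$tau_fret_ps, config$tau_donor_ps)
  mix_for <- function(f_amp, brightness) {
    p <- amplitude_to_photon_fractions(c(f_amp, 1 - f_amp), taus)
    decay_mixture(p, taus, brightness)
  }
  f_cyto <- min(1, config$cytoplasm_fret_scale * f_membrane)
  list(
    background = decay_mixture(c(0, 1), taus, config$background_photons),
    cytoplasm = mix_for(f_cyto,
                        config$cytoplasm_brightness * config$photon_budget),
    membrane = mix_for(f_membrane, config$photon_budget),
    debris = decay_mixture(c(1, 0), taus, config$photon_budget))
}
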