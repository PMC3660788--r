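#' Time-gated image stack
#'
#' The raw FLIM datum: one photon-count frame per gate delay. Counts are
#' stored as a `gate x row x col` array.
#'
#' @param counts 3-D non-negative array (gate, row, col) of photon counts.
#' @param gate_delays_ps Gate opening delays (ps), strictly increasing, one
#'   per count frame.
#' @param gate_width_ps Common gate width (ps).
#'
#' @return An object of class `gated_stack`.
#' @export
gated_stack <- function(counts, gate_delays_ps, gate_width_ps) {
  if (!is.array(counts) || length(dim(counts)) != 3)
    abort("`counts` must be a 3-D array (gate x row x col)")
  if (dim(counts)[1] != length(gate_delays_ps))
    abort("number of count frames must equal the number of gate delays")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("counts must be finite and >= 0")
  if (length(gate_delays_ps) > 1 && any(diff(gate_delays_ps) <= 0))
    abort("gate delays must be strictly increasing")
  if (gate_width_ps <= 0) abort("gate width must be > 0")
  structure(list(counts = counts,
                 gate_delays_ps = as.numeric(gate_delays_ps),
                 gate_width_ps = as.numeric(gate_width_ps)),
            class = "gated_stack")
}

#' @export
print.gated_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<gated_stack> %d gates x %dx%d px, %g photons total\n",
              d[1], d[2], d[3], sum(x$counts)))
  invisible(x)
}

#' Total-intensity image of a gated stack
#'
#' Sums photon counts over all gates, giving the integrated-intensity frame
#' used for segmentation and for the per-pixel photon threshold.
#'
#' @param stack A [gated_stack()].
#' @return Numeric matrix (row x col).
#' @export
intensity_image <- function(stack) {
  stopifnot(inherits(stack, "gated_stack"))
  apply(stack$counts, c(2, 3), sum)
}

#' Reference-dye decay measurement
#'
#' A gated measurement of a short-lifetime lifetime standard (e.g. DASPI)
#' together with its known lifetime. The reference carries the instrument
#' response implicitly and calibrates the decay fitting through reference
#' reconvolution.
#'
#' @param counts Numeric vector of counts, one per gate.
#' @param gate_delays_ps Gate delays (ps), strictly increasing.
#' @param gate_width_ps Gate width (ps).
#' @param tau_ref_ps Known reference lifetime (ps), > 0.
#'
#' @return An object of class `reference_decay`.
#' @export
reference_decay <- function(counts, gate_delays_ps, gate_width_ps, tau_ref_ps) {
  if (length(counts) != length(gate_delays_ps))
    abort("`counts` and `gate_delays_ps` must have equal length")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("reference counts must be finite and >= 0")
  if (length(gate_delays_ps) > 1 && any(diff(gate_delays_ps) <= 0))
    abort("gate delays must be strictly increasing")
  if (tau_ref_ps <= 0) abort("`tau_ref_ps` must be > 0")
  structure(list(counts = as.numeric(counts),
                 gate_delays_ps = as.numeric(gate_delays_ps),
                 gate_width_ps = as.numeric(gate_width_ps),
                 tau_ref_ps = tau_ref_ps),
            class = "reference_decay")
}

#' @export
print.reference_decay <- function(x, ...) {
  cat(sprintf("<reference_decay> %d gates, tau_ref %g ps, %g photons\n",
              length(x$counts), x$tau_ref_ps, sum(x$counts)))
  invisible(x)
}
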