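# Core decay numerics shared by the generator and the fitting engine.
#
# All times in picoseconds. A fluorescence decay excited at time t0 through a
# Gaussian instrument response of standard deviation `sigma` and decaying
# mono-exponentially with lifetime `tau` follows the exponentially modified
# Gaussian (EMG); evaluated in log space so the t << t0 wing underflows to 0
# instead of overflowing.

# unit-area EMG: Gaussian(t0, sigma) convolved with (1/tau) exp(-t/tau)
emg_density <- function(t, tau, t0, sigma) {
  z <- ((t - t0) - sigma^2 / tau) / sigma
  exp(-log(tau) + pnorm(z, log.p = TRUE) + sigma^2 / (2 * tau^2) - (t - t0) / tau)
}

# integral of the EMG over each gate [delay, delay + width], trapezoid rule
# on a grid of step <= dt
gate_integral_emg <- function(tau, delays, width, t0, sigma, dt = 10) {
  n_sub <- max(2L, ceiling(width / dt) + 1L)
  offs <- seq(0, width, length.out = n_sub)
  h <- offs[2] - offs[1]
  vapply(delays, function(d) {
    v <- emg_density(d + offs, tau, t0, sigma)
    sum((v[-1] + v[-length(v)]) / 2) * h
  }, numeric(1))
}

# Unit-sum gated shape of a photon-fraction mixture: counts per gate
# proportional to the gate integral of IRF (x) sum_i beta_i (1/tau_i) e^(-t/tau_i),
# normalised over the gate schedule.
mixture_gate_shape <- function(fractions, lifetimes, config) {
  sigma <- config$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  g <- rep(0, length(config$gate_delays_ps))
  for (i in seq_along(fractions)) {
    g <- g + fractions[i] * gate_integral_emg(
      lifetimes[i], config$gate_delays_ps, config$gate_width_ps,
      config$irf_center_ps, sigma, dt = config$irf_grid_ps)
  }
  if (sum(g) <= 0) return(g * 0)
  g / sum(g)
}

# Causal convolution c(t_k) = int_0^{t_k} R(s) exp(-(t_k - s)/tau) ds for a
# piecewise-linear R given at nodes `grid` (exact for the interpolant).
# `tau` may be a vector; returns length(grid) x length(tau) matrix.
conv_exp_pl <- function(grid, values, tau) {
  n <- length(grid); m <- length(tau)
  out <- matrix(0, n, m)
  D <- diff(grid)
  b <- diff(values) / D
  tau_row <- matrix(tau, 1, m)
  for (k in seq_len(n - 1)) {
    E <- exp(-D[k] / tau)
    seg <- values[k + 1] * tau * (1 - E) -
      b[k] * (tau^2 * (1 - E) - tau * D[k] * E)
    out[k + 1, ] <- out[k, ] * E + seg
  }
  out
}

#' Convert between amplitude and photon fractions of a decay mixture
#'
#' A component with amplitude fraction `beta_i` and lifetime `tau_i`
#' contributes photons in proportion to `beta_i * tau_i`. The generator's
#' mixtures are specified as photon fractions, while the bi-exponential
#' population fraction `beta1` of the global analysis is an amplitude
#' fraction; these helpers convert between the two conventions.
#'
#' @param beta,p Amplitude (resp. photon) fractions, summing to 1.
#' @param tau Component lifetimes (ps).
#' @return Fractions in the other convention, summing to 1.
#' @export
amplitude_to_photon_fractions <- function(beta, tau) {
  p <- beta * tau
  p / sum(p)
}

#' @rdname amplitude_to_photon_fractions
#' @export
photon_to_amplitude_fractions <- function(p, tau) {
  a <- p / tau
  a / sum(a)
}
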