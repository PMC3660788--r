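# Shared fixtures and independent oracles for the test suite. Oracles are
# deliberately brute force (double loops, Riemann convolution, grid scans)
# and stay independent of the implementation paths they check.

default_config <- function(...) simulation_config(...)

# cache the default noiseless reference calibration (built once per run)
.fixture_env <- new.env()
fixture_calibration <- function() {
  if (is.null(.fixture_env$cal)) {
    cfg <- default_config()
    ref <- noiseless_reference(cfg)
    .fixture_env$cal <- calibrate_reference(ref)
    .fixture_env$cfg <- cfg
  }
  .fixture_env$cal
}
fixture_config <- function() {
  fixture_calibration()
  .fixture_env$cfg
}

# reference with expected (noise-free) counts
noiseless_reference <- function(cfg, photons = 1e7) {
  sh <- flimplate:::mixture_gate_shape(1, cfg$tau_ref_ps, cfg)
  reference_decay(sh * photons, cfg$gate_delays_ps, cfg$gate_width_ps,
                  cfg$tau_ref_ps)
}

# expected (noise-free) gated counts of a photon-fraction mixture
expected_counts <- function(fractions, lifetimes, cfg, photons) {
  flimplate:::mixture_gate_shape(fractions, lifetimes, cfg) * photons
}

# --- decay oracle: brute-force numerical convolution ------------------------
# Gaussian IRF convolved with a multi-exponential (photon-normalised) decay
# by direct Riemann summation on a fine grid; no closed forms shared with
# the implementation.
oracle_irf_conv <- function(t_grid, betas, taus, t0, sigma) {
  dt <- t_grid[2] - t_grid[1]
  irf <- exp(-0.5 * ((t_grid - t0) / sigma)^2)
  irf <- irf / sum(irf * dt)
  decay <- rep(0, length(t_grid))
  for (i in seq_along(betas))
    decay <- decay + betas[i] * exp(-t_grid / taus[i]) / taus[i]
  out <- numeric(length(t_grid))
  for (k in seq_along(t_grid)) {
    # int irf(s) decay(t_k - s) ds over s <= t_k
    s_idx <- seq_len(k)
    out[k] <- sum(irf[s_idx] * decay[k - s_idx + 1]) * dt
  }
  out
}

# --- segmentation oracles ---------------------------------------------------
oracle_tophat <- function(img, params) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  stat_fun <- function(v, s) switch(s, median = median(v), mean = mean(v),
                                    max = max(v))
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    close_v <- c(); dist_v <- c()
    for (dr in -params$outer_radius:params$outer_radius)
      for (dc in -params$outer_radius:params$outer_radius) {
        rr <- r + dr; cc <- c + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        d <- sqrt(dr^2 + dc^2)
        if (d <= params$inner_radius + 1e-9) {
          close_v <- c(close_v, img[rr, cc])
        } else if (d <= params$outer_radius + 1e-9) {
          dist_v <- c(dist_v, img[rr, cc])
        }
      }
    out[r, c] <- max(0, stat_fun(close_v, params$close_stat) -
                          stat_fun(dist_v, params$distant_stat))
  }
  out
}

oracle_erode <- function(mask, depth) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  d_int <- ceiling(depth)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!mask[r, c]) next
    keep <- TRUE
    for (dr in -d_int:d_int) for (dc in -d_int:d_int) {
      if (sqrt(dr^2 + dc^2) > depth + 1e-9) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc]) {
        keep <- FALSE; break
      }
    }
    out[r, c] <- keep
  }
  out
}

# profiled chi-square of a mono-exponential reconvolution fit, for grid scans
profiled_chi2 <- function(tau, counts, cal) {
  s <- cal$shapes$shape_fun(tau)[, 1]
  w <- 1 / pmax(counts, 1)
  A <- sum(w * counts * s) / sum(w * s^2)
  sum(w * (counts - A * s)^2)
}

# random blob mask: union of a few random discs, for membrane-mask oracles
random_blob <- function(nr, nc, n_discs = 3) {
  m <- matrix(FALSE, nr, nc)
  for (i in seq_len(n_discs)) {
    r0 <- runif(1, 6, nr - 5); c0 <- runif(1, 6, nc - 5)
    rad <- runif(1, 2, 5)
    m <- m | flimplate:::ellipse_mask(nr, nc, r0, c0, rad, rad)
  }
  m
}
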