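# build a finely sampled synthetic reference (Gaussian IRF x short dye) for
# grid-level checks of the reconvolution identity
fine_reference <- function(tau_ref = 50, t0 = 500, sigma = 64, dt = 2,
                           t_max = 9000) {
  t <- seq(0, t_max, by = dt)
  r <- oracle_irf_conv(t, 1, tau_ref, t0, sigma)
  reference_decay(r, t, dt, tau_ref)
}

test_that("component at tau_ref reproduces the reference itself", {
  ref <- fine_reference()
  pred <- reconvolved_model(list(beta = 1, tau_ps = ref$tau_ref_ps), 2, ref)
  expect_equal(pred, 2 * ref$tau_ref_ps * ref$counts, tolerance = 1e-12)
})

test_that("delta-like reference gives gate-sampled exponentials", {
  # tau_ref -> 0 with a near-delta reference curve: prediction proportional
  # to exp(-t/tau) away from the spike
  t <- seq(0, 8000, by = 2)
  r <- dnorm(t, 300, 10)
  ref <- reference_decay(r, t, 2, tau_ref_ps = 1e-3)
  pred <- reconvolved_model(list(beta = 1, tau_ps = 2000), 1, ref)
  idx <- t > 600
  expected <- exp(-(t[idx] - 300) / 2000)
  ratio <- pred[idx] / expected
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-3)
})

test_that("predictions match the brute-force convolution oracle", {
  ref <- fine_reference()
  t <- ref$gate_delays_ps
  set.seed(7)
  for (i in 1:4) {
    k <- sample(1:3, 1)
    beta <- diff(sort(c(0, runif(k - 1), 1)))
    taus <- runif(k, 400, 4000)
    pred <- reconvolved_model(data.frame(beta = beta, tau_ps = taus), 1, ref)
    # oracle: direct numerical convolution of the explicit IRF with the
    # amplitude-weighted decay (photon-normalised components removed)
    oracle <- oracle_irf_conv(t, beta * taus / sum(beta * taus), taus, 500, 64)
    idx <- oracle > max(oracle) * 1e-3
    scale <- sum(pred[idx] * oracle[idx]) / sum(oracle[idx]^2)
    rel <- abs(pred[idx] - scale * oracle[idx]) / (scale * oracle[idx])
    expect_lt(max(rel), 1e-3)
  }
})

test_that("invalid components are rejected and tau = tau_ref is benign", {
  ref <- fine_reference()
  expect_error(reconvolved_model(list(beta = 1, tau_ps = -5), 1, ref),
               "lifetimes")
  expect_error(reconvolved_model(list(beta = 0.7, tau_ps = 2000), 1, ref),
               "sum to 1")
  expect_silent(reconvolved_model(list(beta = 1, tau_ps = ref$tau_ref_ps),
                                  1, ref))
})

test_that("calibration recovers the instrument response parameters", {
  cfg <- default_config()
  cal <- fixture_calibration()
  sigma_true <- cfg$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  expect_equal(cal$t0_ps, cfg$irf_center_ps, tolerance = 0.01)
  expect_equal(cal$sigma_ps, sigma_true, tolerance = 0.02)
})
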