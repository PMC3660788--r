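test_that("zero photon budget yields an all-zero stack", {
  cfg <- default_config(frame_dim = c(8, 8))
  labels <- matrix(2L, 8, 8)
  mix <- list(membrane = decay_mixture(1, 2500, 0))
  st <- simulate_gated_stack(labels, mix, cfg, seed = 1)
  expect_true(all(st$counts == 0))
})

test_that("delta-like IRF gives gate counts proportional to exp(-t_k/tau)", {
  # narrow IRF well before the gates: the gate integral of an exponential is
  # proportional to exp(-delay/tau)
  cfg <- default_config(gate_delays_ps = seq(1000, 8000, length.out = 8),
                        gate_width_ps = 400, irf_fwhm_ps = 1e-2,
                        irf_center_ps = 0)
  tau <- 1800
  sh <- flimplate:::mixture_gate_shape(1, tau, cfg)
  expected <- exp(-cfg$gate_delays_ps / tau)
  expect_equal(sh / sh[1], expected / expected[1], tolerance = 1e-6)
})

test_that("Poisson means match the analytic expectation", {
  cfg <- default_config(frame_dim = c(8, 8))
  labels <- matrix(2L, 8, 8)
  mix <- list(membrane = decay_mixture(1, 2500, 500))
  exp_stack <- flimplate:::expected_stack(labels, mix, cfg)
  # 1000 realisations per gate via the 64 iid pixels and repeated draws
  sums <- array(0, dim(exp_stack))
  n_rep <- 16 # 16 x 64 pixels = 1024 realisations per gate
  for (r in seq_len(n_rep)) {
    st <- simulate_gated_stack(labels, mix, cfg, seed = 100 + r)
    sums <- sums + st$counts
  }
  n_real <- n_rep * 64
  for (g in seq_len(dim(exp_stack)[1])) {
    mu <- exp_stack[g, 1, 1]
    est <- sum(sums[g, , ]) / n_real
    se <- sqrt(mu / n_real)
    expect_lt(abs(est - mu), 3 * se + 1e-9)
  }
})

test_that("photon conservation: expected counts sum to the budget", {
  cfg <- default_config()
  labels <- matrix(2L, 4, 4)
  mix <- list(membrane = decay_mixture(c(0.3, 0.7), c(766, 2950), 1234))
  exp_stack <- flimplate:::expected_stack(labels, mix, cfg)
  expect_equal(sum(exp_stack[, 1, 1]), 1234, tolerance = 1e-9)
})

test_that("mixture fractions must sum to one", {
  expect_error(decay_mixture(c(0.5, 0.4), c(766, 2950), 100), "sum to 1")
  expect_error(decay_mixture(c(0.5, 0.5), c(-766, 2950), 100), "lifetimes")
})

test_that("reference decay has the right tail slope and delta limit", {
  cfg <- default_config()
  ref <- simulate_reference(cfg, seed = 1, photons = 1e8)
  # late gates: log-counts vs delay linear with slope -1/tau_ref; with
  # tau_ref = 50 ps the decay dies immediately, so use a slower dye
  cfg2 <- default_config(tau_ref_ps = 1500)
  ref2 <- simulate_reference(cfg2, seed = 1, photons = 1e8)
  late <- 9:16
  fit <- lm(log(ref2$counts[late]) ~ cfg2$gate_delays_ps[late])
  expect_equal(-1 / coef(fit)[[2]], 1500, tolerance = 0.01)

  # tau_ref much smaller than the gate spacing: shape approaches the
  # gate-integrated IRF
  cfg3 <- default_config(tau_ref_ps = 1)
  sh3 <- flimplate:::mixture_gate_shape(1, cfg3$tau_ref_ps, cfg3)
  sigma <- cfg3$irf_fwhm_ps / (2 * sqrt(2 * log(2)))
  gates_irf <- vapply(cfg3$gate_delays_ps, function(d) {
    tg <- seq(d, d + cfg3$gate_width_ps, by = 2)
    v <- exp(-0.5 * ((tg - cfg3$irf_center_ps) / sigma)^2)
    sum((v[-1] + v[-length(v)]) / 2) * 2
  }, numeric(1))
  gates_irf <- gates_irf / sum(gates_irf)
  expect_equal(sh3, gates_irf, tolerance = 0.02)

  # determinism under a fixed seed
  expect_identical(simulate_reference(cfg, seed = 9)$counts,
                   simulate_reference(cfg, seed = 9)$counts)
})

test_that("effective lifetime of any mixture lies between tau_F and tau_D", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(42)
  for (f in runif(5)) {
    p <- amplitude_to_photon_fractions(c(f, 1 - f), c(766, 2950))
    y <- expected_counts(p, c(766, 2950), cfg, 1e6)
    fit <- fit_monoexp(y, cal)
    expect_gte(fit$tau_ps, 766 - 1)
    expect_lte(fit$tau_ps, 2950 + 1)
  }
})

test_that("identical seeds give bit-identical stacks", {
  cfg <- default_config(frame_dim = c(16, 16))
  f <- render_cell_field(1, c(16, 16), axes = c(5, 4), axes_jitter = 0.5,
                         seed = 2)
  mix <- flimplate:::well_mixtures(0.5, cfg)
  s1 <- simulate_gated_stack(f, mix, cfg, seed = 33)
  s2 <- simulate_gated_stack(f, mix, cfg, seed = 33)
  expect_identical(s1$counts, s2$counts)
})
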