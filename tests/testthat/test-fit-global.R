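make_biexp_decay <- function(beta1, n_photons, cfg, tau1 = 2950, tau2 = 750,
                             noisy = TRUE) {
  p <- amplitude_to_photon_fractions(c(1 - beta1, beta1), c(tau2, tau1))
  y <- expected_counts(p, c(tau2, tau1), cfg, n_photons)
  if (noisy) rpois(length(y), y) else y
}

test_that("single-component data give beta1 = 1 and an unidentifiable tau2", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  dec <- tibble::tibble(
    condition = c("a", "b"),
    counts = replicate(2, make_biexp_decay(1, 1e5, cfg, noisy = FALSE),
                       simplify = FALSE))
  g <- fit_global_binned(dec, cal, tau1_fixed = 2950)
  expect_true(g$tau2_unidentifiable)
  expect_true(all(abs(g$conditions$beta1 - 1) < 0.01))
})

test_that("tau2 and the population fractions are recovered", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(2)
  betas <- c(0.3, 0.5, 0.8)
  dec <- tibble::tibble(
    condition = letters[1:3],
    counts = lapply(betas, make_biexp_decay, n_photons = 3e5, cfg = cfg))
  g <- fit_global_binned(dec, cal, tau1_fixed = 2950)
  expect_lt(abs(g$tau2_ps - 750), 40)
  expect_true(all(abs(g$conditions$beta1 - betas) < 0.05))
  expect_equal(g$conditions$beta1 + g$conditions$beta2, rep(1, 3))
  expect_false(g$tau2_unidentifiable)
})

test_that("replicate rows yield a tau2 spread estimate", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(3)
  grid <- expand.grid(condition = c("a", "b"), replicate = 1:3,
                      stringsAsFactors = FALSE)
  grid$counts <- lapply(ifelse(grid$condition == "a", 0.3, 0.7),
                        make_biexp_decay, n_photons = 2e5, cfg = cfg)
  g <- fit_global_binned(tibble::as_tibble(grid), cal, tau1_fixed = 2950)
  expect_true(is.finite(g$tau2_sd_ps))
  expect_lt(g$tau2_sd_ps, 100)
})

test_that("beta1 rises monotonically along an inhibitor dose series", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  model <- dose_response_model(ec50 = 0.1, hill = 1, f_max = 0.8,
                               f_min = 0.05)
  doses <- 10^seq(-3, 1, length.out = 6)
  set.seed(4)
  dec <- tibble::tibble(
    condition = sprintf("d%02d", seq_along(doses)),
    counts = lapply(fret_fraction_at_dose(doses, model), function(f)
      make_biexp_decay(1 - f, 5e5, cfg)))
  g <- fit_global_binned(dec, cal, tau1_fixed = 2950)
  expect_true(all(diff(g$conditions$beta1) > 0))
})

test_that("input validation catches malformed series", {
  cal <- fixture_calibration()
  dec1 <- tibble::tibble(condition = "only", counts = list(rep(1, 16)))
  expect_error(fit_global_binned(dec1, cal, 2950), "2 conditions")
  dec2 <- tibble::tibble(condition = c("a", "b"),
                         counts = list(rep(1, 16), rep(1, 5)))
  expect_error(fit_global_binned(dec2, cal, 2950), "one count per gate")
})
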