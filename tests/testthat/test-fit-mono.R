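test_that("noiseless decay is recovered to numerical tolerance", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  y <- expected_counts(1, 2500, cfg, 1e6)
  fit <- fit_monoexp(y, cal)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_ps - 2500), 1)
  expect_equal(fit$amplitude, 1e6, tolerance = 1e-3)
})

test_that("Poisson decay agrees with truth and with a grid-search oracle", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(5)
  y <- rpois(16, expected_counts(1, 2500, cfg, 1e4))
  fit <- fit_monoexp(y, cal)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau_ps - 2500), 3 * fit$se_tau_ps)
  # brute-force profiled chi-square scan over tau
  grid <- seq(2000, 3000, by = 2)
  chi <- vapply(grid, profiled_chi2, numeric(1), counts = y, cal = cal)
  expect_lt(abs(fit$tau_ps - grid[which.min(chi)]), 2)
  expect_lte(profiled_chi2(fit$tau_ps, y, cal), min(chi) + 1e-9)
})

test_that("degenerate decays are flagged not fitted", {
  cal <- fixture_calibration()
  fit <- fit_monoexp(rep(0, 16), cal)
  expect_false(fit$converged)
  expect_true(is.na(fit$tau_ps))
  expect_error(fit_monoexp(c(5, 3), cal), "at least 3 gates")
})

test_that("pixelwise fitting honours the photon threshold", {
  cfg <- default_config(frame_dim = c(8, 8))
  cal <- fixture_calibration()
  # two-pixel stack: threshold 0 fits both pixels
  counts2 <- array(0, c(16, 1, 2))
  y <- expected_counts(1, 2000, cfg, 150)
  counts2[, 1, 1] <- round(y); counts2[, 1, 2] <- round(y)
  st2 <- gated_stack(counts2, cfg$gate_delays_ps, cfg$gate_width_ps)
  li0 <- fit_pixelwise(st2, cal, threshold = 0)
  expect_equal(sum(is.finite(li0$tau_ps)), 2)
  # a 150-photon pixel is excluded at the default 200-photon threshold
  li200 <- fit_pixelwise(st2, cal, threshold = 200)
  expect_equal(sum(is.finite(li200$tau_ps)), 0)
  expect_true(li200$no_pixels)
  # all-zero stack: every pixel undefined
  st0 <- gated_stack(array(0, c(16, 4, 4)), cfg$gate_delays_ps,
                     cfg$gate_width_ps)
  li <- fit_pixelwise(st0, cal, threshold = 0)
  expect_true(all(!is.finite(li$tau_ps)))
})

test_that("pixelwise scatter follows the photon-counting precision law", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  sh <- expected_counts(1, 2500, cfg, 1)
  sd_at <- function(n_photons, n_pix = 400, seed) {
    set.seed(seed)
    counts <- array(rpois(16 * n_pix, rep(sh * n_photons, n_pix)),
                    c(16, 20, n_pix / 20))
    st <- gated_stack(counts, cfg$gate_delays_ps, cfg$gate_width_ps)
    li <- fit_pixelwise(st, cal, threshold = 0)
    sd(li$tau_ps, na.rm = TRUE)
  }
  s1 <- sd_at(2000, seed = 21)
  s4 <- sd_at(8000, seed = 22)
  # quadrupling the photons halves the lifetime scatter
  expect_equal(s1 / s4, 2, tolerance = 0.2)
})

test_that("pixelwise and single-decay fits agree", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(8)
  y <- rpois(16, expected_counts(1, 2200, cfg, 5000))
  counts <- array(y, c(16, 1, 1))
  st <- gated_stack(counts, cfg$gate_delays_ps, cfg$gate_width_ps)
  li <- fit_pixelwise(st, cal, threshold = 0)
  single <- fit_monoexp(y, cal)
  expect_equal(li$tau_ps[1, 1], single$tau_ps, tolerance = 1e-6)
})

test_that("ROI binning pools decays correctly", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(9)
  counts <- array(rpois(16 * 16, rep(expected_counts(1, 2500, cfg, 2000), 16)),
                  c(16, 4, 4))
  st <- gated_stack(counts, cfg$gate_delays_ps, cfg$gate_width_ps)
  # ROI of one pixel equals that pixel's fit
  roi1 <- matrix(FALSE, 4, 4); roi1[2, 3] <- TRUE
  f_roi <- fit_roi_binned(st, cal, roi1)
  f_pix <- fit_monoexp(counts[, 2, 3], cal)
  expect_equal(f_roi$tau_ps, f_pix$tau_ps)
  # two disjoint ROIs holding identical decays give identical lifetimes
  counts_eq <- counts
  counts_eq[, 3, ] <- counts_eq[, 1, ]
  counts_eq[, 4, ] <- counts_eq[, 2, ]
  st_eq <- gated_stack(counts_eq, cfg$gate_delays_ps, cfg$gate_width_ps)
  roi_a <- matrix(FALSE, 4, 4); roi_a[1:2, ] <- TRUE
  roi_b <- matrix(FALSE, 4, 4); roi_b[3:4, ] <- TRUE
  expect_equal(fit_roi_binned(st_eq, cal, roi_a)$tau_ps,
               fit_roi_binned(st_eq, cal, roi_b)$tau_ps)
  # empty ROI errors
  expect_error(fit_roi_binned(st, cal, matrix(FALSE, 4, 4)), "empty")
})

test_that("a 50/50 two-lifetime ROI fits strictly between the lifetimes", {
  cfg <- fixture_config()
  cal <- fixture_calibration()
  set.seed(10)
  n_half <- 8
  y_f <- rpois(16 * n_half, rep(expected_counts(1, 766, cfg, 1500), n_half))
  y_d <- rpois(16 * n_half, rep(expected_counts(1, 2950, cfg, 1500), n_half))
  counts <- array(c(y_f, y_d), c(16, 4, 4))
  st <- gated_stack(counts, cfg$gate_delays_ps, cfg$gate_width_ps)
  roi <- matrix(TRUE, 4, 4)
  fit <- fit_roi_binned(st, cal, roi)
  expect_gt(fit$tau_ps, 766)
  expect_lt(fit$tau_ps, 2950)
  # matches a grid search on the pooled decay
  pooled <- apply(matrix(counts, nrow = 16), 1, sum)
  grid <- seq(900, 2500, by = 2)
  chi <- vapply(grid, profiled_chi2, numeric(1), counts = pooled, cal = cal)
  expect_lt(abs(fit$tau_ps - grid[which.min(chi)]), 2)
  # invariant under pixel permutation inside the ROI
  set.seed(11)
  perm <- sample(16)
  counts_p <- array(matrix(counts, nrow = 16)[, perm], c(16, 4, 4))
  st_p <- gated_stack(counts_p, cfg$gate_delays_ps, cfg$gate_width_ps)
  expect_equal(fit_roi_binned(st_p, cal, roi)$tau_ps, fit$tau_ps)
})
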