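test_that("well aggregation identities", {
  # one FOV, one value: mean is the value, SD 0
  v1 <- tibble::tibble(well = "A1", fov = 1L, value = 2500)
  w1 <- well_aggregate(v1)
  expect_equal(w1$mean_tau, 2500)
  expect_equal(w1$sd_tau, 0)
  # equal FOV means: both methods agree
  v2 <- tibble::tibble(well = "A1", fov = rep(1:4, each = 3),
                       value = rep(c(2400, 2500, 2600), 4))
  expect_equal(well_aggregate(v2, "pixel_pooled")$mean_tau,
               well_aggregate(v2, "fov_mean")$mean_tau)
  # unequal FOV pixel counts: pooled mean equals count-weighted FOV means
  set.seed(61)
  v3 <- tibble::tibble(well = "B2",
                       fov = rep(1:3, times = c(5, 17, 44)),
                       value = rnorm(66, 2500, 100))
  pooled <- well_aggregate(v3, "pixel_pooled")$mean_tau
  per_fov <- tapply(v3$value, v3$fov, mean)
  n_fov <- tapply(v3$value, v3$fov, length)
  expect_equal(pooled, sum(per_fov * n_fov) / sum(n_fov))
  # all-NA well is flagged
  v4 <- tibble::tibble(well = "C3", fov = 1L, value = NA_real_)
  expect_true(well_aggregate(v4)$no_cells)
})

test_that("plate map covers the grid and mirrors the aggregates", {
  layout <- plate_layout_dose_response()
  wells <- tibble::tibble(
    well = c("A1", "B5"), mean_tau = c(2900, 2500),
    no_cells = FALSE)
  pm <- plate_map(wells, layout)
  expect_equal(nrow(pm), 96)
  expect_equal(pm$value[pm$well == "A1"], 2900)
  expect_equal(pm$value[pm$well == "B5"], 2500)
  expect_true(all(is.na(pm$value[pm$role == "excluded"])))
  expect_true(pm$missing[pm$well == "H8"])
  # empty input: everything missing
  pm0 <- plate_map(tibble::tibble(well = character(),
                                  mean_tau = numeric()), layout)
  expect_true(all(pm0$missing | pm0$excluded))
})

test_that("drift check recovers injected gradients", {
  layout <- plate_layout_dose_response()
  lay <- tibble::as_tibble(layout)
  dose_wells <- lay[lay$role == "dose" & lay$col == 5, ]
  # identical wells: zero slope
  flat <- tibble::tibble(well = dose_wells$well, mean_tau = 2500,
                         sd_tau = 0, n = 10, n_fovs = 1, no_cells = FALSE)
  dc <- drift_check(flat, layout, condition = "gag")
  expect_true(all(abs(dc$slopes$slope) < 1e-9))
  # injected linear gradient down the rows is recovered
  grad <- flat
  grad$mean_tau <- 2500 + 12 * dose_wells$row
  dcg <- drift_check(grad, layout, condition = "gag")
  s_row <- dcg$slopes$slope[dcg$slopes$direction == "column_wise"]
  expect_equal(s_row, 12, tolerance = 1e-9)
  # reversing the order negates the slope
  rev_grad <- grad
  rev_grad$mean_tau <- rev(grad$mean_tau)
  dcr <- drift_check(rev_grad, layout, condition = "gag")
  expect_equal(dcr$slopes$slope[dcr$slopes$direction == "column_wise"], -12,
               tolerance = 1e-9)
})

test_that("percent inhibition formula and invariances", {
  expect_equal(as.numeric(percent_inhibition(2530, 2530, 2930)), 0)
  expect_equal(as.numeric(percent_inhibition(2930, 2530, 2930)), 100)
  expect_equal(as.numeric(percent_inhibition(2826, 2530, 2930)), 74.0)
  # invariant under common shifts
  expect_equal(as.numeric(percent_inhibition(2826 + 55, 2530 + 55, 2930 + 55)),
               74.0)
  # out-of-range values are unclamped but flagged
  p <- percent_inhibition(3100, 2530, 2930)
  expect_gt(as.numeric(p), 100)
  expect_true(attr(p, "out_of_range"))
  expect_error(percent_inhibition(2700, 2600, 2600), "equals")
})

test_that("Z-prime closed forms and invariances", {
  # zero spread: perfect assay
  expect_error(z_prime(c(3000, 3000), c(3000, 3000)), "equal")
  z0 <- z_prime(c(3000, 3000, 3000), c(2500, 2500, 2500))
  expect_equal(z0$z_prime, 1)
  # textbook arithmetic: 1 - 3*(50+50)/500 = 0.4
  pos <- c(2950, 3050); neg <- c(2450, 2550)  # sd = 70.7 -> not 50
  pos <- 3000 + c(-1, 1) * 50 / sqrt(2)
  neg <- 2500 + c(-1, 1) * 50 / sqrt(2)
  z <- z_prime(pos, neg)
  expect_equal(z$sigma_pos, 50)
  expect_equal(z$z_prime, 0.4)
  # affine invariance: ps -> ns leaves Z-prime fixed
  z_ns <- z_prime(pos / 1000 + 3, neg / 1000 + 3)
  expect_equal(z_ns$z_prime, z$z_prime)
  # arm substitution is just passing another arm
  alt <- z_prime(pos, c(2601, 2649, 2650))
  expect_s3_class(alt, "assay_metrics")
  expect_error(z_prime(3000, neg), "at least 2")
})

test_that("dose-response table pools repeat wells and flags flat fits", {
  layout <- plate_layout_dose_response()
  lay <- tibble::as_tibble(layout)
  dose_lay <- lay[lay$role == "dose", ]
  set.seed(71)
  wells <- tibble::tibble(
    well = dose_lay$well,
    mean_tau = 1500 + 1300 / (1 + (0.1 / dose_lay$dose_uM)) +
      rnorm(nrow(dose_lay), 0, 10),
    no_cells = FALSE)
  tab <- dose_response_table(wells, layout, n_boot = 50, seed = 1)
  expect_equal(nrow(tab), 9)
  expect_true(all(diff(tab$mean) > -30))
  # table means equal direct pooled averages
  d5 <- dose_lay$dose_uM[dose_lay$col == 5][1]
  expect_equal(tab$mean[tab$dose_uM == d5],
               mean(wells$mean_tau[wells$well %in%
                                     dose_lay$well[dose_lay$dose_uM == d5]]))
  hf <- attr(tab, "hill_fit")
  expect_false(hf$unidentifiable)
  expect_equal(hf$ec50_uM, 0.1, tolerance = 0.3)
  # flat response: unidentifiable
  flat <- wells; flat$mean_tau <- 2500 + rnorm(nrow(flat), 0, 10)
  tf <- dose_response_table(flat, layout, n_boot = 0, seed = 1)
  expect_true(attr(tf, "hill_fit")$unidentifiable)
})
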