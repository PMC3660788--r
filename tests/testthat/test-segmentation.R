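small_params <- function(...) {
  segmentation_params(inner_radius = 2, outer_radius = 5,
                      threshold = 5, min_object_size = 4,
                      erosion_depth = 1, smoothing_radius = 0, ...)
}

test_that("top-hat of a constant image is zero everywhere", {
  p <- small_params()
  img <- matrix(7, 16, 16)
  expect_true(all(tophat_transform(img, p) == 0))
})

test_that("an isolated bright disc scores positive at its centre only", {
  p <- small_params()
  img <- matrix(0, 21, 21)
  img[flimplate:::ellipse_mask(21, 21, 11, 11, 1.5, 1.5)] <- 10
  th <- tophat_transform(img, p)
  expect_gt(th[11, 11], 0)
  expect_equal(th[2, 2], 0)
  expect_equal(th[20, 20], 0)
})

test_that("top-hat equals the brute-force neighbourhood oracle", {
  set.seed(31)
  img <- matrix(runif(16 * 16, 0, 100), 16, 16)
  for (stats in list(c("median", "median"), c("median", "max"),
                     c("mean", "mean"))) {
    p <- small_params(close_stat = stats[1], distant_stat = stats[2])
    expect_equal(tophat_transform(img, p), oracle_tophat(img, p),
                 tolerance = 1e-12)
  }
})

test_that("top-hat is invariant under additive constants", {
  set.seed(32)
  img <- matrix(runif(100, 0, 50), 10, 10)
  p <- small_params()
  expect_equal(tophat_transform(img + 17, p), tophat_transform(img, p),
               tolerance = 1e-9)
})

test_that("blank images give an empty result with the no-cells flag", {
  seg <- segment_cells(matrix(0, 32, 32), small_params())
  expect_true(seg$no_cells)
  expect_equal(length(seg$cell_masks), 0)
})

test_that("two separated synthetic cells are found with ring membranes", {
  cfg <- default_config()
  f <- render_cell_field(2, c(64, 64), seed = 41)
  mix <- flimplate:::well_mixtures(0.5, cfg)
  st <- simulate_gated_stack(f, mix, cfg, seed = 42)
  seg <- segment_cells(intensity_image(st), segmentation_params())
  expect_equal(length(seg$cell_masks), 2)
  for (j in 1:2) {
    ring <- seg$membrane_masks[[j]]
    expect_identical(ring, seg$cell_masks[[j]] &
                       !oracle_erode(seg$cell_masks[[j]], 3))
    # the ring is closed: the eroded interior is enclosed by it
    interior <- seg$cell_masks[[j]] & !ring
    expect_true(all(ring[flimplate:::dilate_disc(interior, 1) & !interior]))
  }
  # segmentation recovers the true cells: each found mask overlaps exactly
  # one ground-truth cell
  for (j in 1:2)
    expect_equal(length(setdiff(unique(f$cell_id[seg$cell_masks[[j]]]), 0L)),
                 1L)
})

test_that("the size sieve boundary is exact", {
  p <- segmentation_params(inner_radius = 2, outer_radius = 5, threshold = 5,
                           min_object_size = 9, erosion_depth = 1,
                           smoothing_radius = 0)
  img <- matrix(0, 24, 24)
  img[3:5, 3:5] <- 100      # 3x3 = 9 px, kept
  img[15:17, 15:16] <- 100  # 3x2 = 6 px bright; score region smaller
  seg <- segment_cells(img, p)
  sizes <- sort(seg$object_sizes)
  expect_true(all(sizes >= 9))
  # shrink the sieve by one and the smaller object appears
  p8 <- segmentation_params(inner_radius = 2, outer_radius = 5, threshold = 5,
                            min_object_size = 8, erosion_depth = 1,
                            smoothing_radius = 0)
  seg8 <- segment_cells(img, p8)
  expect_gte(length(seg8$cell_masks), length(seg$cell_masks))
})

test_that("membrane_mask edge cases and counting oracle", {
  sq <- matrix(FALSE, 15, 15); sq[3:13, 3:13] <- TRUE
  expect_true(all(membrane_mask(sq, 0) == FALSE))
  # depth at least the object radius returns the whole object
  expect_identical(membrane_mask(sq, 8), sq)
  # filled 11x11 square, depth 2: a 2-px frame of 11^2 - 7^2 = 72 pixels
  ring <- membrane_mask(sq, 2)
  expect_equal(sum(ring), 72)
  expect_identical(ring, sq & !oracle_erode(sq, 2))
})

test_that("membrane masks equal the set-difference oracle on random blobs", {
  set.seed(55)
  for (i in 1:8) {
    m <- random_blob(24, 24)
    depth <- sample(1:3, 1)
    expect_identical(membrane_mask(m, depth), m & !oracle_erode(m, depth))
  }
})

test_that("labelling is deterministic and 8-connected", {
  m <- matrix(FALSE, 6, 6)
  m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal touch: one component
  lab <- flimplate:::label_components(m)
  expect_equal(max(lab), 1L)
  m[5, 5] <- TRUE                    # separate component
  lab2 <- flimplate:::label_components(m)
  expect_equal(max(lab2), 2L)
  expect_identical(lab2, flimplate:::label_components(m))
})

test_that("parameter validation rejects bad radii", {
  expect_error(segmentation_params(inner_radius = 5, outer_radius = 4),
               "outer_radius")
  expect_error(segmentation_params(erosion_depth = 0), "erosion_depth")
  expect_error(segmentation_params(close_stat = "mode"), "statistics")
})
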