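# Compartment codes used throughout the generator
COMP_BACKGROUND <- 0L
COMP_CYTOPLASM <- 1L
COMP_MEMBRANE <- 2L
COMP_DEBRIS <- 3L

#' Render a field of synthetic cells
#'
#' Places non-overlapping elliptical cells in a frame. Each cell consists of
#' a cytoplasm region enclosed by a closed membrane ring of the requested
#' width; the ring is the set difference between the filled ellipse and the
#' ellipse eroded by a disc of radius `membrane_width`. Optionally scatters
#' small bright "debris" discs on the background, emulating FRETing cell
#' debris shed by budding virus-like particles.
#'
#' Placement uses bounded rejection sampling; if the frame cannot hold the
#' requested number of cells the field is returned with fewer cells and its
#' `packed` flag set to `FALSE`.
#'
#' @param n_cells Number of cells to place.
#' @param frame_dim Frame height and width (pixels).
#' @param axes Mean ellipse semi-axes `c(major, minor)` in pixels.
#' @param axes_jitter Half-range of uniform jitter applied to each semi-axis.
#' @param membrane_width Membrane ring width (pixels).
#' @param n_debris Number of debris discs to scatter outside cells.
#' @param debris_radius Range `c(min, max)` of debris radii (pixels).
#' @param max_tries Placement attempts per cell before giving up.
#' @param seed Optional RNG seed (integer) for a reproducible field.
#'
#' @return An object of class `cell_field`: a list with `cells` (a tibble of
#'   centres, semi-axes and sizes), `cell_id` (integer matrix, 0 background),
#'   `compartment` (integer matrix: 0 background, 1 cytoplasm, 2 membrane,
#'   3 debris) and `packed` (logical).
#' @export
render_cell_field <- function(n_cells, frame_dim = c(64L, 64L),
                              axes = c(9, 7), axes_jitter = 1,
                              membrane_width = 3L,
                              n_debris = 0L, debris_radius = c(2L, 4L),
                              max_tries = 200L, seed = NULL) {
  stopifnot(n_cells >= 0, length(frame_dim) == 2, membrane_width >= 1)
  if (n_cells > 0 && (max(axes) + axes_jitter + 1) * 2 > min(frame_dim))
    abort("frame too small to hold a cell at the configured axes")
  with_seed_maybe(seed, {
    nr <- frame_dim[1]; nc <- frame_dim[2]
    cell_id <- matrix(0L, nr, nc)
    compartment <- matrix(COMP_BACKGROUND, nr, nc)
    cells <- list()
    placed <- 0L
    for (k in seq_len(n_cells)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        a <- axes[1] + stats::runif(1, -axes_jitter, axes_jitter)
        b <- axes[2] + stats::runif(1, -axes_jitter, axes_jitter)
        cr <- stats::runif(1, a + 2, nr - a - 1)
        cc <- stats::runif(1, b + 2, nc - b - 1)
        ell <- ellipse_mask(nr, nc, cr, cc, a, b)
        # keep a 1-px clearance between neighbouring cells
        if (any(cell_id[dilate_disc(ell, 1)] > 0L)) next
        ring <- ell & !erode_disc(ell, membrane_width)
        placed <- placed + 1L
        cell_id[ell] <- placed
        compartment[ell & !ring] <- COMP_CYTOPLASM
        compartment[ring] <- COMP_MEMBRANE
        cells[[placed]] <- tibble(
          cell = placed, center_row = cr, center_col = cc,
          semi_axis_row = a, semi_axis_col = b,
          membrane_width = as.integer(membrane_width),
          size_px = sum(ell), membrane_px = sum(ring))
        ok <- TRUE
        break
      }
      if (!ok) break
    }
    # debris: small bright discs strictly outside cells (with clearance)
    n_deb_placed <- 0L
    for (k in seq_len(n_debris)) {
      for (try in seq_len(max_tries)) {
        rad <- sample(seq(debris_radius[1], debris_radius[2]), 1)
        cr <- stats::runif(1, rad + 1, nr - rad)
        cc <- stats::runif(1, rad + 1, nc - rad)
        blob <- ellipse_mask(nr, nc, cr, cc, rad, rad)
        if (any(cell_id[dilate_disc(blob, 1)] > 0L) ||
            any(compartment[blob] == COMP_DEBRIS)) next
        compartment[blob] <- COMP_DEBRIS
        n_deb_placed <- n_deb_placed + 1L
        break
      }
    }
    cells_tbl <- if (placed) dplyr::bind_rows(cells) else tibble(
      cell = integer(), center_row = numeric(), center_col = numeric(),
      semi_axis_row = numeric(), semi_axis_col = numeric(),
      membrane_width = integer(), size_px = integer(), membrane_px = integer())
    if (placed < n_cells)
      warn(sprintf("placed %d of %d requested cells (frame too crowded)",
                   placed, n_cells))
    structure(list(cells = cells_tbl, cell_id = cell_id,
                   compartment = compartment,
                   n_debris = n_deb_placed,
                   packed = placed == n_cells),
              class = "cell_field")
  })
}

# filled ellipse (axis-aligned) as a logical matrix
ellipse_mask <- function(nr, nc, center_row, center_col, a, b) {
  rr <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ((rr - center_row) / a)^2 + ((cc - center_col) / b)^2 <= 1
}

#' @export
print.cell_field <- function(x, ...) {
  cat(sprintf("<cell_field> %d cells, %d debris blobs, %dx%d px%s\n",
              nrow(x$cells), x$n_debris, nrow(x$cell_id), ncol(x$cell_id),
              if (x$packed) "" else " (under-packed)"))
  invisible(x)
}

#' @export
#' @method tidy cell_field
tidy.cell_field <- function(x, ...) x$cells
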