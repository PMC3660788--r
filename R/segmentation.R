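#' Segmentation parameters
#'
#' Parameters of the size-tuned nonlinear top-hat segmentation. The top-hat
#' enhances a pixel when a rank statistic of its close vicinity (a disc of
#' radius `inner_radius`) exceeds a rank statistic of its distant vicinity
#' (the annulus between `inner_radius` and `outer_radius`); the statistics
#' are configurable. The default pair (median, median) requires an object to
#' fill at least half of the close disc — suppressing small bright debris —
#' while tolerating up to half of the annulus being occupied by the cell's
#' own or a neighbour's pixels. A `distant_stat = "max"` variant suppresses
#' any pixel with a bright distant neighbour and is stricter.
#'
#' @param inner_radius Close-vicinity disc radius (px), >= 1.
#' @param outer_radius Distant-vicinity outer radius (px), > `inner_radius`.
#' @param threshold Intensity threshold applied to the transformed image.
#' @param min_object_size Minimum object size (px) kept by the size sieve.
#' @param erosion_depth Erosion depth (px) used for the membrane mask
#'   (the width of the cell membrane).
#' @param smoothing_radius Disc radius for binary closing-then-opening.
#' @param close_stat,distant_stat Statistic over each neighbourhood:
#'   `"median"`, `"mean"` or `"max"`.
#'
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(inner_radius = 5, outer_radius = 12,
                                threshold = 100, min_object_size = 100,
                                erosion_depth = 3, smoothing_radius = 1,
                                close_stat = "median",
                                distant_stat = "median") {
  if (inner_radius < 1) abort("`inner_radius` must be >= 1")
  if (outer_radius <= inner_radius)
    abort("`outer_radius` must exceed `inner_radius`")
  if (erosion_depth < 1) abort("`erosion_depth` must be >= 1")
  if (min_object_size < 1) abort("`min_object_size` must be >= 1")
  stat_names <- c("median", "mean", "max")
  if (!close_stat %in% stat_names || !distant_stat %in% stat_names)
    abort("statistics must be one of: median, mean, max")
  structure(list(inner_radius = inner_radius, outer_radius = outer_radius,
                 threshold = threshold, min_object_size = min_object_size,
                 erosion_depth = erosion_depth,
                 smoothing_radius = smoothing_radius,
                 close_stat = close_stat, distant_stat = distant_stat),
            class = "segmentation_params")
}

# value matrix of a pixel neighbourhood: one row per pixel, one column per
# offset, NA where the offset falls outside the image (clipped borders)
neighbourhood_values <- function(img, offsets) {
  nr <- nrow(img); nc <- ncol(img); n <- nr * nc
  out <- matrix(NA_real_, n, nrow(offsets))
  for (i in seq_len(nrow(offsets)))
    out[, i] <- shift_matrix(img, -offsets$dr[i], -offsets$dc[i], NA_real_)
  out
}

stat_over <- function(vals, stat) {
  switch(stat,
    median = apply(vals, 1, median, na.rm = TRUE),
    mean = rowMeans(vals, na.rm = TRUE),
    max = {
      v <- vals
      v[is.na(v)] <- -Inf
      do.call(pmax, as.data.frame(v))
    })
}

#' Size-tuned nonlinear top-hat transform
#'
#' Transforms an intensity image pixel by pixel, enhancing pixels whose
#' close vicinity is bright while their distant vicinity is dim:
#' `score = max(0, stat_close(disc) - stat_distant(annulus))`, with the
#' neighbourhoods clipped at the image borders. The transform is invariant
#' under adding a constant to the whole image.
#'
#' @param img Numeric matrix, finite and non-negative.
#' @param params A [segmentation_params()].
#' @return Numeric matrix of the same shape.
#' @export
tophat_transform <- function(img, params) {
  stopifnot(is.matrix(img), inherits(params, "segmentation_params"))
  if (any(!is.finite(img)) || any(img < 0))
    abort("image must be finite and non-negative")
  off_in <- disc_offsets(params$inner_radius)
  off_all <- disc_offsets(params$outer_radius)
  key <- function(o) paste(o$dr, o$dc)
  off_out <- off_all[!(key(off_all) %in% key(off_in)), , drop = FALSE]
  close_v <- stat_over(neighbourhood_values(img, off_in), params$close_stat)
  dist_v <- stat_over(neighbourhood_values(img, off_out), params$distant_stat)
  matrix(pmax(close_v - dist_v, 0), nrow(img), ncol(img))
}

#' Segment cells and derive membrane masks
#'
#' Full segmentation pipeline: top-hat transform, binarisation at the
#' threshold, morphological smoothing (closing then opening with a disc of
#' `smoothing_radius`), 8-connected component labelling, a size sieve
#' removing objects below `min_object_size`, and per-object membrane masks
#' computed as the exact set difference between the cell mask and its
#' erosion by `erosion_depth` pixels.
#'
#' @param img Intensity image (matrix), typically [intensity_image()] of a
#'   gated stack.
#' @param params A [segmentation_params()].
#'
#' @return An object of class `segmentation_result`: `labels` (integer
#'   matrix, 0 background), `cell_masks` and `membrane_masks` (lists of
#'   logical matrices per retained object), `object_sizes`, `no_cells`
#'   (flag set when nothing survives), `params`.
#' @export
segment_cells <- function(img, params = segmentation_params()) {
  stopifnot(is.matrix(img), inherits(params, "segmentation_params"))
  score <- tophat_transform(img, params)
  binary <- score >= params$threshold
  if (params$smoothing_radius > 0)
    binary <- open_disc(close_disc(binary, params$smoothing_radius),
                        params$smoothing_radius)
  labels0 <- label_components(binary)
  sizes0 <- tabulate(labels0[labels0 > 0])
  keep <- which(sizes0 >= params$min_object_size)
  labels <- matrix(0L, nrow(img), ncol(img))
  cell_masks <- list(); membrane_masks <- list()
  for (j in seq_along(keep)) {
    m <- labels0 == keep[j]
    labels[m] <- j
    cell_masks[[j]] <- m
    membrane_masks[[j]] <- membrane_mask(m, params$erosion_depth)
  }
  structure(list(labels = labels, cell_masks = cell_masks,
                 membrane_masks = membrane_masks,
                 object_sizes = if (length(keep)) sizes0[keep] else integer(),
                 no_cells = length(keep) == 0,
                 params = params),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("<segmentation_result> %d object(s)%s\n",
              length(x$cell_masks),
              if (x$no_cells) " [no cells found]" else ""))
  invisible(x)
}

#' @export
#' @method tidy segmentation_result
tidy.segmentation_result <- function(x, ...) {
  if (x$no_cells)
    return(tibble(label = integer(), size_px = integer(),
                  membrane_px = integer(),
                  centroid_row = numeric(), centroid_col = numeric()))
  purrr::map_dfr(seq_along(x$cell_masks), function(j) {
    idx <- which(x$cell_masks[[j]], arr.ind = TRUE)
    tibble(label = j, size_px = nrow(idx),
           membrane_px = sum(x$membrane_masks[[j]]),
           centroid_row = mean(idx[, 1]), centroid_col = mean(idx[, 2]))
  })
}
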