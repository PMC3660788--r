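# Binary morphology on logical matrices with a disc structuring element.
# Pixels outside the image are treated as background; neighbourhood offsets
# are the exact set {(dr, dc) : sqrt(dr^2 + dc^2) <= r}.

disc_offsets <- function(r) {
  r_int <- as.integer(ceiling(r))
  g <- expand.grid(dr = -r_int:r_int, dc = -r_int:r_int)
  g[sqrt(g$dr^2 + g$dc^2) <= r + 1e-9, , drop = FALSE]
}

# shift a matrix by (dr, dc), filling vacated cells with `fill`
shift_matrix <- function(m, dr, dc, fill) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  sr <- max(1, 1 + dr):min(nr, nr + dr)
  sc <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(sr) && length(sc))
    out[sr, sc] <- m[sr - dr, sc - dc, drop = FALSE]
  out
}

erode_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- disc_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out & shift_matrix(mask, off$dr[i], off$dc[i], FALSE)
  out
}

dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  off <- disc_offsets(r)
  out <- mask
  for (i in seq_len(nrow(off)))
    out <- out | shift_matrix(mask, off$dr[i], off$dc[i], FALSE)
  out
}

close_disc <- function(mask, r) erode_disc(dilate_disc(mask, r), r)
open_disc <- function(mask, r) dilate_disc(erode_disc(mask, r), r)

# 8-connected component labelling; returns an integer matrix, 0 = background,
# components numbered in raster-scan order of their first pixel.
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  nxt <- 0L
  stack <- integer(length(idx))
  for (start in idx) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nxt
    while (top > 0L) {
      p <- stack[top]; top <- top - 1L
      r0 <- (p - 1L) %% nr + 1L
      c0 <- (p - 1L) %/% nr + 1L
      for (dc in -1:1) {
        cc <- c0 + dc
        if (cc < 1L || cc > nc) next
        base <- (cc - 1L) * nr
        for (dr in -1:1) {
          rr <- r0 + dr
          if (rr < 1L || rr > nr) next
          q <- base + rr
          if (mask[q] && lab[q] == 0L) {
            lab[q] <- nxt
            top <- top + 1L
            if (top > length(stack)) stack <- c(stack, integer(length(stack)))
            stack[top] <- q
          }
        }
      }
    }
  }
  lab
}

#' Membrane mask of a cell by morphological erosion
#'
#' The membrane-only mask is the exact set difference between a binary cell
#' mask and the same mask eroded by a disc of radius `erosion_depth` (the
#' width of the cell membrane in pixels): `mask & !erode(mask, depth)`.
#'
#' @param mask Logical matrix (a single cell's binary mask).
#' @param erosion_depth Erosion depth in pixels; 0 gives an empty mask and a
#'   depth at least the object's radius returns the whole object.
#'
#' @return Logical matrix of the same shape.
#' @export
membrane_mask <- function(mask, erosion_depth) {
  stopifnot(is.matrix(mask), erosion_depth >= 0)
  mask <- mask != 0
  mask & !erode_disc(mask, erosion_depth)
}
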