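#' Default region-of-interest template
#'
#' A deterministic geometric stand-in for the manually drawn ROIs: the
#' hypothalamus as a 70-voxel rectangle, the hippocampus as two 30-voxel
#' squares, the nucleus accumbens (NAc) as two 40-voxel ovals, and the
#' infralimbic area (ILA) as a 20-voxel circle. Component centres are
#' stored as fractions of the image matrix so the template scales with
#' geometry while the voxel counts stay exact.
#'
#' @return an object of class `mpmri_roi_template`: a list with a
#'   `components` data frame (region, shape, n_voxels, centre fractions,
#'   shape parameters, slice) and the region label codes used in masks.
#' @export
roi_template <- function() {
  components <- data.frame(
    region   = c("hypothalamus", "hippocampus", "hippocampus",
                 "nac", "nac", "ila"),
    shape    = c("rect", "rect", "rect", "oval", "oval", "circle"),
    n_voxels = c(70L, 30L, 30L, 40L, 40L, 20L),
    # rect height x width in voxels (ignored for oval/circle)
    height   = c(7L, 5L, 5L, NA, NA, NA),
    width    = c(10L, 6L, 6L, NA, NA, NA),
    # oval row/col semi-axis ratio (row:col)
    aspect   = c(NA, NA, NA, 0.7, 0.7, 1),
    row_frac = c(0.66, 0.40, 0.40, 0.56, 0.56, 0.30),
    col_frac = c(0.50, 0.33, 0.67, 0.36, 0.64, 0.50),
    slice    = c(1L, 1L, 1L, 2L, 2L, 2L),
    stringsAsFactors = FALSE
  )
  structure(
    list(components = components,
         region_codes = c(other_brain = 1L, csf = 2L, hypothalamus = 3L,
                          hippocampus = 4L, nac = 5L, ila = 6L)),
    class = "mpmri_roi_template")
}

# exact-count shape rasterisers ------------------------------------------

rect_voxels <- function(center, height, width, dim) {
  r0 <- round(center[1] - (height - 1) / 2)
  c0 <- round(center[2] - (width - 1) / 2)
  rows <- r0:(r0 + height - 1)
  cols <- c0:(c0 + width - 1)
  if (min(rows) < 1 || max(rows) > dim[1] || min(cols) < 1 || max(cols) > dim[2])
    return(NULL)
  as.matrix(expand.grid(row = rows, col = cols))
}

# n voxels nearest (in aspect-scaled distance) to the centre: realises
# circles/ovals with an exact voxel count, deterministic tie-break
round_voxels <- function(center, n, aspect, dim) {
  half <- ceiling(sqrt(n)) + 2
  rows <- (round(center[1]) - half):(round(center[1]) + half)
  cols <- (round(center[2]) - half):(round(center[2]) + half)
  if (min(rows) < 1 || max(rows) > dim[1] || min(cols) < 1 || max(cols) > dim[2])
    return(NULL)
  g <- expand.grid(row = rows, col = cols)
  d <- ((g$row - center[1]) / aspect)^2 + (g$col - center[2])^2
  ord <- order(d, g$row, g$col)
  as.matrix(g[ord[seq_len(n)], c("row", "col")])
}

#' Rasterise the ROI template into an integer label mask
#'
#' @param template an [roi_template()] object.
#' @param geometry list with at least `matrix` (image side in voxels), or a
#'   single integer.
#' @return integer matrix of region label codes (0 where no ROI), with the
#'   code map in `attr(, "region_codes")`. Component voxel counts are
#'   guaranteed to equal the template exactly and masks to be pairwise
#'   disjoint; too-small geometries raise an error.
#' @examples
#' m <- make_roi_masks(roi_template(), list(matrix = 128))
#' sum(m == attr(m, "region_codes")[["hypothalamus"]])  # 70
#' @export
make_roi_masks <- function(template = roi_template(), geometry = list(matrix = 128L)) {
  if (is.numeric(geometry)) geometry <- list(matrix = as.integer(geometry))
  n <- as.integer(geometry$matrix)
  if (length(n) != 1 || is.na(n) || n <= 0) stop("geometry must give a positive matrix size")
  dim <- c(n, n)
  mask <- matrix(0L, n, n)
  codes <- template$region_codes
  for (i in seq_len(nrow(template$components))) {
    comp <- template$components[i, ]
    center <- c(comp$row_frac * n, comp$col_frac * n)
    vox <- switch(comp$shape,
      rect   = rect_voxels(center, comp$height, comp$width, dim),
      oval   = round_voxels(center, comp$n_voxels, comp$aspect, dim),
      circle = round_voxels(center, comp$n_voxels, comp$aspect, dim),
      stop("unknown shape: ", comp$shape))
    if (is.null(vox))
      stop("geometry too small: ", comp$region, " does not fit in a ",
           n, "x", n, " matrix")
    idx <- vox[, "row"] + (vox[, "col"] - 1L) * n
    if (any(mask[idx] != 0L))
      stop("geometry too small: ", comp$region, " overlaps another region")
    if (nrow(vox) != comp$n_voxels)
      stop("internal error: realised voxel count differs from template")
    mask[idx] <- codes[[comp$region]]
  }
  attr(mask, "region_codes") <- codes
  mask
}
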