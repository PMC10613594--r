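#' Rasterize a contour stack onto a grid
#'
#' A voxel belongs to the structure iff its center lies inside the polygon of
#' the nearest-z contour slice (even-odd rule). No inter-slice interpolation
#' of contours is performed; a slice represents half a `slice_thickness`
#' either side of its z position, so the stack has finite longitudinal
#' extent. Structures extending beyond the grid are silently truncated with a
#' warning.
#'
#' @param set A [structure_set()].
#' @param name Structure name to rasterize.
#' @param grid Target [grid_spec()].
#' @return Object of class `binary_mask`: `list(grid =, values =)` with
#'   `values` a logical `nx x ny x nz` array.
#' @export
rasterize_structure <- function(set, name, grid) {
  slices <- get_structure(set, name)
  ax <- grid_axes(grid)
  vals <- array(FALSE, dim = grid$shape)
  if (length(slices) == 0L) {
    warning(sprintf("structure '%s' is empty; returning all-false mask", name), call. = FALSE)
    return(structure(list(grid = grid, values = vals), class = "binary_mask"))
  }
  zs <- vapply(slices, function(s) s$z, numeric(1))
  half <- set$slice_thickness / 2 + 1e-9
  bbox <- structure_bbox(set, name)
  gmin <- grid$origin - grid$spacing / 2
  gmax <- grid$origin + (grid$shape - 0.5) * grid$spacing
  if (any(bbox["min", ] < gmin - 1e-9) || any(bbox["max", ] > gmax + 1e-9)) {
    warning(sprintf("structure '%s' extends beyond the grid; mask is truncated", name),
            call. = FALSE)
  }
  px <- rep(ax$x, times = grid$shape[2])
  py <- rep(ax$y, each = grid$shape[1])
  for (k in seq_len(grid$shape[3])) {
    zc <- ax$z[k]
    i <- which.min(abs(zs - zc))
    if (abs(zs[i] - zc) > half) next
    v <- slices[[i]]$vertices
    vals[, , k] <- points_in_polygon(px, py, v[, 1], v[, 2])
  }
  if (!any(vals)) {
    warning(sprintf("structure '%s' rasterizes to an empty mask on this grid", name),
            call. = FALSE)
  }
  structure(list(grid = grid, values = vals), class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d / %d voxels set (%.3f cm^3)\n",
              sum(x$values), length(x$values), mask_volume_cc(x)))
  invisible(x)
}

#' Volume of a binary mask
#' @param mask A `binary_mask`.
#' @return Volume in cm^3 (voxel count x voxel volume).
#' @export
mask_volume_cc <- function(mask) sum(mask$values) * voxel_volume_cc(mask$grid)

# Even-odd (crossing-number) point-in-polygon test, vectorized over points.
points_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- (vy[i] > py) != (vy[j] > py)
    if (any(crosses)) {
      xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
      inside <- xor(inside, crosses & (px < xint))
    }
    j <- i
  }
  inside
}
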