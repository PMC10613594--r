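#' 3D point in patient coordinates
#'
#' Plain numeric length-3 vector `(x, y, z)` in mm. Provided as a constructor
#' so invariants (finiteness) are checked at the boundaries of the package.
#'
#' @param x,y,z Coordinates in mm.
#' @return Named numeric vector of class `point3`.
#' @export
point3 <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (length(p) != 3L || any(!is.finite(p))) {
    stop("point3: coordinates must be three finite numbers", call. = FALSE)
  }
  class(p) <- "point3"
  p
}

#' Regular 3D grid specification
#'
#' Defines a voxel grid in patient space. `origin` is the *center* of the
#' first voxel (index `(1,1,1)` in R, `(0,0,0)` in the native JSON dialect);
#' voxel `(i,j,k)` has center `origin + (i-1, j-1, k-1) * spacing`. Masks and
#' dose grids share this specification, which removes off-by-half ambiguity
#' between structures and dose.
#'
#' @param origin Numeric length 3, mm (center of first voxel).
#' @param spacing Numeric length 3 `(dx, dy, dz)`, mm, all > 0.
#' @param shape Integer length 3 `(nx, ny, nz)`, all >= 1.
#' @return Object of class `grid_spec`.
#' @export
grid_spec <- function(origin, spacing, shape) {
  origin <- as.numeric(origin); spacing <- as.numeric(spacing)
  shape <- as.integer(shape)
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("grid_spec: origin must be three finite numbers", call. = FALSE)
  }
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("grid_spec: spacing must be three positive numbers", call. = FALSE)
  }
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L)) {
    stop("grid_spec: shape must be three integers >= 1", call. = FALSE)
  }
  structure(list(origin = origin, spacing = spacing, shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Voxel-center coordinates along each axis
#' @param grid A [grid_spec()].
#' @return List with numeric vectors `x`, `y`, `z` (mm).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  list(x = grid$origin[1] + (seq_len(grid$shape[1]) - 1) * grid$spacing[1],
       y = grid$origin[2] + (seq_len(grid$shape[2]) - 1) * grid$spacing[2],
       z = grid$origin[3] + (seq_len(grid$shape[3]) - 1) * grid$spacing[3])
}

#' All voxel centers as an N x 3 matrix
#'
#' Rows are ordered column-major (x fastest), matching the linear ordering of
#' a `array(dim = shape)` in R, so row `i` corresponds to `values[[i]]`.
#'
#' @param grid A [grid_spec()].
#' @return Numeric matrix with columns `x`, `y`, `z` (mm).
#' @export
grid_centers <- function(grid) {
  ax <- grid_axes(grid)
  n <- grid$shape
  cbind(x = rep(ax$x, times = n[2] * n[3]),
        y = rep(rep(ax$y, each = n[1]), times = n[3]),
        z = rep(ax$z, each = n[1] * n[2]))
}

#' Voxel volume of a grid
#' @param grid A [grid_spec()].
#' @return Volume of one voxel in cm^3.
#' @export
voxel_volume_cc <- function(grid) prod(grid$spacing) / 1000

grid_equal <- function(a, b, tol = 1e-9) {
  all(abs(a$origin - b$origin) < tol) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(a$shape == b$shape)
}

# Trilinear interpolation of a 3D array at arbitrary points.
# Points outside the grid are clamped to the boundary voxel centers.
trilinear_sample <- function(values, grid, pts) {
  n <- grid$shape
  fx <- (pts[, 1] - grid$origin[1]) / grid$spacing[1] + 1
  fy <- (pts[, 2] - grid$origin[2]) / grid$spacing[2] + 1
  fz <- (pts[, 3] - grid$origin[3]) / grid$spacing[3] + 1
  fx <- pmin(pmax(fx, 1), n[1]); fy <- pmin(pmax(fy, 1), n[2]); fz <- pmin(pmax(fz, 1), n[3])
  i0 <- pmin(floor(fx), n[1] - (n[1] > 1)); j0 <- pmin(floor(fy), n[2] - (n[2] > 1))
  k0 <- pmin(floor(fz), n[3] - (n[3] > 1))
  wx <- fx - i0; wy <- fy - j0; wz <- fz - k0
  i1 <- pmin(i0 + 1, n[1]); j1 <- pmin(j0 + 1, n[2]); k1 <- pmin(k0 + 1, n[3])
  nx <- n[1]; nxy <- n[1] * n[2]
  idx <- function(i, j, k) i + (j - 1) * nx + (k - 1) * nxy
  v <- values
  v000 <- v[idx(i0, j0, k0)]; v100 <- v[idx(i1, j0, k0)]
  v010 <- v[idx(i0, j1, k0)]; v110 <- v[idx(i1, j1, k0)]
  v001 <- v[idx(i0, j0, k1)]; v101 <- v[idx(i1, j0, k1)]
  v011 <- v[idx(i0, j1, k1)]; v111 <- v[idx(i1, j1, k1)]
  (v000 * (1 - wx) + v100 * wx) * (1 - wy) * (1 - wz) +
    (v010 * (1 - wx) + v110 * wx) * wy * (1 - wz) +
    (v001 * (1 - wx) + v101 * wx) * (1 - wy) * wz +
    (v011 * (1 - wx) + v111 * wx) * wy * wz
}

# Evaluate a function with a temporary RNG state derived from `seed`,
# restoring the caller's .Random.seed afterwards (no global state leaks).
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
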