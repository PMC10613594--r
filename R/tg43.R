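# TG-43 (update 1) line-source dose engine.
#
# Dose rate at (r, theta) from one dwell:
#   Ddot(r, theta) = S_k * Lambda * G_L(r,theta)/G_L(r0,theta0) * g(r) * F(r,theta)
# with r0 = 10 mm, theta0 = 90 deg. S_k in U, Lambda in cGy/(h U), result
# converted to Gy/h. Distances in mm throughout.

#' TG-43 line-source geometry function
#'
#' \eqn{G_L(r, \theta) = \beta / (L r \sin\theta)} off axis, where
#' \eqn{\beta} is the angle (radians) subtended by the active length at the
#' field point; on axis \eqn{G_L = 1/(r^2 - L^2/4)} (valid for `r > L/2`).
#' `L = 0` selects the point-source limit \eqn{1/r^2}. Continuous in theta at
#' the on-axis limit.
#'
#' @param r Radial distance from the source center, mm (> 0); vectorized.
#' @param theta Polar angle from the source long axis, degrees in `[0, 180]`;
#'   vectorized.
#' @param L Active length, mm (>= 0).
#' @return Geometry function value(s), mm^-2.
#' @export
line_source_geometry_function <- function(r, theta, L) {
  if (any(!is.finite(r)) || any(r <= 0)) {
    stop("line_source_geometry_function: r must be > 0", call. = FALSE)
  }
  if (any(theta < -1e-9) || any(theta > 180 + 1e-9)) {
    stop("line_source_geometry_function: theta must be in [0, 180] degrees", call. = FALSE)
  }
  if (!is.finite(L) || L < 0) {
    stop("line_source_geometry_function: L must be >= 0", call. = FALSE)
  }
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (L == 0) return(1 / r^2)
  th <- theta * pi / 180
  st <- sin(th); ct <- cos(th)
  # field point at (x, y) = (r sin(theta), r cos(theta)); source on y axis
  x <- r * st; y <- r * ct
  on_axis <- x < 1e-9 * pmax(r, 1)
  out <- numeric(n)
  if (any(on_axis)) {
    ra <- r[on_axis]
    if (any(ra <= L / 2)) {
      stop("line_source_geometry_function: on-axis point inside the source (r <= L/2)",
           call. = FALSE)
    }
    out[on_axis] <- 1 / (ra^2 - L^2 / 4)
  }
  if (any(!on_axis)) {
    xo <- x[!on_axis]; yo <- y[!on_axis]
    # beta = angle at the field point between the two source tips
    u1x <- -xo; u1y <- L / 2 - yo
    u2x <- -xo; u2y <- -L / 2 - yo
    beta <- atan2(abs(u1x * u2y - u1y * u2x), u1x * u2x + u1y * u2y)
    out[!on_axis] <- beta / (L * r[!on_axis] * st[!on_axis])
  }
  out
}

#' Single-dwell TG-43 dose rate
#'
#' \eqn{\dot{D}(r,\theta) = S_K \Lambda \frac{G_L(r,\theta)}{G_L(r_0,\theta_0)}
#' g(r) F(r,\theta)} converted to Gy/h. Radii outside the tabulated g/F range
#' are clamped to the boundary value (with a warning when `warn = TRUE`).
#'
#' @param source A [source_model()].
#' @param r Radial distance, mm (> 0); vectorized.
#' @param theta Polar angle, degrees; vectorized.
#' @param warn Warn when table clamping occurs (default `TRUE`).
#' @return Dose rate(s), Gy/h.
#' @export
single_dwell_dose_rate <- function(source, r, theta = 90, warn = TRUE) {
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  L <- source$active_length
  G <- line_source_geometry_function(r, theta, L)
  G0 <- line_source_geometry_function(10, 90, L)
  g <- radial_dose_at(source, r, warn = warn)
  Fv <- anisotropy_at(source, r, theta)
  source$air_kerma_strength * source$dose_rate_constant / 100 * (G / G0) * g * Fv
}

# Robust evaluation for superposition: radii under 1 mm are held at 1 mm,
# and near-axis points inside the active-length envelope (where the
# line-source geometry function is undefined) are held just outside it.
# Returns the rate (Gy/h) and a flag for held voxels.
dose_rate_safe <- function(source, r, theta) {
  rc <- pmax(r, 1)
  held <- r < 1
  L <- source$active_length
  if (L > 0) {
    st <- sin(theta * pi / 180)
    inside <- (rc * st < 1e-6) & (rc <= L / 2 + 0.5)
    rc[inside] <- L / 2 + 0.5
    held <- held | inside
  }
  list(rate = single_dwell_dose_rate(source, rc, theta, warn = FALSE), held = held)
}

#' Precomputed single-dwell dose kernel
#'
#' Evaluates the TG-43 dose rate on a grid of positions relative to one dwell
#' (source long axis along the kernel z axis) and stores dose per second of
#' dwell time per unit air-kerma strength (Gy s^-1 U^-1). Voxels closer than
#' 1 mm to the source are held at the r = 1 mm value and flagged near-source.
#'
#' @param source A [source_model()].
#' @param kernel_grid A [grid_spec()] of *relative* positions (mm), normally
#'   centered on the dwell at (0, 0, 0).
#' @return Object of class `dose_kernel`: `list(grid, values, near_source)`.
#' @export
build_dose_kernel <- function(source, kernel_grid) {
  pts <- grid_centers(kernel_grid)
  r <- sqrt(rowSums(pts^2))
  ct <- pts[, 3] / pmax(r, 1e-12)
  ct <- pmin(pmax(ct, -1), 1)
  theta <- acos(ct) * 180 / pi
  ev <- dose_rate_safe(source, r, theta)
  vals <- array(ev$rate / 3600 / source$air_kerma_strength, dim = kernel_grid$shape)
  structure(list(grid = kernel_grid, values = vals,
                 near_source = array(ev$held, dim = kernel_grid$shape)),
            class = "dose_kernel")
}

#' @export
print.dose_kernel <- function(x, ...) {
  cat(sprintf("<dose_kernel> %d x %d x %d voxels, spacing (%g, %g, %g) mm\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              x$grid$spacing[1], x$grid$spacing[2], x$grid$spacing[3]))
  invisible(x)
}

# default kernel grid for a plan/grid pair: covers every relative position
# voxel-center minus dwell-position, with the dose grid's spacing
default_kernel_grid <- function(plan, grid) {
  dw <- dwell_table(plan)
  ax <- grid_axes(grid)
  lo <- c(min(ax$x) - max(dw$x), min(ax$y) - max(dw$y), min(ax$z) - max(dw$z))
  hi <- c(max(ax$x) - min(dw$x), max(ax$y) - min(dw$y), max(ax$z) - min(dw$z))
  sp <- grid$spacing
  lo <- floor(lo / sp) * sp - sp
  shape <- ceiling((hi - lo) / sp) + 2
  grid_spec(lo, sp, shape)
}

#' Multi-dwell dose superposition on a voxel grid
#'
#' Computes total-course absorbed dose
#' \eqn{D(v) = n_{fx} \sum_i t_i \dot{d}_i(v) A_i(v)} where \eqn{\dot{d}_i}
#' is the single-dwell TG-43 dose per second of dwell time and
#' \eqn{A_i(v) = 2^{-\ell_i(v)/\mathrm{HVL}}} is the lead-block transmission
#' for the ray from dwell `i` to voxel `v` (1 when `shield` is `NULL`). The
#' result is linear in every dwell time and in the air-kerma strength.
#'
#' Two kernel strategies are available: `"direct"` evaluates the TG-43
#' formula per (dwell, voxel) pair with the source axis taken along the local
#' catheter direction; `"kernel"` resamples a precomputed single-dwell kernel
#' (fixed axis along z) by trilinear interpolation, the strategy a
#' treatment-planning-export workflow uses. `"direct"` serves as the oracle
#' for `"kernel"`.
#'
#' @param plan A [brachy_plan()].
#' @param grid Target [grid_spec()].
#' @param shield Optional [shield_model()]; requires `structures`.
#' @param structures A [structure_set()] holding the shield's block contours
#'   (only needed when `shield` is given).
#' @param method `"direct"` (default) or `"kernel"`.
#' @param kernel Optional precomputed [build_dose_kernel()] for
#'   `method = "kernel"`; built automatically when missing.
#' @return A [dose_grid()] of total-course dose (Gy) with `near_source` (and,
#'   with a shield, `in_shield`) flags.
#' @export
compute_dose <- function(plan, grid, shield = NULL, structures = NULL,
                         method = c("direct", "kernel"), kernel = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(plan, "brachy_plan"), inherits(grid, "grid_spec"))
  dw <- dwell_table(plan)
  src <- plan$source
  centers <- grid_centers(grid)
  nvox <- nrow(centers)
  block <- NULL
  if (!is.null(shield)) {
    if (is.null(structures)) {
      stop("compute_dose: a shield requires the structure set holding the block contours",
           call. = FALSE)
    }
    block <- shield_block_mask(shield, structures)
  }
  if (method == "kernel" && is.null(kernel)) {
    kernel <- build_dose_kernel(src, default_kernel_grid(plan, grid))
  }
  vals <- numeric(nvox)
  near <- logical(nvox)
  for (i in seq_len(nrow(dw))) {
    t_i <- dw$time[i]
    p <- c(dw$x[i], dw$y[i], dw$z[i])
    rel <- cbind(centers[, 1] - p[1], centers[, 2] - p[2], centers[, 3] - p[3])
    r <- sqrt(rowSums(rel^2))
    near <- near | (r < 1)
    if (t_i == 0) next
    if (method == "direct") {
      ct <- (rel[, 1] * dw$ax[i] + rel[, 2] * dw$ay[i] + rel[, 3] * dw$az[i]) / pmax(r, 1)
      ct[r < 1e-12] <- 0
      theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
      ev <- dose_rate_safe(src, r, theta)
      near <- near | ev$held
      contrib <- ev$rate / 3600 * t_i
    } else {
      k <- trilinear_sample(kernel$values, kernel$grid, rel)
      contrib <- k * src$air_kerma_strength * t_i
    }
    if (!is.null(block)) {
      pl <- ray_path_lengths_cpp(matrix(p, nrow = 1), rel + matrix(p, nvox, 3, byrow = TRUE),
                                 block$mask$values, block$mask$grid$shape,
                                 block$mask$grid$origin, block$mask$grid$spacing)
      contrib <- contrib * 2^(-pl / shield$half_value_layer)
    }
    vals <- vals + contrib
  }
  vals <- vals * plan$n_fractions
  if (any(!is.finite(vals))) {
    stop("compute_dose: non-finite dose encountered (internal error)", call. = FALSE)
  }
  in_shield <- NULL
  if (!is.null(block)) {
    in_shield <- suppressWarnings(
      rasterize_structure(structures, shield$block_structure_name, grid)$values)
  }
  dose_grid(grid, array(vals, dim = grid$shape),
            near_source = array(near, dim = grid$shape),
            in_shield = in_shield)
}
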