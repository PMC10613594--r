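#' 3D absorbed-dose grid
#'
#' Scalar field of total-course absorbed dose (Gy) on a [grid_spec()], with
#' optional voxel flags: `near_source` (voxel center within 1 mm of a dwell,
#' where TG-43 tables are unreliable) and `in_shield` (voxel inside the lead
#' block, where the attenuation-only model is unreliable). Flagged voxels are
#' excluded from DVH computation by default.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric array matching `grid$shape`; finite, >= 0.
#' @param near_source,in_shield Optional logical arrays matching `grid$shape`.
#' @return Object of class `dose_grid`.
#' @export
dose_grid <- function(grid, values, near_source = NULL, in_shield = NULL) {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!all(dim(values) == grid$shape)) {
    stop("dose_grid: values shape does not match grid", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("dose_grid: values must be finite", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("dose_grid: values must be non-negative", call. = FALSE)
  }
  for (fl in list(near_source, in_shield)) {
    if (!is.null(fl) && !all(dim(fl) == grid$shape)) {
      stop("dose_grid: flag array shape does not match grid", call. = FALSE)
    }
  }
  structure(list(grid = grid, values = values,
                 near_source = near_source, in_shield = in_shield),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("<dose_grid> %d x %d x %d voxels; dose range [%.3g, %.3g] Gy\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$values), max(x$values)))
  nflag <- sum(!excluded_ok(x))
  if (nflag > 0) cat(sprintf("  %d voxels flagged (near-source / in-shield)\n", nflag))
  invisible(x)
}

# logical array: TRUE where the voxel is usable (not flagged)
excluded_ok <- function(dose) {
  ok <- array(TRUE, dim = dose$grid$shape)
  if (!is.null(dose$near_source)) ok <- ok & !dose$near_source
  if (!is.null(dose$in_shield)) ok <- ok & !dose$in_shield
  ok
}

#' Multiply a dose grid by a scalar
#' @param dose A [dose_grid()].
#' @param scale Non-negative scalar.
#' @return A new `dose_grid`; flags are preserved.
#' @export
scale_dose <- function(dose, scale) {
  stopifnot(is.finite(scale), scale >= 0)
  dose_grid(dose$grid, dose$values * scale, dose$near_source, dose$in_shield)
}
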