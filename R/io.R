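# Native JSON dialects. Documented schemas:
#
# plan v1:       { format: "brachyshield-plan-v1", prescription_dose_gy,
#                  n_fractions, source: { air_kerma_strength_U,
#                  dose_rate_constant_cGy_h_U, active_length_mm,
#                  radial_dose: null | {r_mm: [], g: []},
#                  anisotropy: null | {type: "phi", r_mm: [], phi: []}
#                             | {type: "F", r_mm: [], theta_deg: [], F: [[]]} },
#                  catheters: [ { id, dwells: [{x,y,z,time_s}] } ] }
# structures v1: { format: "brachyshield-structures-v1", slice_thickness_mm,
#                  structures: { name: [ { z_mm, vertices: [[x,y],...] } ] } }
# dose v1:       { format: "brachyshield-dose-v1",
#                  grid: { origin_mm, spacing_mm, shape },
#                  values_gy: [...]  (flattened, x fastest),
#                  near_source_idx, in_shield_idx: 1-based flat indices }

#' Write a plan to the native JSON dialect
#' @param plan A [brachy_plan()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_plan <- function(plan, path) {
  stopifnot(inherits(plan, "brachy_plan"))
  src <- plan$source
  rd <- if (is.null(src$radial_dose)) NULL else
    list(r_mm = src$radial_dose$r, g = src$radial_dose$g)
  an <- if (is.null(src$anisotropy)) NULL
  else if (is.data.frame(src$anisotropy))
    list(type = "phi", r_mm = src$anisotropy$r, phi = src$anisotropy$phi)
  else
    list(type = "F", r_mm = src$anisotropy$r, theta_deg = src$anisotropy$theta,
         F = src$anisotropy$F)
  obj <- list(
    format = "brachyshield-plan-v1",
    prescription_dose_gy = plan$prescription_dose,
    n_fractions = plan$n_fractions,
    source = list(air_kerma_strength_U = src$air_kerma_strength,
                  dose_rate_constant_cGy_h_U = src$dose_rate_constant,
                  active_length_mm = src$active_length,
                  radial_dose = rd, anisotropy = an),
    catheters = lapply(plan$catheters, function(cat_i) {
      list(id = cat_i$id,
           dwells = lapply(seq_len(nrow(cat_i$dwells)), function(i) {
             d <- cat_i$dwells[i, ]
             list(x = d$x, y = d$y, z = d$z, time_s = d$time)
           }))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a plan from the native JSON dialect
#' @param path Input file path.
#' @return A [brachy_plan()].
#' @export
read_plan <- function(path) {
  obj <- parse_native(path, "brachyshield-plan-v1")
  s <- obj$source
  need(s, "source")
  for (f in c("air_kerma_strength_U", "dose_rate_constant_cGy_h_U", "active_length_mm")) {
    need(s[[f]], paste0("source.", f))
  }
  rd <- if (is.null(s$radial_dose)) NULL else {
    need(s$radial_dose$r_mm, "source.radial_dose.r_mm")
    data.frame(r = unlist(s$radial_dose$r_mm), g = unlist(s$radial_dose$g))
  }
  an <- if (is.null(s$anisotropy)) NULL
  else if (identical(s$anisotropy$type, "phi"))
    data.frame(r = unlist(s$anisotropy$r_mm), phi = unlist(s$anisotropy$phi))
  else if (identical(s$anisotropy$type, "F"))
    list(r = unlist(s$anisotropy$r_mm), theta = unlist(s$anisotropy$theta_deg),
         F = to_matrix(s$anisotropy$F))
  else stop("read_plan: unknown anisotropy type in field 'source.anisotropy.type'",
            call. = FALSE)
  src <- source_model(air_kerma_strength = s$air_kerma_strength_U,
                      dose_rate_constant = s$dose_rate_constant_cGy_h_U,
                      active_length = s$active_length_mm,
                      radial_dose = rd, anisotropy = an)
  need(obj$catheters, "catheters")
  catheters <- lapply(obj$catheters, function(cat_i) {
    need(cat_i$dwells, "catheters[].dwells")
    dw <- do.call(rbind, lapply(cat_i$dwells, function(d) {
      for (f in c("x", "y", "z", "time_s")) need(d[[f]], paste0("catheters[].dwells[].", f))
      data.frame(x = d$x, y = d$y, z = d$z, time = d$time_s)
    }))
    list(id = cat_i$id, dwells = dw)
  })
  need(obj$prescription_dose_gy, "prescription_dose_gy")
  need(obj$n_fractions, "n_fractions")
  brachy_plan(src, catheters,
              prescription_dose = obj$prescription_dose_gy,
              n_fractions = obj$n_fractions)
}

#' Write a structure set to the native JSON dialect
#' @param set A [structure_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structures <- function(set, path) {
  stopifnot(inherits(set, "structure_set"))
  obj <- list(
    format = "brachyshield-structures-v1",
    slice_thickness_mm = set$slice_thickness,
    structures = lapply(set$structures, function(slices) {
      lapply(slices, function(s) list(z_mm = s$z, vertices = unname(s$vertices)))
    }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a structure set from the native JSON dialect
#'
#' Slices are re-sorted by z on read; malformed contours (fewer than three
#' vertices, self-intersecting rings) and duplicate structure names raise
#' validation errors.
#'
#' @param path Input file path.
#' @return A [structure_set()].
#' @export
read_structures <- function(path) {
  obj <- parse_native(path, "brachyshield-structures-v1")
  need(obj$slice_thickness_mm, "slice_thickness_mm")
  need(obj$structures, "structures")
  structures <- lapply(obj$structures, function(slices) {
    lapply(slices, function(s) {
      need(s$z_mm, "structures[].z_mm")
      need(s$vertices, "structures[].vertices")
      contour_slice(s$z_mm, to_matrix(s$vertices))
    })
  })
  structure_set(structures, slice_thickness = obj$slice_thickness_mm)
}

#' Write a dose grid to the native JSON dialect
#' @param dose A [dose_grid()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dose <- function(dose, path) {
  stopifnot(inherits(dose, "dose_grid"))
  obj <- list(
    format = "brachyshield-dose-v1",
    grid = list(origin_mm = dose$grid$origin, spacing_mm = dose$grid$spacing,
                shape = dose$grid$shape),
    values_gy = as.vector(dose$values),
    near_source_idx = if (is.null(dose$near_source)) NULL else which(dose$near_source),
    in_shield_idx = if (is.null(dose$in_shield)) NULL else which(dose$in_shield))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a dose grid from the native JSON dialect
#' @param path Input file path.
#' @return A [dose_grid()].
#' @export
read_dose <- function(path) {
  obj <- parse_native(path, "brachyshield-dose-v1")
  need(obj$grid, "grid")
  g <- grid_spec(unlist(obj$grid$origin_mm), unlist(obj$grid$spacing_mm),
                 unlist(obj$grid$shape))
  need(obj$values_gy, "values_gy")
  vals <- array(unlist(obj$values_gy), dim = g$shape)
  mk_flag <- function(idx) {
    if (is.null(idx) || length(idx) == 0L) return(NULL)
    fl <- array(FALSE, dim = g$shape); fl[unlist(idx)] <- TRUE; fl
  }
  dose_grid(g, vals, near_source = mk_flag(obj$near_source_idx),
            in_shield = mk_flag(obj$in_shield_idx))
}

parse_native <- function(path, fmt) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop(sprintf("parse error in '%s': %s", path, conditionMessage(e)),
                         call. = FALSE)
                  })
  if (!identical(obj$format, fmt)) {
    stop(sprintf("parse error in '%s': field 'format' is not '%s'", path, fmt),
         call. = FALSE)
  }
  obj
}

need <- function(x, field) {
  if (is.null(x)) stop(sprintf("parse error: missing field '%s'", field), call. = FALSE)
  invisible(x)
}

to_matrix <- function(x) {
  if (is.matrix(x)) return(x)
  do.call(rbind, lapply(x, function(row) as.numeric(unlist(row))))
}
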