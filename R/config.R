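#' Default configuration schema
#'
#' All numeric defaults of the toolchain live in one nested list so the CLI
#' and scripts share a single source of truth. Any subset can be overridden
#' from a JSON file with [read_config()].
#'
#' @return Nested list with sections `prescription`, `grid`, `shield`, `arm`,
#'   `dvh`, `phantom`.
#' @export
default_config <- function() {
  list(
    prescription = list(dose_gy = 54, n_fractions = 9),
    grid = list(spacing_mm = c(1, 1, NA)),   # NA dz = slice thickness
    shield = list(structure = "lead_block", hvl_mm = 2.76, raster_spacing_mm = 0.5),
    arm = list(eta = 0.05, max_iterations = 500, convergence_tol = 1e-4,
               min_dwell_time_s = 0, recompute_contributions_every = 1),
    dvh = list(metrics = c("D1cc", "D2cc", "D5cc", "D95%"), alpha_beta_gy = 3),
    phantom = list(catheter_spacing_mm = 10, dwell_step_mm = 2.5,
                   lead_thickness_mm = 3, slice_thickness_mm = 2))
}

#' Read a configuration file, merged over the defaults
#' @param path JSON file with any subset of the [default_config()] sections,
#'   or `NULL` for pure defaults.
#' @return Nested configuration list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_lists(cfg, user)
}

merge_lists <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_lists(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}
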