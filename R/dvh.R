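# DVH construction and summary metrics. The DVH is kept in "dose-sorted"
# form (all masked voxel doses sorted descending) with linear interpolation
# between voxel ranks: no histogram binning, so bin width never enters as a
# hidden parameter.

#' Cumulative DVH of a structure
#'
#' Collects the doses of all masked voxels, sorted descending. Voxels flagged
#' near-source or in-shield on the dose grid are excluded by default (their
#' TG-43 / attenuation-only dose is unreliable).
#'
#' @param dose A [dose_grid()].
#' @param mask A `binary_mask` on the same grid.
#' @param structure Structure name carried along for reporting.
#' @param include_flagged Include flagged voxels (default `FALSE`).
#' @return Object of class `dvh_curve`: `list(dose, voxel_volume_cc,
#'   total_volume_cc, structure)` with `dose` sorted descending.
#' @export
cumulative_dvh <- function(dose, mask, structure = "structure",
                           include_flagged = FALSE) {
  stopifnot(inherits(dose, "dose_grid"), inherits(mask, "binary_mask"))
  if (!grid_equal(dose$grid, mask$grid)) {
    stop("cumulative_dvh: dose and mask are on different grids", call. = FALSE)
  }
  sel <- mask$values
  if (!include_flagged) sel <- sel & excluded_ok(dose)
  d <- sort(dose$values[sel], decreasing = TRUE)
  if (length(d) == 0L) {
    warning(sprintf("empty DVH for '%s' (mask empty after flag exclusion)", structure),
            call. = FALSE)
  }
  vv <- voxel_volume_cc(dose$grid)
  structure(list(dose = d, voxel_volume_cc = vv,
                 total_volume_cc = length(d) * vv, structure = structure),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf("<dvh_curve> '%s': %.2f cm^3 (%d voxels), dose range [%.3g, %.3g] Gy\n",
              x$structure, x$total_volume_cc, length(x$dose),
              if (length(x$dose)) min(x$dose) else NA, if (length(x$dose)) max(x$dose) else NA))
  invisible(x)
}

#' Minimum dose to the hottest part of a structure
#'
#' `D_x cc` (`volume_cc`) or `D_x%` (`percent`): the minimum dose received by
#' the hottest `x` cm^3 (or `x` percent) of the structure, read from the
#' sorted-voxel DVH with linear interpolation between voxel ranks.
#'
#' @param dvh A [cumulative_dvh()].
#' @param volume_cc Absolute volume, cm^3 (0 < v <= structure volume).
#' @param percent Relative volume, percent (0 < p <= 100). Exactly one of
#'   `volume_cc`/`percent` must be given.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, volume_cc = NULL, percent = NULL) {
  stopifnot(inherits(dvh, "dvh_curve"))
  if (is.null(volume_cc) == is.null(percent)) {
    stop("dose_at_volume: give exactly one of volume_cc or percent", call. = FALSE)
  }
  if (!is.null(percent)) {
    if (percent <= 0 || percent > 100) {
      stop("dose_at_volume: percent must be in (0, 100]", call. = FALSE)
    }
    volume_cc <- percent / 100 * dvh$total_volume_cc
  }
  if (volume_cc <= 0) stop("dose_at_volume: volume must be > 0", call. = FALSE)
  if (volume_cc > dvh$total_volume_cc + 1e-9) {
    stop(sprintf("dose_at_volume: requested %.3f cm^3 exceeds structure volume %.3f cm^3",
                 volume_cc, dvh$total_volume_cc), call. = FALSE)
  }
  n <- length(dvh$dose)
  k <- volume_cc / dvh$voxel_volume_cc    # fractional voxel rank
  if (k <= 1) return(dvh$dose[1])
  if (k >= n) return(dvh$dose[n])
  f <- floor(k)
  dvh$dose[f] + (k - f) * (dvh$dose[f + 1] - dvh$dose[f])
}

#' Rescale a plan and its dose so that PTV D95 equals the prescription
#'
#' Computes `scale = prescription / D_95%` on the PTV and multiplies both the
#' dose grid and the plan's dwell times by it; linearity of the dose engine
#' makes the two consistent.
#'
#' @param dose A [dose_grid()] computed from `plan`.
#' @param plan The [brachy_plan()] (supplies the prescription).
#' @param ptv_mask `binary_mask` of the PTV on the dose grid.
#' @return List `scale`, `dose` (rescaled), `plan` (dwell times rescaled).
#' @export
rescale_to_d95 <- function(dose, plan, ptv_mask) {
  dvh <- cumulative_dvh(dose, ptv_mask, structure = "PTV")
  d95 <- dose_at_volume(dvh, percent = 95)
  if (d95 <= 0) stop("rescale_to_d95: PTV D95 is zero", call. = FALSE)
  scale <- plan$prescription_dose / d95
  list(scale = scale, dose = scale_dose(dose, scale),
       plan = scale_dwell_times(plan, scale))
}

#' Fractionation parameters for EQD2 conversion
#' @param n_fractions Number of fractions (> 0).
#' @param alpha_beta Tissue alpha/beta ratio, Gy (> 0; 3 Gy for late-reacting
#'   normal tissue such as bone).
#' @return Object of class `fractionation`.
#' @export
fractionation <- function(n_fractions, alpha_beta) {
  n_fractions <- as.integer(n_fractions)
  stopifnot(!is.na(n_fractions), n_fractions >= 1,
            is.finite(alpha_beta), alpha_beta > 0)
  structure(list(n_fractions = n_fractions, alpha_beta = alpha_beta),
            class = "fractionation")
}

#' Equivalent dose in 2-Gy fractions
#'
#' Linear-quadratic conversion \eqn{EQD2 = D (d + \alpha/\beta) /
#' (2 + \alpha/\beta)} with dose per fraction \eqn{d = D/n}.
#'
#' @param total_dose Total physical dose D, Gy (>= 0); vectorized.
#' @param frac A [fractionation()].
#' @return EQD2 in Gy.
#' @export
eqd2 <- function(total_dose, frac) {
  if (any(total_dose < 0)) stop("eqd2: total_dose must be >= 0", call. = FALSE)
  d <- total_dose / frac$n_fractions
  total_dose * (d + frac$alpha_beta) / (2 + frac$alpha_beta)
}

#' Physical dose whose EQD2 equals a given limit
#'
#' Inverts [eqd2()]: the positive root of
#' \eqn{D^2/n + (\alpha/\beta) D - EQD2 (2 + \alpha/\beta) = 0}.
#'
#' @param eqd2_limit EQD2 limit, Gy (> 0); vectorized.
#' @param frac A [fractionation()].
#' @return Physical total dose in Gy.
#' @export
physical_dose_for_eqd2 <- function(eqd2_limit, frac) {
  if (any(eqd2_limit <= 0)) {
    stop("physical_dose_for_eqd2: eqd2_limit must be > 0", call. = FALSE)
  }
  ab <- frac$alpha_beta
  n <- frac$n_fractions
  (-ab + sqrt(ab^2 + 4 * eqd2_limit * (2 + ab) / n)) / (2 / n)
}

#' Paired plan-difference summary
#'
#' Summarizes per-case differences `b - a` (and relative differences
#' `(b - a)/a`) across paired plans: mean, sample SD (n - 1 denominator),
#' min, max.
#'
#' @param values_a,values_b Equal-length numeric vectors (length >= 2), e.g.
#'   a DVH metric per case under two calculation methods.
#' @return Data frame with rows `absolute` (Gy) and `relative`
#'   (dimensionless), columns `mean`, `sd`, `min`, `max`.
#' @export
summarize_paired_differences <- function(values_a, values_b) {
  if (length(values_a) != length(values_b)) {
    stop("summarize_paired_differences: input lengths differ", call. = FALSE)
  }
  if (length(values_a) < 2L) {
    stop("summarize_paired_differences: need at least two cases", call. = FALSE)
  }
  d <- values_b - values_a
  rel <- d / values_a
  data.frame(row.names = c("absolute", "relative"),
             mean = c(mean(d), mean(rel)),
             sd = c(sd(d), sd(rel)),
             min = c(min(d), min(rel)),
             max = c(max(d), max(rel)))
}
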