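# Seeded synthetic tongue-ISBT phantom factory. The phantom emulates the
# clinical geometry of interstitial tongue brachytherapy with a shielded
# spacer: an ellipsoidal PTV (tongue tumor), a curved-prism mandible lateral
# to it, a resin spacer slab filling the gap, and a 3-mm lead slab embedded
# in the spacer, with parallel catheters running through the PTV. All
# randomness flows from one seed; no global RNG state is touched.

#' Phantom configuration
#'
#' Defaults emulate the clinical population the package targets: PTV volume
#' sampled uniformly on 2.7-28.6 cm^3, 3-14 catheters, a 3-mm lead slab in a
#' spacer of 3-14.9 mm (the sampled spacer range is truncated below at the
#' lead thickness so the block always fits), prescription 54 Gy in 9
#' fractions. `NULL` fields are sampled from the seed in
#' [generate_phantom()]; set them to fix a value.
#'
#' @param ptv_volume_cc Target PTV volume, cm^3, or `NULL` to sample
#'   U(2.7, 28.6).
#' @param n_catheters Number of catheters, or `NULL` to sample 3..14.
#' @param catheter_spacing In-plane catheter spacing, mm (default 10).
#' @param dwell_step Dwell spacing along each catheter, mm (default 2.5).
#' @param spacer_thickness Spacer slab thickness, mm, or `NULL` to sample
#'   U(max(lead, 2.8), 14.9).
#' @param lead_thickness Lead slab thickness, mm (default 3).
#' @param mandible_offset Gap between PTV surface and mandible inner face,
#'   mm; `NULL` (default) uses the spacer thickness (the spacer fills the
#'   gap).
#' @param slice_thickness Contour/CT slice thickness, mm (default 2).
#' @param grid_spacing Dose-grid spacing `(dx, dy, dz)`, mm; `NA` dz uses the
#'   slice thickness (default `c(1, 1, NA)`).
#' @param prescription_dose,n_fractions Prescription (default 54 Gy / 9).
#' @param seed Integer seed driving all sampling (default 0).
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(ptv_volume_cc = NULL, n_catheters = NULL,
                           catheter_spacing = 10, dwell_step = 2.5,
                           spacer_thickness = NULL, lead_thickness = 3,
                           mandible_offset = NULL, slice_thickness = 2,
                           grid_spacing = c(1, 1, NA),
                           prescription_dose = 54, n_fractions = 9,
                           seed = 0) {
  chk_pos <- function(x, nm) {
    if (!is.null(x) && (!all(is.finite(x)) || any(x <= 0))) {
      stop(sprintf("phantom_config: %s must be positive", nm), call. = FALSE)
    }
  }
  chk_pos(ptv_volume_cc, "ptv_volume_cc"); chk_pos(catheter_spacing, "catheter_spacing")
  chk_pos(dwell_step, "dwell_step"); chk_pos(spacer_thickness, "spacer_thickness")
  chk_pos(lead_thickness, "lead_thickness"); chk_pos(slice_thickness, "slice_thickness")
  chk_pos(mandible_offset, "mandible_offset")
  if (!is.null(n_catheters) && n_catheters < 1) {
    stop("phantom_config: n_catheters must be >= 1", call. = FALSE)
  }
  if (!is.null(spacer_thickness) && lead_thickness > spacer_thickness) {
    stop("phantom_config: lead_thickness must be <= spacer_thickness", call. = FALSE)
  }
  structure(list(ptv_volume_cc = ptv_volume_cc, n_catheters = n_catheters,
                 catheter_spacing = catheter_spacing, dwell_step = dwell_step,
                 spacer_thickness = spacer_thickness, lead_thickness = lead_thickness,
                 mandible_offset = mandible_offset, slice_thickness = slice_thickness,
                 grid_spacing = grid_spacing, prescription_dose = prescription_dose,
                 n_fractions = n_fractions, seed = as.integer(seed)),
            class = "phantom_config")
}

circle_ring <- function(cx, cy, rx, ry, n = 48) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + rx * cos(t), cy + ry * sin(t))
}

#' Generate a synthetic shielded tongue-ISBT phantom
#'
#' Deterministic for a fixed seed. Builds the structure set (`PTV`,
#' `mandible`, `spacer`, `lead_block`), a dose grid covering everything with
#' 5 mm margin, and a plan with parallel catheters along z and uniform
#' initial dwell times normalized so that the unshielded PTV D95 equals the
#' prescription.
#'
#' @param config A [phantom_config()].
#' @return Object of class `phantom`: `list(structures, plan, grid, config)`
#'   where `config` has all sampled values filled in.
#' @export
generate_phantom <- function(config = phantom_config()) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  with_seed(cfg$seed, {
    if (is.null(cfg$ptv_volume_cc)) cfg$ptv_volume_cc <- runif(1, 2.7, 28.6)
    if (is.null(cfg$n_catheters)) cfg$n_catheters <- sample(3:14, 1)
    if (is.null(cfg$spacer_thickness)) {
      cfg$spacer_thickness <- runif(1, max(cfg$lead_thickness, 2.8), 14.9)
    }
    if (is.null(cfg$mandible_offset)) cfg$mandible_offset <- cfg$spacer_thickness
    if (cfg$lead_thickness > cfg$spacer_thickness) {
      stop("generate_phantom: lead_thickness exceeds spacer_thickness", call. = FALSE)
    }
    dz <- cfg$slice_thickness
    # PTV ellipsoid: semi-axes a:b:c = 1 : 1.25 : 1.5, scaled to the volume
    s <- (3 * cfg$ptv_volume_cc * 1000 / (4 * pi * 1 * 1.25 * 1.5))^(1 / 3)
    a <- s; b <- 1.25 * s; c_ <- 1.5 * s
    zs <- seq(-c_ + dz / 2, c_ - dz / 2, by = dz)
    if (length(zs) < 3L) zs <- seq(-c_ * 0.8, c_ * 0.8, length.out = 3)
    ptv <- lapply(zs, function(z) {
      f <- sqrt(max(1e-4, 1 - (z / c_)^2))
      contour_slice(z, circle_ring(0, 0, a * f, b * f))
    })
    # mandible: arc prism lateral to the PTV (+x), constant cross-section
    r1 <- a + cfg$mandible_offset
    r2 <- r1 + 8
    ang <- seq(-40, 40, length.out = 25) * pi / 180
    arc <- rbind(cbind(r1 * cos(ang), r1 * sin(ang)),
                 cbind(r2 * cos(rev(ang)), r2 * sin(rev(ang))))
    zm <- seq(min(zs), max(zs), by = dz)
    mandible <- lapply(zm, function(z) contour_slice(z, arc))
    # spacer slab fills the PTV-mandible gap; lead slab centered inside it
    y_half <- r2 * sin(max(ang)) + 2
    rect <- function(x1, x2) rbind(c(x1, -y_half), c(x2, -y_half),
                                   c(x2, y_half), c(x1, y_half))
    zspan <- seq(min(zs) - dz, max(zs) + dz, by = dz)
    spacer <- lapply(zspan, function(z) contour_slice(z, rect(a, a + cfg$spacer_thickness)))
    lead_mid <- a + cfg$spacer_thickness / 2
    lead <- lapply(zspan, function(z) {
      contour_slice(z, rect(lead_mid - cfg$lead_thickness / 2,
                            lead_mid + cfg$lead_thickness / 2))
    })
    structures <- structure_set(list(PTV = ptv, mandible = mandible,
                                     spacer = spacer, lead_block = lead),
                                slice_thickness = dz)
    # catheters: candidate grid in the transverse plane, jittered, the
    # n closest to the PTV axis retained; dwells step along z inside the PTV
    spacing <- cfg$catheter_spacing
    cand <- NULL
    for (shrink in 0:20) {
      sp <- spacing * 0.85^shrink
      gx <- seq(-a, a, by = sp)
      gy <- seq(-b, b, by = sp)
      cand <- expand.grid(x = gx, y = gy)
      cand <- cand[(cand$x / a)^2 + (cand$y / b)^2 <= 0.8^2, , drop = FALSE]
      if (nrow(cand) >= cfg$n_catheters) break
    }
    if (nrow(cand) < cfg$n_catheters) {
      stop("generate_phantom: could not place the requested number of catheters",
           call. = FALSE)
    }
    cand$x <- cand$x + rnorm(nrow(cand), 0, 0.5)
    cand$y <- cand$y + rnorm(nrow(cand), 0, 0.5)
    ord <- order(cand$x^2 + cand$y^2)
    cand <- cand[ord[seq_len(cfg$n_catheters)], , drop = FALSE]
    catheters <- lapply(seq_len(nrow(cand)), function(i) {
      x <- cand$x[i]; y <- cand$y[i]
      h <- c_ * sqrt(max(0.05, 1 - (x / a)^2 - (y / b)^2)) * 0.9
      zd <- seq(-h, h, by = cfg$dwell_step)
      if (length(zd) == 0L) zd <- 0
      list(id = sprintf("cath%02d", i),
           dwells = data.frame(x = x, y = y, z = zd, time = 1))
    })
    source <- toy_source()
    plan <- brachy_plan(source, catheters,
                        prescription_dose = cfg$prescription_dose,
                        n_fractions = cfg$n_fractions)
    # dose grid: union bounding box + 5 mm margin
    bb <- Reduce(function(acc, nm) {
      bx <- structure_bbox(structures, nm)
      rbind(min = pmin(acc["min", ], bx["min", ]), max = pmax(acc["max", ], bx["max", ]))
    }, structure_names(structures)[-1], structure_bbox(structures, "PTV"))
    sp3 <- cfg$grid_spacing
    if (is.na(sp3[3])) sp3[3] <- dz
    origin <- bb["min", ] - 5
    shape <- ceiling((bb["max", ] + 5 - origin) / sp3) + 1
    grid <- grid_spec(origin, sp3, shape)
    # normalize the uniform initial times so unshielded PTV D95 = prescription
    ptv_mask <- rasterize_structure(structures, "PTV", grid)
    pts <- grid_centers(grid)[which(ptv_mask$values), , drop = FALSE]
    colnames(pts) <- c("x", "y", "z")
    rates <- dose_rate_matrix(plan, as.data.frame(pts))
    doses <- as.vector(rates %*% dwell_table(plan)$time)
    d95 <- unname(stats::quantile(doses, 0.05, type = 4))
    if (d95 > 0) plan <- scale_dwell_times(plan, cfg$prescription_dose / d95)
    structure(list(structures = structures, plan = plan, grid = grid, config = cfg),
              class = "phantom")
  })
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("<phantom> PTV %.1f cm^3 target, %d catheters, spacer %.1f mm, lead %.1f mm, seed %d\n",
              x$config$ptv_volume_cc, x$config$n_catheters,
              x$config$spacer_thickness, x$config$lead_thickness, x$config$seed))
  print(x$grid)
  invisible(x)
}

#' Displace the lead slab of a phantom
#'
#' Translates the lead-block contours by a seeded random direction in the
#' plane perpendicular to the PTV-mandible axis (the block's shielding
#' plane), scaled to the given magnitude. Supports sensitivity experiments on
#' block placement. The "lead between PTV and mandible" invariant may break;
#' the returned phantom carries a `lead_between` flag.
#'
#' @param phantom A [generate_phantom()] result.
#' @param displacement Displacement magnitude, mm (>= 0).
#' @param seed Integer seed for the direction (default 0).
#' @return A new `phantom` with translated `lead_block` and attribute
#'   `lead_between` (logical).
#' @export
perturb_phantom <- function(phantom, displacement, seed = 0) {
  stopifnot(inherits(phantom, "phantom"))
  if (!is.finite(displacement) || displacement < 0) {
    stop("perturb_phantom: displacement must be >= 0", call. = FALSE)
  }
  out <- phantom
  if (displacement > 0) {
    delta <- with_seed(seed, {
      phi <- runif(1, 0, 2 * pi)
      c(0, cos(phi), sin(phi)) * displacement
    })
    out$structures <- translate_structure(out$structures, "lead_block", delta)
  }
  # flag: block still sits in the PTV-mandible gap and covers most of the
  # mandible's lateral/longitudinal extent
  bb <- function(nm) structure_bbox(out$structures, nm)
  lead_b <- bb("lead_block"); mand_b <- bb("mandible")
  cen <- function(b) colMeans(rbind(b))
  overlap_frac <- function(a, b) {
    ov <- max(0, min(a[2], b[2]) - max(a[1], b[1]))
    ov / (b[2] - b[1])
  }
  x_between <- cen(lead_b)[1] > cen(bb("PTV"))[1] && cen(lead_b)[1] < cen(mand_b)[1]
  cover_y <- overlap_frac(lead_b[, 2], mand_b[, 2])
  cover_z <- overlap_frac(lead_b[, 3], mand_b[, 3])
  out$lead_between <- x_between && cover_y >= 0.5 && cover_z >= 0.5
  out
}
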