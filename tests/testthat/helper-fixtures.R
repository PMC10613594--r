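# Fixtures are built in code; nothing is read from disk except the package's
# own bundled toy source tables.

# bare point source with unity g and F (closed-form inverse-square dose)
point_source <- function(sk = 40800) {
  source_model(air_kerma_strength = sk, dose_rate_constant = 1.109,
               active_length = 0)
}

# axis-aligned box as a contour stack: center (mm), size (mm), slices at dz
box_slices <- function(center, size, dz) {
  x1 <- center[1] - size[1] / 2; x2 <- center[1] + size[1] / 2
  y1 <- center[2] - size[2] / 2; y2 <- center[2] + size[2] / 2
  zs <- seq(center[3] - size[3] / 2 + dz / 2, center[3] + size[3] / 2 - dz / 2, by = dz)
  lapply(zs, function(z) {
    contour_slice(z, rbind(c(x1, y1), c(x2, y1), c(x2, y2), c(x1, y2)))
  })
}

# structure set with one lead slab spanning x in [x0, x0 + thickness]
slab_structures <- function(x0 = 20, thickness = 3, half_yz = 30, dz = 2) {
  structure_set(list(lead_block = box_slices(
    c(x0 + thickness / 2, 0, 0), c(thickness, 2 * half_yz, 2 * half_yz), dz)),
    slice_thickness = dz)
}

# fine rasterized slab mask for direct ray-tracing tests
slab_mask <- function(x0 = 20, thickness = 3, half_yz = 30, raster = 0.5) {
  set <- slab_structures(x0, thickness, half_yz, dz = 2)
  sh <- shield_model("lead_block", raster_spacing = raster)
  brachyshield:::shield_block_mask(sh, set)$mask
}

# simple n-dwell plan with explicit positions (one catheter per dwell)
dwell_plan <- function(positions, times, source = point_source(), n_fractions = 1,
                       prescription = 10) {
  catheters <- lapply(seq_len(nrow(positions)), function(i) {
    list(id = sprintf("c%d", i),
         dwells = data.frame(x = positions[i, 1], y = positions[i, 2],
                             z = positions[i, 3], time = times[i]))
  })
  brachy_plan(source, catheters, prescription_dose = prescription,
              n_fractions = n_fractions)
}

# the 2-dwell / 3-point ARM toy with an (almost) unique feasible point:
# symmetric dwells, two target points with lower limits, one mid OAR point
# with an upper limit right at the feasibility threshold
arm_toy <- function(upper = 10.35) {
  plan <- dwell_plan(rbind(c(0, 0, 0), c(20, 0, 0)), c(10, 10))
  points <- data.frame(structure = c("PTV", "PTV", "OAR"),
                       x = c(0, 20, 10), y = c(8, 8, 3), z = 0,
                       lower = c(10, 10, NA), upper = c(NA, NA, upper),
                       weight = 1)
  rates <- brachyshield:::dose_rate_matrix(plan, points)
  list(plan = plan, points = points, rates = rates)
}

toy_violation_objective <- function(rates, points, t) {
  d <- as.vector(rates %*% t)
  deficit <- ifelse(!is.na(points$lower) & d < points$lower,
                    (points$lower - d) / points$lower, 0)
  excess <- ifelse(!is.na(points$upper) & d > points$upper,
                   (d - points$upper) / points$upper, 0)
  sum(points$weight * (deficit + excess)^2)
}

# small, fast phantom for engine-level tests (standard defaults are used in
# the acceptance suite)
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_phantom(phantom_config(
        seed = 1, ptv_volume_cc = 6, n_catheters = 3, grid_spacing = c(2, 2, 2)))
    }
    cache
  }
})

standard_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_config(seed = 0))
    cache
  }
})

# independent TG-43 evaluation used as the brute-force oracle: geometry
# factor via numeric integration of inverse square along the source segment
oracle_dose_rate <- function(source, r, theta_deg) {
  L <- source$active_length
  G <- if (L == 0) 1 / r^2 else {
    th <- theta_deg * pi / 180
    x <- r * sin(th); y <- r * cos(th)
    if (x < 1e-9) 1 / (r^2 - L^2 / 4)
    else integrate(function(s) 1 / (x^2 + (y - s)^2), -L / 2, L / 2,
                   rel.tol = 1e-12)$value / L
  }
  G0 <- if (L == 0) 1 / 100 else
    integrate(function(s) 1 / (100 + s^2), -L / 2, L / 2, rel.tol = 1e-12)$value / L
  g <- if (is.null(source$radial_dose)) 1 else
    approx(source$radial_dose$r, source$radial_dose$g,
           xout = min(max(r, min(source$radial_dose$r)), max(source$radial_dose$r)))$y
  an <- source$anisotropy
  Fv <- if (is.null(an)) 1
  else if (is.data.frame(an)) approx(an$r, an$phi, xout = min(max(r, min(an$r)), max(an$r)))$y
  else {
    rc <- min(max(r, min(an$r)), max(an$r))
    tc <- min(max(theta_deg, min(an$theta)), max(an$theta))
    i <- findInterval(rc, an$r); i <- min(max(i, 1), length(an$r) - 1)
    j <- findInterval(tc, an$theta); j <- min(max(j, 1), length(an$theta) - 1)
    wr <- (rc - an$r[i]) / (an$r[i + 1] - an$r[i])
    wt <- (tc - an$theta[j]) / (an$theta[j + 1] - an$theta[j])
    (an$F[i, j] * (1 - wr) + an$F[i + 1, j] * wr) * (1 - wt) +
      (an$F[i, j + 1] * (1 - wr) + an$F[i + 1, j + 1] * wr) * wt
  }
  source$air_kerma_strength * source$dose_rate_constant / 100 * (G / G0) * g * Fv
}
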