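test_that("geometry function matches closed forms and the line-integral oracle", {
  # point-source limit
  expect_equal(line_source_geometry_function(10, 47, 0), 0.01)
  # on-axis closed form
  expect_equal(line_source_geometry_function(10, 0, 3.5), 1 / (100 - 3.0625))
  expect_equal(line_source_geometry_function(10, 180, 3.5), 1 / (100 - 3.0625))
  # transverse axis: G_L = beta/(L r sin theta) equals the normalized line
  # integral of inverse square along the active length
  oracle <- integrate(function(s) 1 / (100 + s^2), -1.75, 1.75, rel.tol = 1e-12)$value / 3.5
  expect_equal(line_source_geometry_function(10, 90, 3.5), oracle, tolerance = 1e-5)
  # oblique angle against the same oracle
  th <- 37; x <- 10 * sin(th * pi / 180); y <- 10 * cos(th * pi / 180)
  oracle <- integrate(function(s) 1 / (x^2 + (y - s)^2), -1.75, 1.75, rel.tol = 1e-12)$value / 3.5
  expect_equal(line_source_geometry_function(10, th, 3.5), oracle, tolerance = 1e-5)
  # continuity at the on-axis limit
  expect_equal(line_source_geometry_function(10, 1e-4, 3.5),
               line_source_geometry_function(10, 0, 3.5), tolerance = 1e-6)
  # inside the source on axis is a domain error
  expect_error(line_source_geometry_function(1.5, 0, 3.5), "inside the source")
})

test_that("single-dwell dose rate composes S_k, Lambda, G, g and F", {
  src <- point_source(sk = 40800)
  # reference point with unity tables: exactly S_k * Lambda (cGy/h -> Gy/h)
  expect_equal(single_dwell_dose_rate(src, 10, 90), 40800 * 1.109 / 100)
  # inverse square in point mode
  expect_equal(single_dwell_dose_rate(src, 10, 90) / single_dwell_dose_rate(src, 20, 90), 4)
  # tabulated toy g(r) = exp(-0.005 (r - 10)): term-by-term product at a knot
  rtab <- seq(1, 100, by = 1)
  src_g <- source_model(air_kerma_strength = 40800, dose_rate_constant = 1.109,
                        active_length = 3.5,
                        radial_dose = data.frame(r = rtab, g = exp(-0.005 * (rtab - 10))))
  G <- line_source_geometry_function(20, 90, 3.5)
  G0 <- line_source_geometry_function(10, 90, 3.5)
  expect_equal(single_dwell_dose_rate(src_g, 20, 90),
               40800 * 1.109 / 100 * (G / G0) * exp(-0.005 * 10))
  # clamping outside the table range holds the boundary value and warns
  expect_warning(v <- single_dwell_dose_rate(src_g, 150, 90), "table range")
  G150 <- line_source_geometry_function(150, 90, 3.5)
  expect_equal(v, 40800 * 1.109 / 100 * (G150 / G0) * exp(-0.005 * 90))
})

test_that("dose kernel is symmetric, matches its definition, and direct evaluation", {
  src <- toy_source()
  kg <- grid_spec(c(-10, -10, -10), c(1, 1, 1), c(21, 21, 21))
  k <- build_dose_kernel(src, kg)
  # mirror symmetry z -> -z (theta -> 180 - theta with symmetric F)
  expect_equal(k$values, k$values[, , 21:1], tolerance = 1e-12)
  # kernel voxel on the transverse axis equals the dose-rate definition
  expect_equal(k$values[21, 11, 11],
               single_dwell_dose_rate(src, 10, 90) / 3600 / src$air_kerma_strength)
  # every voxel matches an independent per-voxel evaluation (r >= 2 mm)
  ax <- grid_axes(kg)
  idx <- which(array(TRUE, dim = kg$shape), arr.ind = TRUE)
  pts <- cbind(ax$x[idx[, 1]], ax$y[idx[, 2]], ax$z[idx[, 3]])
  r <- sqrt(rowSums(pts^2))
  sel <- which(r >= 2)
  sel <- sel[seq(1, length(sel), by = 97)]   # thin subsample
  for (i in sel) {
    theta <- acos(pts[i, 3] / r[i]) * 180 / pi
    expect_equal(k$values[idx[i, 1], idx[i, 2], idx[i, 3]],
                 oracle_dose_rate(src, r[i], theta) / 3600 / src$air_kerma_strength,
                 tolerance = 1e-4)
  }
  # near-source voxels are flagged and held at the r = 1 mm value
  expect_true(k$near_source[11, 11, 11])
  # elongating the source redistributes the kernel: near-axis voxels gain
  # (the line-source geometry factor peaks toward the poles) while
  # near-field transverse voxels lose relative to a point source; the
  # far-field sum rises slightly because TG-43 normalizes at the transverse
  # reference point. Each claim is checked against direct evaluation.
  src0 <- point_source(); srcL <- source_model(active_length = 3.5)
  k0 <- build_dose_kernel(src0, kg); kL <- build_dose_kernel(srcL, kg)
  far <- array(r >= 3, dim = kg$shape)
  expect_gt(sum(kL$values[far]), sum(k0$values[far]))
  expect_gt(kL$values[11, 11, 16], k0$values[11, 11, 16])   # on axis, z = +5
  expect_lt(kL$values[16, 11, 11], k0$values[16, 11, 11])   # transverse, x = +5
  # spot-check both regions against the independent line-integral oracle
  expect_equal(kL$values[11, 11, 16],
               oracle_dose_rate(srcL, 5, 0) / 3600 / srcL$air_kerma_strength,
               tolerance = 1e-6)
  expect_equal(kL$values[16, 11, 11],
               oracle_dose_rate(srcL, 5, 90) / 3600 / srcL$air_kerma_strength,
               tolerance = 1e-6)
})

test_that("dose superposition is linear in dwell time and air-kerma strength", {
  plan <- dwell_plan(rbind(c(0, 0, 0), c(10, 5, -3)), c(7, 13))
  grid <- grid_spec(c(-10, -10, -10), c(4, 4, 4), c(6, 6, 6))
  d1 <- compute_dose(plan, grid)
  d2 <- compute_dose(scale_dwell_times(plan, 2), grid)
  expect_equal(d2$values, 2 * d1$values)
  plan_sk <- dwell_plan(rbind(c(0, 0, 0), c(10, 5, -3)), c(7, 13),
                        source = point_source(sk = 3 * 40800))
  expect_equal(compute_dose(plan_sk, grid)$values, 3 * d1$values)
  # two co-located dwells of time t == one dwell of 2t
  pa <- dwell_plan(rbind(c(1, 2, 3), c(1, 2, 3)), c(5, 5))
  pb <- dwell_plan(rbind(c(1, 2, 3)), c(10))
  expect_equal(compute_dose(pa, grid)$values, compute_dose(pb, grid)$values)
})

test_that("3-dwell plans match a brute-force per-voxel summation oracle", {
  set.seed(42)
  for (rep in 1:2) {
    pos <- matrix(runif(9, -8, 8), ncol = 3)
    times <- runif(3, 2, 20)
    plan <- dwell_plan(pos, times, source = toy_source(), n_fractions = 9)
    grid <- grid_spec(c(-19, -19, -19), c(2, 2, 2), c(20, 20, 20))
    dose <- compute_dose(plan, grid)
    centers <- grid_centers(grid)
    check <- sample(nrow(centers), 40)
    for (v in check) {
      acc <- 0
      for (i in 1:3) {
        rel <- centers[v, ] - pos[i, ]
        r <- max(sqrt(sum(rel^2)), 1)
        theta <- acos(min(max(rel[3] / r, -1), 1)) * 180 / pi
        acc <- acc + oracle_dose_rate(plan$source, r, theta) / 3600 * times[i]
      }
      acc <- acc * 9
      expect_equal(dose$values[v], acc, tolerance = 1e-6)
    }
  }
})

test_that("kernel-lookup dose agrees with direct evaluation within 1% at 2-10 Gy", {
  ph <- generate_phantom(phantom_config(seed = 7, ptv_volume_cc = 6, n_catheters = 3,
                                        grid_spacing = c(2, 2, 2)))
  dd <- compute_dose(ph$plan, ph$grid, method = "direct")
  dk <- compute_dose(ph$plan, ph$grid, method = "kernel")
  sel <- dd$values >= 2 & dd$values <= 10
  expect_gt(sum(sel), 500)
  rel <- abs(dk$values[sel] - dd$values[sel]) / dd$values[sel]
  expect_lt(max(rel), 0.01)
})

test_that("a slab between dwells and voxels only ever reduces dose", {
  structures <- slab_structures(x0 = 15, thickness = 3)
  plan <- dwell_plan(rbind(c(0, 0, 0)), 10)
  grid <- grid_spec(c(25, -10, -10), c(2, 2, 2), c(5, 11, 11))
  dose_w <- compute_dose(plan, grid)
  dose_s <- compute_dose(plan, grid, shield = shield_model(), structures = structures)
  # every ray from the origin to x >= 25 crosses the slab: strict decrease
  expect_true(all(dose_s$values < dose_w$values))
  # and never an increase anywhere, even for unshielded geometry
  grid_b <- grid_spec(c(-12, -10, -10), c(2, 2, 2), c(5, 11, 11))
  back_w <- compute_dose(plan, grid_b)
  back_s <- compute_dose(plan, grid_b, shield = shield_model(), structures = structures)
  expect_true(all(back_s$values <= back_w$values + 1e-15))
  expect_equal(back_s$values, back_w$values)  # behind the source: no crossing
})
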