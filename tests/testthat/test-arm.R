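test_that("optimization points cover every voxel of every constrained structure", {
  dz <- 2
  structures <- structure_set(list(PTV = box_slices(c(0, 0, 0), c(10, 10, 10), dz),
                                   OAR = box_slices(c(4, 0, 0), c(10, 10, 10), dz)),
                              slice_thickness = dz)
  grid <- grid_spec(c(-9, -9, -9), c(1, 1, 2), c(19, 19, 10))
  cons <- list(dose_constraint("PTV", lower = 54),
               dose_constraint("OAR", upper = 40))
  pts <- collect_optimization_points(structures, grid, cons)
  ptv_n <- sum(rasterize_structure(structures, "PTV", grid)$values)
  oar_n <- sum(rasterize_structure(structures, "OAR", grid)$values)
  expect_equal(sum(pts$structure == "PTV"), ptv_n)
  expect_equal(sum(pts$structure == "OAR"), oar_n)
  # overlapping voxels appear once per constraint
  expect_gt(nrow(merge(pts[pts$structure == "PTV", c("x", "y", "z")],
                       pts[pts$structure == "OAR", c("x", "y", "z")])), 0)
  # missing structure is a configuration error
  expect_error(collect_optimization_points(structures, grid,
                                           list(dose_constraint("nope", upper = 1))),
               "not in the structure set")
  # constraint selecting no voxels warns
  far <- structure_set(list(S = box_slices(c(500, 0, 0), c(4, 4, 4), dz)),
                       slice_thickness = dz)
  w <- testthat::capture_warnings(
    empty <- collect_optimization_points(far, grid, list(dose_constraint("S", upper = 1))))
  expect_true(any(grepl("no voxels", w)))
  expect_true(is.null(empty) || nrow(empty) == 0L)
})

test_that("contribution factors normalize per-dwell dose fractions", {
  # single dwell: every factor is 1
  plan1 <- dwell_plan(rbind(c(0, 0, 0)), 10)
  pts <- data.frame(structure = "S", x = c(5, -3), y = c(0, 4), z = 0,
                    lower = NA, upper = 10, weight = 1)
  c1 <- contribution_matrix(plan1, pts)
  expect_equal(as.vector(c1), c(1, 1))
  # two identical dwells equidistant from a point: 0.5 each
  plan2 <- dwell_plan(rbind(c(-5, 0, 0), c(5, 0, 0)), c(10, 10))
  mid <- data.frame(structure = "S", x = 0, y = 7, z = 0, lower = NA, upper = 10, weight = 1)
  expect_equal(as.vector(contribution_matrix(plan2, mid)), c(0.5, 0.5))
  # 3-dwell random geometry: rows equal brute-force per-dwell dose ratios
  set.seed(5)
  pos <- matrix(runif(9, -10, 10), ncol = 3)
  times <- c(4, 9, 2)
  plan3 <- dwell_plan(pos, times)
  pts3 <- data.frame(structure = "S", x = runif(4, -10, 10), y = runif(4, -10, 10),
                     z = runif(4, -10, 10), lower = NA, upper = 10, weight = 1)
  cm <- contribution_matrix(plan3, pts3)
  expect_equal(rowSums(cm), rep(1, 4), tolerance = 1e-12)
  for (v in 1:4) {
    d <- vapply(1:3, function(i) {
      r <- max(sqrt(sum((c(pts3$x[v], pts3$y[v], pts3$z[v]) - pos[i, ])^2)), 1)
      oracle_dose_rate(plan3$source, r, 90) / 3600 * times[i]
    }, numeric(1))
    expect_equal(unname(cm[v, ]), d / sum(d), tolerance = 1e-9)
  }
  # all-zero dwell times are rejected
  expect_error(contribution_matrix(dwell_plan(rbind(c(0, 0, 0)), 0), pts),
               "all dwell times are zero")
})

test_that("attraction/repulsion forces follow the relative-violation formula", {
  # everything within limits: zero force
  pts <- data.frame(lower = c(10, NA), upper = c(NA, 20), weight = 1)
  cmat <- matrix(c(0.6, 0.4, 0.3, 0.7), nrow = 2, byrow = TRUE)
  expect_equal(arm_forces(c(15, 15), cmat, pts), c(0, 0))
  # one point at twice its upper limit, one dwell with c = 1, w = 1: f = -1
  expect_equal(arm_forces(20, matrix(1), data.frame(lower = NA, upper = 10, weight = 1)),
               -1)
  # random 5-point, 2-dwell instance vs independent summation
  set.seed(9)
  doses <- runif(5, 0, 30)
  pts5 <- data.frame(lower = c(12, 15, NA, NA, 8), upper = c(NA, NA, 10, 22, 25),
                     weight = runif(5, 0.5, 2))
  cm5 <- matrix(runif(10), nrow = 5)
  cm5 <- cm5 / rowSums(cm5)
  f <- arm_forces(doses, cm5, pts5)
  oracle <- c(0, 0)
  for (v in 1:5) {
    s <- 0
    if (!is.na(pts5$lower[v]) && doses[v] < pts5$lower[v]) {
      s <- (pts5$lower[v] - doses[v]) / pts5$lower[v]
    }
    if (!is.na(pts5$upper[v]) && doses[v] > pts5$upper[v]) {
      s <- (pts5$upper[v] - doses[v]) / pts5$upper[v]
    }
    oracle <- oracle + pts5$weight[v] * cm5[v, ] * s
  }
  expect_equal(f, oracle, tolerance = 1e-12)
  # a violated zero limit is a domain error
  expect_error(arm_forces(5, matrix(1), data.frame(lower = NA, upper = 0, weight = 1)),
               "zero limit")
})

test_that("the multiplicative step clamps at the floor and fixes zero force", {
  cfg <- arm_config(eta = 0.2, min_dwell_time = 0.5)
  expect_equal(arm_step(c(10, 3), c(0, 0), cfg), c(10, 3))
  expect_equal(arm_step(10, -0.5, cfg), 9.0)
  expect_equal(arm_step(10, -20, cfg), 0.5)      # eta*f <= -1: clamp to floor
  expect_error(arm_step(-1, 0, cfg), ">= 0")
})

test_that("a feasible plan is a fixed point of the optimizer", {
  dz <- 2
  structures <- structure_set(list(PTV = box_slices(c(0, 0, 0), c(8, 8, 8), dz)),
                              slice_thickness = dz)
  grid <- grid_spec(c(-5, -5, -5), c(2, 2, 2), c(6, 6, 6))
  plan <- dwell_plan(rbind(c(0, 0, 0)), 50, n_fractions = 9)
  # bracket the dose actually delivered so no constraint is violated
  pts <- collect_optimization_points(structures, grid,
                                     list(dose_constraint("PTV", lower = 1)))
  rates <- brachyshield:::dose_rate_matrix(plan, pts)
  doses <- as.vector(rates %*% dwell_table(plan)$time)
  cons <- list(dose_constraint("PTV", lower = min(doses) * 0.9, upper = max(doses) * 1.1))
  res <- optimize_arm(plan, structures, cons, grid)
  expect_equal(dwell_table(res$plan)$time, dwell_table(plan)$time)
  expect_true(res$converged)
  expect_equal(res$trace$objective[1], 0)
})

test_that("single dwell with one over-limit voxel converges to the closed-form fixed point", {
  dz <- 2
  structures <- structure_set(list(OAR = box_slices(c(10, 0, 0), c(2, 2, 2), dz)),
                              slice_thickness = dz)
  grid <- grid_spec(c(10, 0, 0), c(2, 2, 2), c(1, 1, 1))   # one voxel at (10, 0, 0)
  plan <- dwell_plan(rbind(c(0, 0, 0)), 100, n_fractions = 1)
  cons <- list(dose_constraint("OAR", upper = 5))
  res <- optimize_arm(plan, structures, cons, grid,
                      config = arm_config(eta = 0.1, convergence_tol = 1e-8,
                                          max_iterations = 2000))
  # fixed point of t <- t (1 + eta (U - D)/U) is D = U, i.e. t* = U / rate
  pts <- collect_optimization_points(structures, grid, cons)
  rate <- brachyshield:::dose_rate_matrix(plan, pts)[1, 1]
  expect_equal(dwell_table(res$plan)$time, 5 / rate, tolerance = 1e-4)
})

test_that("the 2-dwell toy reaches the exhaustive grid-search optimum", {
  toy <- arm_toy()
  # exhaustive search over (t1, t2)
  tgrid <- seq(0, 120, length.out = 500)
  V <- outer(tgrid, tgrid, Vectorize(function(t1, t2) {
    toy_violation_objective(toy$rates, toy$points, c(t1, t2))
  }))
  best <- which(V == min(V), arr.ind = TRUE)[1, ]
  t_best <- c(tgrid[best[1]], tgrid[best[2]])
  # ARM loop on the same rates
  times <- c(10, 10)
  cfg <- arm_config(eta = 0.05, convergence_tol = 1e-8, max_iterations = 5000)
  for (it in 1:5000) {
    d <- as.vector(toy$rates %*% times)
    cm <- sweep(toy$rates, 2, times, "*"); cm <- cm / rowSums(cm)
    nt <- arm_step(times, arm_forces(d, cm, toy$points), cfg)
    if (max(abs(nt - times) / pmax(times, 1e-12)) < cfg$convergence_tol) {
      times <- nt; break
    }
    times <- nt
  }
  expect_equal(times, t_best, tolerance = 0.05)
})

test_that("the violation objective is non-increasing at small step size", {
  toy <- arm_toy()
  times <- c(10, 10)
  cfg <- arm_config(eta = 0.01)
  objs <- numeric(400)
  for (it in 1:400) {
    objs[it] <- toy_violation_objective(toy$rates, toy$points, times)
    d <- as.vector(toy$rates %*% times)
    cm <- sweep(toy$rates, 2, times, "*"); cm <- cm / rowSums(cm)
    times <- arm_step(times, arm_forces(d, cm, toy$points), cfg)
  }
  expect_true(all(diff(objs) <= 1e-12))
})

test_that("optimization is deterministic and respects the dwell-time floor", {
  dz <- 2
  structures <- structure_set(list(PTV = box_slices(c(0, 0, 0), c(8, 8, 8), dz),
                                   OAR = box_slices(c(12, 0, 0), c(4, 4, 4), dz)),
                              slice_thickness = dz)
  grid <- grid_spec(c(-5, -5, -5), c(2, 2, 2), c(10, 6, 6))
  plan <- dwell_plan(rbind(c(-2, 0, 0), c(2, 0, 0)), c(20, 20), n_fractions = 9)
  cons <- list(dose_constraint("PTV", lower = 54), dose_constraint("OAR", upper = 1))
  cfg <- arm_config(eta = 0.05, max_iterations = 150, min_dwell_time = 0.2)
  r1 <- optimize_arm(plan, structures, cons, grid, config = cfg, keep_snapshots = TRUE)
  r2 <- optimize_arm(plan, structures, cons, grid, config = cfg, keep_snapshots = TRUE)
  expect_identical(r1$trace, r2$trace)
  expect_identical(dwell_table(r1$plan)$time, dwell_table(r2$plan)$time)
  expect_true(all(r1$snapshots >= 0.2))
  # the input plan is unmodified
  expect_equal(dwell_table(plan)$time, c(20, 20))
})
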