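# Attraction-repulsion model (ARM) inverse planning.
#
# Every voxel of every constrained structure is an optimization point. At
# each iteration the total dose and the per-dwell contribution factor of
# every point are computed; points below their lower limit exert an
# attraction (dwell times increase), points above their upper limit a
# repulsion (dwell times decrease), each weighted by the fraction of the
# point's dose that the dwell delivers. The dwell-time update is
# multiplicative with a floor, which keeps times non-negative by
# construction and makes single-voxel fixed points solvable in closed form.

#' Dose constraint for one structure
#' @param structure Structure name.
#' @param lower,upper Lower / upper total-course dose limit in Gy, or `NULL`
#'   for one-sided constraints. `lower <= upper` when both are set.
#' @param weight Non-negative point weight (default 1).
#' @return Object of class `dose_constraint`.
#' @export
dose_constraint <- function(structure, lower = NULL, upper = NULL, weight = 1) {
  if (is.null(lower) && is.null(upper)) {
    stop("dose_constraint: at least one of lower/upper must be set", call. = FALSE)
  }
  if (!is.null(lower) && !is.null(upper) && lower > upper) {
    stop("dose_constraint: lower must be <= upper", call. = FALSE)
  }
  if (!is.finite(weight) || weight < 0) {
    stop("dose_constraint: weight must be >= 0", call. = FALSE)
  }
  structure(list(structure = as.character(structure),
                 lower = if (is.null(lower)) NA_real_ else as.numeric(lower),
                 upper = if (is.null(upper)) NA_real_ else as.numeric(upper),
                 weight = as.numeric(weight)),
            class = "dose_constraint")
}

#' ARM hyperparameters
#' @param eta Multiplicative step size (> 0, default 0.05).
#' @param max_iterations Iteration cap (default 500).
#' @param convergence_tol Stop when the maximum relative dwell-time change
#'   falls below this (default 1e-4).
#' @param min_dwell_time Dwell-time floor in seconds (default 0).
#' @param recompute_contributions_every Recompute contribution factors every
#'   k iterations (default 1).
#' @return Object of class `arm_config`.
#' @export
arm_config <- function(eta = 0.05, max_iterations = 500, convergence_tol = 1e-4,
                       min_dwell_time = 0, recompute_contributions_every = 1) {
  stopifnot(is.finite(eta), eta > 0,
            max_iterations >= 1,
            is.finite(convergence_tol), convergence_tol > 0,
            is.finite(min_dwell_time), min_dwell_time >= 0,
            recompute_contributions_every >= 1)
  structure(list(eta = eta, max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 min_dwell_time = min_dwell_time,
                 recompute_contributions_every = as.integer(recompute_contributions_every)),
            class = "arm_config")
}

#' Collect optimization points from constrained structures
#'
#' Every voxel of every constrained structure becomes one optimization point
#' carrying that structure's limits and weight; a voxel covered by two
#' constrained structures yields one point per constraint.
#'
#' @param structures A [structure_set()].
#' @param grid Rasterization [grid_spec()].
#' @param constraints List of [dose_constraint()]s.
#' @return Data frame with columns `structure`, `x`, `y`, `z` (voxel centers,
#'   mm), `lower`, `upper` (Gy, `NA` when one-sided), `weight`.
#' @export
collect_optimization_points <- function(structures, grid, constraints) {
  if (length(constraints) == 0L) {
    stop("collect_optimization_points: need at least one constraint", call. = FALSE)
  }
  centers <- grid_centers(grid)
  out <- lapply(constraints, function(con) {
    if (!con$structure %in% structure_names(structures)) {
      stop(sprintf("constraint names structure '%s' which is not in the structure set",
                   con$structure), call. = FALSE)
    }
    mask <- suppressWarnings(rasterize_structure(structures, con$structure, grid))
    idx <- which(mask$values)
    if (length(idx) == 0L) {
      warning(sprintf("constraint on '%s' selects no voxels on this grid", con$structure),
              call. = FALSE)
      return(NULL)
    }
    data.frame(structure = con$structure,
               x = centers[idx, 1], y = centers[idx, 2], z = centers[idx, 3],
               lower = con$lower, upper = con$upper, weight = con$weight,
               stringsAsFactors = FALSE)
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) {
    return(data.frame(structure = character(), x = numeric(), y = numeric(),
                      z = numeric(), lower = numeric(), upper = numeric(),
                      weight = numeric()))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# Per-dwell dose-rate matrix at the optimization points: entry (v, j) is the
# total-course dose (Gy) voxel v receives per second of dwell time at dwell
# j, including shield attenuation. Dose d_vj = rate_vj * t_j; this geometry
# factor is constant across ARM iterations.
dose_rate_matrix <- function(plan, points, shield = NULL, structures = NULL) {
  dw <- dwell_table(plan)
  src <- plan$source
  P <- as.matrix(points[, c("x", "y", "z")])
  nv <- nrow(P)
  block <- if (!is.null(shield)) shield_block_mask(shield, structures) else NULL
  rates <- matrix(0, nrow = nv, ncol = nrow(dw))
  for (j in seq_len(nrow(dw))) {
    p <- c(dw$x[j], dw$y[j], dw$z[j])
    rel <- cbind(P[, 1] - p[1], P[, 2] - p[2], P[, 3] - p[3])
    r <- sqrt(rowSums(rel^2))
    ct <- (rel[, 1] * dw$ax[j] + rel[, 2] * dw$ay[j] + rel[, 3] * dw$az[j]) / pmax(r, 1)
    ct[r < 1e-12] <- 0
    theta <- acos(pmin(pmax(ct, -1), 1)) * 180 / pi
    rate <- dose_rate_safe(src, r, theta)$rate / 3600
    if (!is.null(block)) {
      pl <- ray_path_lengths_cpp(matrix(p, nrow = 1), P,
                                 block$mask$values, block$mask$grid$shape,
                                 block$mask$grid$origin, block$mask$grid$spacing)
      rate <- rate * 2^(-pl / shield$half_value_layer)
    }
    rates[, j] <- rate
  }
  rates * plan$n_fractions
}

#' Per-dwell dose contribution factors
#'
#' Entry \eqn{c_{vj} = d_{vj} / \sum_k d_{vk}}: the fraction of optimization
#' point v's total dose delivered by dwell j (shield attenuation included).
#' Rows sum to 1 where the point receives any dose; a point receiving zero
#' dose yields a zero row, flagged in the `"zero_dose"` attribute.
#'
#' @param plan A [brachy_plan()] (dwell times >= 0, not all zero).
#' @param points Data frame from [collect_optimization_points()].
#' @param shield Optional [shield_model()] (with `structures`).
#' @param structures [structure_set()] holding the block contours.
#' @param rates Optional precomputed [dose_rate_matrix] (internal reuse).
#' @return Numeric matrix (points x dwells) with attribute `zero_dose`.
#' @export
contribution_matrix <- function(plan, points, shield = NULL, structures = NULL,
                                rates = NULL) {
  times <- dwell_table(plan)$time
  if (all(times == 0)) {
    stop("contribution_matrix: all dwell times are zero", call. = FALSE)
  }
  if (is.null(rates)) rates <- dose_rate_matrix(plan, points, shield, structures)
  d <- sweep(rates, 2, times, "*")
  tot <- rowSums(d)
  zero <- tot <= 0
  tot[zero] <- 1
  cmat <- d / tot
  cmat[zero, ] <- 0
  attr(cmat, "zero_dose") <- zero
  cmat
}

# violation score per point: positive attraction below the lower limit,
# negative repulsion above the upper limit, zero inside the limits
violation_scores <- function(doses, lower, upper) {
  s <- numeric(length(doses))
  att <- !is.na(lower) & doses < lower
  rep_ <- !is.na(upper) & doses > upper
  if (any(att & lower == 0) || any(rep_ & upper == 0)) {
    stop("arm_forces: violated constraint with a zero limit (relative violation undefined)",
         call. = FALSE)
  }
  s[att] <- (lower[att] - doses[att]) / lower[att]
  s[rep_] <- (upper[rep_] - doses[rep_]) / upper[rep_]
  s
}

#' Net attraction/repulsion force on each dwell position
#'
#' \eqn{f_j = \sum_v w_v c_{vj} s_v} with the relative violation score
#' \eqn{s_v = (L_v - D_v)/L_v > 0} for points below their lower limit
#' (attraction: the dwell time should grow) and
#' \eqn{s_v = (U_v - D_v)/U_v < 0} above the upper limit (repulsion); 0 for
#' points within their limits. Linear in the per-point weights.
#'
#' @param doses Per-point total dose, Gy (>= 0).
#' @param cmat [contribution_matrix()] (points x dwells).
#' @param points Data frame with `lower`, `upper`, `weight` per point.
#' @return Numeric per-dwell force vector (dimensionless).
#' @export
arm_forces <- function(doses, cmat, points) {
  if (any(doses < 0)) stop("arm_forces: doses must be >= 0", call. = FALSE)
  s <- violation_scores(doses, points$lower, points$upper)
  as.vector(crossprod(cmat, points$weight * s))
}

#' One multiplicative ARM dwell-time update
#'
#' \eqn{t_j \leftarrow \max(t_{\min}, t_j (1 + \eta f_j))}. Zero force leaves
#' a time unchanged; a large repulsion (\eqn{\eta f_j \le -1}) clamps to the
#' floor instead of going negative.
#'
#' @param times Per-dwell times, s (>= 0).
#' @param forces Per-dwell forces from [arm_forces()].
#' @param config An [arm_config()].
#' @return Updated times.
#' @export
arm_step <- function(times, forces, config) {
  if (any(times < 0)) stop("arm_step: times must be >= 0", call. = FALSE)
  pmax(config$min_dwell_time, times * (1 + config$eta * forces))
}

# violation objective: sum of w * (relative excess + relative deficit)^2
violation_objective <- function(doses, points) {
  lo <- points$lower; up <- points$upper
  deficit <- ifelse(!is.na(lo) & doses < lo, (lo - doses) / lo, 0)
  excess <- ifelse(!is.na(up) & doses > up, (doses - up) / up, 0)
  sum(points$weight * (deficit + excess)^2)
}

#' ARM inverse optimization of dwell times
#'
#' Iterates dose accumulation, attraction/repulsion force computation, and
#' multiplicative dwell-time feedback until the maximum relative dwell-time
#' change drops below `convergence_tol` or `max_iterations` is reached. A
#' plan already satisfying every constraint generates zero force and is
#' returned unchanged. If the violation objective rises for 10 consecutive
#' iterations the step size is halved (divergence guard); after 3 halvings
#' the loop aborts with a diagnostic. Fully deterministic.
#'
#' @param plan Initial [brachy_plan()] with positive total dwell time.
#' @param structures A [structure_set()].
#' @param constraints List of [dose_constraint()]s (>= 1).
#' @param grid [grid_spec()] used to rasterize the constrained structures.
#' @param shield Optional [shield_model()]; optimization is then
#'   attenuation-aware.
#' @param config An [arm_config()].
#' @param keep_snapshots Record the dwell-time vector each iteration.
#' @return List with `plan` (optimized; input unmodified), `trace` (data
#'   frame: `iteration`, `objective`, `max_rel_change`, `eta`), `converged`,
#'   `aborted`, and optionally `snapshots` (matrix, iterations x dwells).
#' @export
optimize_arm <- function(plan, structures, constraints, grid, shield = NULL,
                         config = arm_config(), keep_snapshots = FALSE) {
  points <- collect_optimization_points(structures, grid, constraints)
  if (is.null(points) || nrow(points) == 0L) {
    stop("optimize_arm: no optimization points (empty constrained structures)",
         call. = FALSE)
  }
  times <- dwell_table(plan)$time
  if (sum(times) <= 0) {
    stop("optimize_arm: initial plan must have positive total dwell time", call. = FALSE)
  }
  rates <- dose_rate_matrix(plan, points, shield, structures)
  eta <- config$eta
  cfg <- config
  prev_obj <- Inf
  rises <- 0L
  halvings <- 0L
  aborted <- FALSE
  converged <- FALSE
  trace <- vector("list", config$max_iterations)
  snaps <- if (keep_snapshots) vector("list", config$max_iterations) else NULL
  cmat <- NULL
  for (it in seq_len(config$max_iterations)) {
    doses <- as.vector(rates %*% times)
    obj <- violation_objective(doses, points)
    if (is.null(cmat) || (it - 1L) %% config$recompute_contributions_every == 0L) {
      d <- sweep(rates, 2, times, "*")
      tot <- rowSums(d)
      zero <- tot <= 0
      tot[zero] <- 1
      cmat <- d / tot
      cmat[zero, ] <- 0
    }
    forces <- arm_forces(doses, cmat, points)
    cfg$eta <- eta
    new_times <- arm_step(times, forces, cfg)
    denom <- pmax(times, .Machine$double.eps)
    max_rel <- max(abs(new_times - times) / denom)
    trace[[it]] <- data.frame(iteration = it, objective = obj,
                              max_rel_change = max_rel, eta = eta)
    if (keep_snapshots) snaps[[it]] <- new_times
    times <- new_times
    if (sum(times) <= 0) {
      warning("optimize_arm: repulsion drove every dwell time to zero; aborting",
              call. = FALSE)
      aborted <- TRUE
      break
    }
    if (obj > prev_obj + 1e-15) rises <- rises + 1L else rises <- 0L
    if (rises >= 10L) {
      halvings <- halvings + 1L
      rises <- 0L
      if (halvings > 3L) {
        warning("optimize_arm: objective kept rising after 3 step-size halvings; aborting",
                call. = FALSE)
        aborted <- TRUE
        break
      }
      eta <- eta / 2
    }
    prev_obj <- obj
    if (max_rel < config$convergence_tol) {
      converged <- TRUE
      break
    }
  }
  trace <- do.call(rbind, trace[!vapply(trace, is.null, logical(1))])
  out <- list(plan = set_dwell_times(plan, times), trace = trace,
              converged = converged, aborted = aborted)
  if (keep_snapshots) {
    out$snapshots <- do.call(rbind, snaps[seq_len(nrow(trace))])
  }
  out
}

#' Export an optimization trace to CSV
#' @param result Result of [optimize_arm()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(result, path) {
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}
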