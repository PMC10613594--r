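#' HDR treatment plan
#'
#' A plan holds the source description, the catheters with their ordered
#' dwell positions and per-fraction dwell times (the inverse-planning decision
#' variables), and the prescription. The default prescription is 54 Gy in 9
#' fractions.
#'
#' @param source A [source_model()].
#' @param catheters List of catheter records, each `list(id =, dwells =)`
#'   where `dwells` is a data frame with columns `x`, `y`, `z` (mm) and
#'   `time` (seconds per fraction, >= 0), ordered along the catheter.
#' @param prescription_dose Total prescription dose over the course, Gy.
#' @param n_fractions Number of fractions, integer > 0.
#' @return Object of class `brachy_plan`.
#' @export
brachy_plan <- function(source, catheters, prescription_dose = 54, n_fractions = 9) {
  stopifnot(inherits(source, "source_model"))
  if (!is.finite(prescription_dose) || prescription_dose <= 0) {
    stop("brachy_plan: prescription_dose must be > 0", call. = FALSE)
  }
  n_fractions <- as.integer(n_fractions)
  if (is.na(n_fractions) || n_fractions < 1L) {
    stop("brachy_plan: n_fractions must be a positive integer", call. = FALSE)
  }
  if (length(catheters) < 1L) {
    stop("brachy_plan: need at least one catheter", call. = FALSE)
  }
  catheters <- lapply(seq_along(catheters), function(i) {
    cat_i <- catheters[[i]]
    if (is.null(cat_i$id)) cat_i$id <- as.character(i)
    dw <- as.data.frame(cat_i$dwells)
    req <- c("x", "y", "z", "time")
    if (!all(req %in% names(dw))) {
      stop(sprintf("brachy_plan: catheter '%s' dwells need columns x, y, z, time", cat_i$id),
           call. = FALSE)
    }
    dw <- dw[, req]
    if (nrow(dw) < 1L) {
      stop(sprintf("brachy_plan: catheter '%s' has no dwell positions", cat_i$id), call. = FALSE)
    }
    if (any(!is.finite(as.matrix(dw)))) {
      stop(sprintf("brachy_plan: catheter '%s' has non-finite dwell fields", cat_i$id),
           call. = FALSE)
    }
    if (any(dw$time < 0)) {
      stop(sprintf("brachy_plan: negative dwell time in catheter '%s'", cat_i$id), call. = FALSE)
    }
    list(id = as.character(cat_i$id), dwells = dw)
  })
  ids <- vapply(catheters, function(catheter) catheter$id, character(1))
  if (anyDuplicated(ids)) {
    stop("brachy_plan: catheter ids must be unique", call. = FALSE)
  }
  structure(list(source = source, catheters = catheters,
                 prescription_dose = as.numeric(prescription_dose),
                 n_fractions = n_fractions),
            class = "brachy_plan")
}

#' @export
print.brachy_plan <- function(x, ...) {
  dw <- dwell_table(x)
  cat(sprintf("<brachy_plan> %d catheters, %d dwell positions, total dwell time %.1f s/fraction\n",
              length(x$catheters), nrow(dw), sum(dw$time)))
  cat(sprintf("  prescription %g Gy / %d fractions; S_k = %g U\n",
              x$prescription_dose, x$n_fractions, x$source$air_kerma_strength))
  invisible(x)
}

#' Flat dwell-position table of a plan
#'
#' @param plan A [brachy_plan()].
#' @return Data frame with one row per dwell position: `catheter_id`, `index`
#'   (0-based position along the catheter), `x`, `y`, `z` (mm), `time` (s),
#'   and the unit catheter direction `ax`, `ay`, `az` at the dwell (central
#'   difference of neighboring dwell positions; `(0, 0, 1)` for single-dwell
#'   catheters), used as the source long axis for anisotropy evaluation.
#' @export
dwell_table <- function(plan) {
  rows <- lapply(plan$catheters, function(cat_i) {
    dw <- cat_i$dwells
    n <- nrow(dw)
    P <- as.matrix(dw[, c("x", "y", "z")])
    axes <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
    if (n > 1L) {
      nxt <- P[pmin(seq_len(n) + 1L, n), , drop = FALSE]
      prv <- P[pmax(seq_len(n) - 1L, 1L), , drop = FALSE]
      d <- nxt - prv
      len <- sqrt(rowSums(d^2))
      ok <- len > 0
      axes[ok, ] <- d[ok, , drop = FALSE] / len[ok]
    }
    data.frame(catheter_id = cat_i$id, index = seq_len(n) - 1L,
               x = dw$x, y = dw$y, z = dw$z, time = dw$time,
               ax = axes[, 1], ay = axes[, 2], az = axes[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Replace the dwell times of a plan
#'
#' @param plan A [brachy_plan()].
#' @param times Numeric vector, one per dwell position in [dwell_table()]
#'   order (catheters in order, dwells along each catheter); all >= 0.
#' @return A new plan; the input is unmodified.
#' @export
set_dwell_times <- function(plan, times) {
  counts <- vapply(plan$catheters, function(cat_i) nrow(cat_i$dwells), integer(1))
  if (length(times) != sum(counts) || any(!is.finite(times)) || any(times < 0)) {
    stop("set_dwell_times: times must be non-negative, one per dwell position",
         call. = FALSE)
  }
  off <- 0L
  for (i in seq_along(plan$catheters)) {
    n <- counts[i]
    plan$catheters[[i]]$dwells$time <- times[off + seq_len(n)]
    off <- off + n
  }
  plan
}

#' Multiply all dwell times by a scalar
#' @param plan A [brachy_plan()].
#' @param scale Positive scalar.
#' @return A new plan.
#' @export
scale_dwell_times <- function(plan, scale) {
  stopifnot(is.finite(scale), scale >= 0)
  set_dwell_times(plan, dwell_table(plan)$time * scale)
}
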