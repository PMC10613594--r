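#' HDR source model for the TG-43 formalism
#'
#' Physical description of one HDR stepping source: air-kerma strength
#' \eqn{S_K} (U = uGy m^2 / h), dose-rate constant \eqn{\Lambda}
#' (cGy / (h U)), active length \eqn{L} (mm), and sampled radial-dose
#' \eqn{g(r)} and anisotropy tables. The reference point of the formalism is
#' \eqn{r_0 = 10} mm, \eqn{\theta_0 = 90^\circ}; tables must be normalized
#' there.
#'
#' @param air_kerma_strength \eqn{S_K} in U, > 0.
#' @param dose_rate_constant \eqn{\Lambda} in cGy h^-1 U^-1, > 0.
#' @param active_length Active source length \eqn{L} in mm, >= 0. `0` selects
#'   the point-source geometry factor \eqn{1/r^2}.
#' @param radial_dose `NULL` (\eqn{g \equiv 1}) or a data frame with columns
#'   `r` (mm) and `g`; linearly interpolated, held at the boundary outside the
#'   tabulated range.
#' @param anisotropy `NULL` (\eqn{F \equiv 1}), a data frame with columns `r`
#'   and `phi` (1D isotropically averaged anisotropy \eqn{\phi_{an}(r)}), or a
#'   list `list(r =, theta =, F =)` with `F` a `length(r) x length(theta)`
#'   matrix (full 2D \eqn{F(r, \theta)}, theta in degrees).
#' @return Object of class `source_model`.
#' @export
source_model <- function(air_kerma_strength = 40800,
                         dose_rate_constant = 1.109,
                         active_length = 3.6,
                         radial_dose = NULL,
                         anisotropy = NULL) {
  if (!is.finite(air_kerma_strength) || air_kerma_strength <= 0) {
    stop("source_model: air_kerma_strength must be > 0", call. = FALSE)
  }
  if (!is.finite(dose_rate_constant) || dose_rate_constant <= 0) {
    stop("source_model: dose_rate_constant must be > 0", call. = FALSE)
  }
  if (!is.finite(active_length) || active_length < 0) {
    stop("source_model: active_length must be >= 0", call. = FALSE)
  }
  if (!is.null(radial_dose)) {
    radial_dose <- as.data.frame(radial_dose)
    if (!all(c("r", "g") %in% names(radial_dose))) {
      stop("source_model: radial_dose needs columns 'r' and 'g'", call. = FALSE)
    }
    radial_dose <- radial_dose[order(radial_dose$r), , drop = FALSE]
    g0 <- approx(radial_dose$r, radial_dose$g, xout = 10, rule = 2)$y
    if (abs(g0 - 1) > 1e-3) {
      stop(sprintf("source_model: g(r) must be normalized at r0 = 10 mm (got g(10) = %.4f)", g0),
           call. = FALSE)
    }
  }
  if (!is.null(anisotropy)) {
    if (is.data.frame(anisotropy) || (is.list(anisotropy) && all(c("r", "phi") %in% names(anisotropy)) && is.null(anisotropy$F))) {
      anisotropy <- as.data.frame(anisotropy)
      anisotropy <- anisotropy[order(anisotropy$r), , drop = FALSE]
    } else if (is.list(anisotropy) && all(c("r", "theta", "F") %in% names(anisotropy))) {
      anisotropy$F <- as.matrix(anisotropy$F)
      if (!all(dim(anisotropy$F) == c(length(anisotropy$r), length(anisotropy$theta)))) {
        stop("source_model: anisotropy F matrix must be length(r) x length(theta)", call. = FALSE)
      }
      F0 <- bilinear_lookup(anisotropy$r, anisotropy$theta, anisotropy$F, 10, 90)
      if (abs(F0 - 1) > 1e-3) {
        stop(sprintf("source_model: F(r, theta) must be normalized at (10 mm, 90 deg) (got %.4f)", F0),
             call. = FALSE)
      }
    } else {
      stop("source_model: anisotropy must be NULL, an (r, phi) table, or list(r, theta, F)",
           call. = FALSE)
    }
  }
  structure(list(air_kerma_strength = air_kerma_strength,
                 dose_rate_constant = dose_rate_constant,
                 active_length = active_length,
                 radial_dose = radial_dose,
                 anisotropy = anisotropy),
            class = "source_model")
}

#' @export
print.source_model <- function(x, ...) {
  cat(sprintf("<source_model> S_k = %g U, Lambda = %g cGy/(h U), L = %g mm\n",
              x$air_kerma_strength, x$dose_rate_constant, x$active_length))
  cat(sprintf("  g(r): %s;  anisotropy: %s\n",
              if (is.null(x$radial_dose)) "unity" else sprintf("%d-point table", nrow(x$radial_dose)),
              if (is.null(x$anisotropy)) "unity"
              else if (is.data.frame(x$anisotropy)) "1D phi_an(r)"
              else "2D F(r, theta)"))
  invisible(x)
}

# clamped linear interpolation of a table column
interp_clamped <- function(x, y, xq) {
  approx(x, y, xout = pmin(pmax(xq, min(x)), max(x)), rule = 2)$y
}

# clamped bilinear lookup on an (r, theta) grid
bilinear_lookup <- function(rg, tg, M, rq, tq) {
  rq <- pmin(pmax(rq, min(rg)), max(rg))
  tq <- pmin(pmax(tq, min(tg)), max(tg))
  i <- findInterval(rq, rg, rightmost.closed = TRUE)
  j <- findInterval(tq, tg, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(rg) - 1L)
  j <- pmin(pmax(j, 1L), length(tg) - 1L)
  wr <- (rq - rg[i]) / (rg[i + 1] - rg[i])
  wt <- (tq - tg[j]) / (tg[j + 1] - tg[j])
  nr <- length(rg)
  m <- M
  m00 <- m[i + (j - 1) * nr]; m10 <- m[i + 1 + (j - 1) * nr]
  m01 <- m[i + j * nr]; m11 <- m[i + 1 + j * nr]
  (m00 * (1 - wr) + m10 * wr) * (1 - wt) + (m01 * (1 - wr) + m11 * wr) * wt
}

# g(r) with boundary clamping; warns once per call when clamping occurs
radial_dose_at <- function(source, r, warn = FALSE) {
  if (is.null(source$radial_dose)) return(rep(1, length(r)))
  tab <- source$radial_dose
  if (warn && (any(r < min(tab$r)) || any(r > max(tab$r)))) {
    warning("radial distance outside g(r) table range; boundary value held", call. = FALSE)
  }
  interp_clamped(tab$r, tab$g, r)
}

# anisotropy factor at (r, theta); theta in degrees
anisotropy_at <- function(source, r, theta) {
  an <- source$anisotropy
  if (is.null(an)) return(rep(1, length(r)))
  if (is.data.frame(an)) return(interp_clamped(an$r, an$phi, r))
  bilinear_lookup(an$r, an$theta, an$F, r, theta)
}

#' Read source characterization tables from columnar text files
#'
#' The radial-dose file has two whitespace-separated columns `r_mm g`; the
#' anisotropy file either two columns `r_mm phi` (1D averaged anisotropy) or
#' a grid block: a first line `theta: t1 t2 ...` followed by rows
#' `r F(r,t1) F(r,t2) ...`. Lines starting with `#` are comments.
#'
#' @param radial_path Path to the radial-dose table, or `NULL`.
#' @param anisotropy_path Path to the anisotropy table, or `NULL`.
#' @param ... Passed to [source_model()] (strength, constant, length).
#' @return A [source_model()].
#' @export
read_source_tables <- function(radial_path = NULL, anisotropy_path = NULL, ...) {
  rd <- NULL
  if (!is.null(radial_path)) {
    m <- read_table_body(radial_path)
    rd <- data.frame(r = m[, 1], g = m[, 2])
  }
  an <- NULL
  if (!is.null(anisotropy_path)) {
    lines <- readLines(anisotropy_path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (grepl("^theta:", lines[1])) {
      theta <- as.numeric(strsplit(sub("^theta:\\s*", "", lines[1]), "\\s+")[[1]])
      body <- do.call(rbind, lapply(lines[-1], function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
      an <- list(r = body[, 1], theta = theta, F = body[, -1, drop = FALSE])
    } else {
      body <- do.call(rbind, lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
      an <- data.frame(r = body[, 1], phi = body[, 2])
    }
  }
  source_model(radial_dose = rd, anisotropy = an, ...)
}

read_table_body <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  do.call(rbind, lapply(lines, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
}

#' Bundled toy source model
#'
#' A smooth synthetic Ir-192-like source (active length 3.6 mm, dose-rate
#' constant 1.109 cGy h^-1 U^-1) with small bundled g(r) and F(r, theta)
#' tables, normalized at the TG-43 reference point. The tables are synthetic
#' stand-ins for consensus data so the package builds and tests without any
#' external download; measured consensus tables for a real source are loaded
#' with [read_source_tables()].
#'
#' @param air_kerma_strength \eqn{S_K} in U (default 40800, ~10 Ci).
#' @return A [source_model()].
#' @export
toy_source <- function(air_kerma_strength = 40800) {
  read_source_tables(
    radial_path = system.file("extdata", "toy_source_radial_synthetic.tsv",
                              package = "brachyshield", mustWork = TRUE),
    anisotropy_path = system.file("extdata", "toy_source_anisotropy_synthetic.tsv",
                                  package = "brachyshield", mustWork = TRUE),
    air_kerma_strength = air_kerma_strength,
    dose_rate_constant = 1.109,
    active_length = 3.6)
}
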