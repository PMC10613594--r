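#' Planar contour slice
#'
#' One closed polygon ring at constant z. Vertices are an ordered `n x 2`
#' matrix of `(x, y)` mm; the ring is implicitly closed (last vertex connects
#' back to the first) and must be simple (non-self-intersecting).
#'
#' @param z Slice position, mm.
#' @param vertices `n x 2` numeric matrix (n >= 3) of `(x, y)` mm.
#' @return Object of class `contour_slice`.
#' @export
contour_slice <- function(z, vertices) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (!is.finite(z)) stop("contour_slice: z must be finite", call. = FALSE)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L || any(!is.finite(vertices))) {
    stop("contour_slice: vertices must be a finite n x 2 matrix with n >= 3",
         call. = FALSE)
  }
  if (ring_self_intersects(vertices)) {
    stop("contour_slice: ring is self-intersecting", call. = FALSE)
  }
  structure(list(z = as.numeric(z), vertices = vertices), class = "contour_slice")
}

# Segment-intersection test for ring simplicity (O(n^2); contours are small).
ring_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  seg <- cbind(v, v[c(2:n, 1L), , drop = FALSE])
  for (i in seq_len(n - 2L)) {
    jmax <- if (i == 1L) n - 1L else n
    for (j in (i + 2L):jmax) {
      if (segments_cross(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

#' Named set of contour stacks
#'
#' Maps structure names (PTV, mandible, lead block, ...) to z-sorted stacks of
#' [contour_slice()]s. Structure names must be unique; slices of one structure
#' must have strictly increasing z after sorting.
#'
#' @param structures Named list; each element a list of [contour_slice()]s
#'   (or bare `list(z =, vertices =)` records, which are validated).
#' @param slice_thickness Longitudinal slice thickness in mm (> 0); sets the
#'   z extent each contour represents (half a thickness either side).
#' @return Object of class `structure_set`.
#' @export
structure_set <- function(structures, slice_thickness) {
  if (!is.finite(slice_thickness) || slice_thickness <= 0) {
    stop("structure_set: slice_thickness must be > 0", call. = FALSE)
  }
  nm <- names(structures)
  if (is.null(nm) || any(nm == "") ) {
    stop("structure_set: structures must be a named list", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("structure_set: duplicate structure name '%s'", nm[duplicated(nm)][1]),
         call. = FALSE)
  }
  structures <- lapply(structures, function(slices) {
    slices <- lapply(slices, function(s) {
      if (inherits(s, "contour_slice")) s else contour_slice(s$z, s$vertices)
    })
    zs <- vapply(slices, function(s) s$z, numeric(1))
    slices <- slices[order(zs)]
    zs <- sort(zs)
    if (length(zs) > 1L && any(diff(zs) <= 0)) {
      stop("structure_set: slice z values must be strictly increasing within a structure",
           call. = FALSE)
    }
    slices
  })
  structure(list(structures = structures, slice_thickness = as.numeric(slice_thickness)),
            class = "structure_set")
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures, slice thickness %g mm\n",
              length(x$structures), x$slice_thickness))
  for (nm in names(x$structures)) {
    cat(sprintf("  %-12s %d slices\n", nm, length(x$structures[[nm]])))
  }
  invisible(x)
}

#' Structure names of a set
#' @param set A [structure_set()].
#' @return Character vector.
#' @export
structure_names <- function(set) names(set$structures)

get_structure <- function(set, name) {
  if (!name %in% names(set$structures)) {
    stop(sprintf("structure '%s' not present in the structure set (have: %s)",
                 name, paste(names(set$structures), collapse = ", ")), call. = FALSE)
  }
  set$structures[[name]]
}

# axis-aligned bounding box of one structure: matrix 2x3 (min; max)
structure_bbox <- function(set, name) {
  slices <- get_structure(set, name)
  xs <- unlist(lapply(slices, function(s) s$vertices[, 1]))
  ys <- unlist(lapply(slices, function(s) s$vertices[, 2]))
  zs <- vapply(slices, function(s) s$z, numeric(1))
  half <- set$slice_thickness / 2
  rbind(min = c(min(xs), min(ys), min(zs) - half),
        max = c(max(xs), max(ys), max(zs) + half))
}

# translate one structure's contours by a 3-vector (used by phantom perturbation)
translate_structure <- function(set, name, delta) {
  slices <- get_structure(set, name)
  slices <- lapply(slices, function(s) {
    contour_slice(s$z + delta[3], sweep(s$vertices, 2, delta[1:2], "+"))
  })
  set$structures[[name]] <- slices
  set
}
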