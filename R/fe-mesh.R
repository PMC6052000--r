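#' Cell geometry for the contraction simulation
#'
#' The cell is a prolate spheroid (major axis along the tendon/z axis) of
#' equivalent radius \code{a} — the radius of the sphere with the same
#' volume — and aspect ratio major/minor. Contraction removes
#' \code{contraction_volume_fraction} of the cell volume (default 5 %,
#' i.e. the cell shrinks to 95 % of its original volume), applied either
#' isotropically or along the axis only (\code{"axial"} polarization).
#'
#' @param a equivalent radius, micrometres (> 0).
#' @param aspect_ratio major/minor axis ratio (>= 1; 1 = rounded,
#'   larger = spindle).
#' @param contraction_volume_fraction fraction of volume lost (in (0, 1)).
#' @param polarization \code{"isotropic"} or \code{"axial"}.
#' @return object of class \code{"cell_geometry"} with derived semi-axes
#'   \code{a_r} (equatorial) and \code{a_z} (polar).
#' @export
cell_geometry <- function(a = 5, aspect_ratio = 1,
                          contraction_volume_fraction = 0.05,
                          polarization = c("isotropic", "axial")) {
  polarization <- match.arg(polarization)
  if (a <= 0) stop("'a' must be > 0")
  if (aspect_ratio < 1) stop("'aspect_ratio' must be >= 1")
  if (contraction_volume_fraction <= 0 || contraction_volume_fraction >= 1)
    stop("'contraction_volume_fraction' must be in (0, 1)")
  structure(list(a = a, aspect_ratio = aspect_ratio,
                 contraction_volume_fraction = contraction_volume_fraction,
                 polarization = polarization,
                 a_r = a / aspect_ratio^(1 / 3),
                 a_z = a * aspect_ratio^(2 / 3)),
            class = "cell_geometry")
}

#' Mesh sizing specification
#'
#' @param near_size element size at the cell surface, micrometres.
#' @param far_size element size at the outer boundary, micrometres.
#' @param R_out domain (outer) radius, micrometres.
#' @return object of class \code{"mesh_spec"}.
#' @export
mesh_spec <- function(near_size = 1, far_size = 6, R_out = 100) {
  if (!(near_size < far_size && far_size < R_out))
    stop("need near_size < far_size < R_out")
  structure(list(near_size = near_size, far_size = far_size, R_out = R_out),
            class = "mesh_spec")
}

#' Build the axisymmetric mesh around a contracting cell
#'
#' Quarter-domain axisymmetric half-plane mesh: an elliptical cavity (the
#' cell) at the origin inside a quarter disc of radius \code{R_out}, meshed
#' with 3-node triangles by transfinite interpolation between the cavity
#' ellipse and the outer circle. Radial layer thicknesses grow geometrically
#' from \code{near_size} at the cavity to \code{far_size} at the outer
#' boundary; the angular division is set by the near size on the cavity arc.
#' Symmetry edges (the z axis and the z = 0 midplane) are marked.
#'
#' @param cell a [cell_geometry()].
#' @param spec a [mesh_spec()].
#' @return object of class \code{"axisym_mesh"}: \code{nodes} (N x 2 matrix,
#'   columns r, z, reference coordinates), \code{tri} (M x 3 node indices),
#'   \code{cavity}, \code{outer}, \code{axis}, \code{midplane} (node index
#'   vectors), \code{min_angle} (degrees), plus the generating \code{cell}
#'   and \code{spec}.
#' @export
build_mesh <- function(cell, spec = mesh_spec()) {
  stopifnot(inherits(cell, "cell_geometry"), inherits(spec, "mesh_spec"))
  a_r <- cell$a_r; a_z <- cell$a_z; R <- spec$R_out
  if (max(a_r, a_z) >= R / 2)
    stop("unmeshable geometry: cavity too large for the domain")
  # geometric radial grading from near_size to far_size
  dist <- R - max(a_r, a_z)
  h0 <- spec$near_size; h1 <- spec$far_size
  nl <- 2L
  repeat {
    g <- (h1 / h0)^(1 / (nl - 1))
    S <- h0 * if (abs(g - 1) < 1e-12) nl else (g^nl - 1) / (g - 1)
    if (S >= dist || nl > 10000L) break
    nl <- nl + 1L
  }
  th <- h0 * g^(0:(nl - 1))
  s <- c(0, cumsum(th)) / sum(th)         # radial fractions 0..1
  # angular divisions from the quarter-ellipse arc and the near size
  arc <- (pi / 2) * sqrt((a_r^2 + a_z^2) / 2)
  nphi <- max(8L, ceiling(arc / h0))
  phi <- seq(0, pi / 2, length.out = nphi + 1)
  # transfinite interpolation between cavity and outer circle
  nr <- length(s)
  cav <- cbind(a_r * cos(phi), a_z * sin(phi))
  out <- cbind(R * cos(phi), R * sin(phi))
  nodes <- matrix(0, nr * (nphi + 1), 2)
  for (i in seq_len(nr))
    nodes[((i - 1) * (nphi + 1) + 1):(i * (nphi + 1)), ] <-
      (1 - s[i]) * cav + s[i] * out
  nid <- function(i, j) (i - 1L) * (nphi + 1L) + j  # layer i, angle j
  tri <- matrix(0L, 0, 3)
  tris <- vector("list", (nr - 1) * nphi)
  k <- 0L
  for (i in seq_len(nr - 1)) for (j in seq_len(nphi)) {
    n1 <- nid(i, j); n2 <- nid(i, j + 1L)
    n3 <- nid(i + 1L, j); n4 <- nid(i + 1L, j + 1L)
    # split each quad along its shorter diagonal
    d14 <- sum((nodes[n1, ] - nodes[n4, ])^2)
    d23 <- sum((nodes[n2, ] - nodes[n3, ])^2)
    k <- k + 1L
    tris[[k]] <- if (d14 <= d23)
      rbind(c(n1, n3, n4), c(n1, n4, n2)) else
        rbind(c(n1, n3, n2), c(n2, n3, n4))
  }
  tri <- do.call(rbind, tris)
  # orient all triangles counter-clockwise
  v1 <- nodes[tri[, 2], ] - nodes[tri[, 1], ]
  v2 <- nodes[tri[, 3], ] - nodes[tri[, 1], ]
  detA <- v1[, 1] * v2[, 2] - v1[, 2] * v2[, 1]
  flip <- detA < 0
  tri[flip, c(2, 3)] <- tri[flip, c(3, 2)]
  # element quality: minimum interior angle
  ang <- function(p, q, r) {
    u <- q - p; v <- r - p
    acos(pmin(pmax(rowSums(u * v) /
                     sqrt(rowSums(u^2) * rowSums(v^2)), -1), 1))
  }
  P1 <- nodes[tri[, 1], ]; P2 <- nodes[tri[, 2], ]; P3 <- nodes[tri[, 3], ]
  min_angle <- min(ang(P1, P2, P3), ang(P2, P3, P1), ang(P3, P1, P2)) *
    180 / pi
  structure(list(nodes = nodes, tri = tri,
                 cavity = nid(1L, seq_len(nphi + 1L)),
                 outer = nid(nr, seq_len(nphi + 1L)),
                 axis = nid(seq_len(nr), nphi + 1L),      # phi = 90: r = 0
                 midplane = nid(seq_len(nr), 1L),         # phi = 0: z = 0
                 min_angle = min_angle, cell = cell, spec = spec),
            class = "axisym_mesh")
}

#' @export
print.axisym_mesh <- function(x, ...) {
  cat(sprintf(
    "Axisymmetric mesh: %d nodes, %d triangles, min angle %.1f deg\n",
    nrow(x$nodes), nrow(x$tri), x$min_angle))
  cat(sprintf("  cavity a_r = %.3g, a_z = %.3g um; R_out = %g um\n",
              x$cell$a_r, x$cell$a_z, x$spec$R_out))
  invisible(x)
}

#' @export
plot.axisym_mesh <- function(x, ...) {
  graphics::plot(x$nodes, type = "n", asp = 1, xlab = "r (um)",
                 ylab = "z (um)", ...)
  graphics::segments(x$nodes[x$tri[, 1], 1], x$nodes[x$tri[, 1], 2],
                     x$nodes[x$tri[, 2], 1], x$nodes[x$tri[, 2], 2],
                     col = "grey60")
  graphics::segments(x$nodes[x$tri[, 2], 1], x$nodes[x$tri[, 2], 2],
                     x$nodes[x$tri[, 3], 1], x$nodes[x$tri[, 3], 2],
                     col = "grey60")
  graphics::segments(x$nodes[x$tri[, 3], 1], x$nodes[x$tri[, 3], 2],
                     x$nodes[x$tri[, 1], 1], x$nodes[x$tri[, 1], 2],
                     col = "grey60")
  invisible(x)
}
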