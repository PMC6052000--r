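# Axisymmetric finite-element solver for a contracting cell in the fibrous
# matrix. Total Lagrangian formulation on 3-node triangles with one-point
# quadrature; the hoop stretch is evaluated at the element centroid. All
# element quantities are vectorized across elements; the consistent tangent
# is assembled from central differences of the element internal force.

# element precomputation: shape-function gradients, areas, centroid radii
.fe_setup <- function(mesh) {
  nd <- mesh$nodes; tri <- mesh$tri
  P1 <- nd[tri[, 1], ]; P2 <- nd[tri[, 2], ]; P3 <- nd[tri[, 3], ]
  detA <- (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
    (P3[, 1] - P1[, 1]) * (P2[, 2] - P1[, 2])
  A <- detA / 2
  b <- cbind(P2[, 2] - P3[, 2], P3[, 2] - P1[, 2], P1[, 2] - P2[, 2]) / detA
  c_ <- cbind(P3[, 1] - P2[, 1], P1[, 1] - P3[, 1], P2[, 1] - P1[, 1]) / detA
  Rc <- (P1[, 1] + P2[, 1] + P3[, 1]) / 3
  list(A = A, b = b, c = c_, Rc = Rc, w = 2 * pi * A * Rc,
       tri = tri, nnode = nrow(nd))
}

# internal nodal forces for all elements given element displacement matrix
# Ue (M x 6: ur1 ur2 ur3 uz1 uz2 uz3); returns list(f = M x 6, ok = logical)
.fe_internal <- function(Ue, fe, params) {
  b <- fe$b; c_ <- fe$c; Rc <- fe$Rc; w <- fe$w
  ur <- Ue[, 1:3, drop = FALSE]; uz <- Ue[, 4:6, drop = FALSE]
  F11 <- 1 + rowSums(b * ur); F12 <- rowSums(c_ * ur)
  F21 <- rowSums(b * uz);     F22 <- 1 + rowSums(c_ * uz)
  F33 <- 1 + rowMeans(ur) / Rc
  d <- F11 * F22 - F12 * F21
  J <- d * F33
  if (any(J <= 0)) return(list(ok = FALSE))
  # in-plane left Cauchy-Green and its principal decomposition
  B11 <- F11^2 + F12^2; B12 <- F11 * F21 + F12 * F22; B22 <- F21^2 + F22^2
  half <- (B11 - B22) / 2
  disc <- sqrt(half^2 + B12^2)
  e1 <- (B11 + B22) / 2 + disc; e2 <- (B11 + B22) / 2 - disc
  l1 <- sqrt(pmax(e1, 1e-300)); l2 <- sqrt(pmax(e2, 1e-300)); l3 <- F33
  s <- principal_cauchy(cbind(l1, l2, l3), params)
  th <- 0.5 * atan2(2 * B12, B11 - B22)   # major principal axis angle
  ct <- cos(th); st <- sin(th)
  s11 <- ct^2 * s[, 1] + st^2 * s[, 2]
  s22 <- st^2 * s[, 1] + ct^2 * s[, 2]
  s12 <- ct * st * (s[, 1] - s[, 2])
  s33 <- s[, 3]
  # first Piola-Kirchhoff P = J sigma F^{-T} (block in-plane + hoop)
  Fi11 <- F22 / d; Fi12 <- -F12 / d; Fi21 <- -F21 / d; Fi22 <- F11 / d
  P11 <- J * (s11 * Fi11 + s12 * Fi12)
  P12 <- J * (s11 * Fi21 + s12 * Fi22)
  P21 <- J * (s12 * Fi11 + s22 * Fi12)
  P22 <- J * (s12 * Fi21 + s22 * Fi22)
  P33 <- d * s33
  f <- cbind(w * (P11 * b[, 1] + P12 * c_[, 1] + P33 / (3 * Rc)),
             w * (P11 * b[, 2] + P12 * c_[, 2] + P33 / (3 * Rc)),
             w * (P11 * b[, 3] + P12 * c_[, 3] + P33 / (3 * Rc)),
             w * (P21 * b[, 1] + P22 * c_[, 1]),
             w * (P21 * b[, 2] + P22 * c_[, 2]),
             w * (P21 * b[, 3] + P22 * c_[, 3]))
  list(ok = TRUE, f = f)
}

# scatter element forces (M x 6) into the global residual (2 * nnode)
.fe_scatter <- function(f, fe) {
  idx <- cbind(2L * fe$tri - 1L, 2L * fe$tri)   # ur dofs then uz dofs
  res <- numeric(2L * fe$nnode)
  rs <- rowsum(as.numeric(f), as.integer(idx))
  res[as.integer(rownames(rs))] <- rs
  res
}

#' Simulate cell contraction in the fibrous matrix
#'
#' Quasi-static finite-deformation solve of the fibrous-matrix law on an
#' axisymmetric mesh. The cavity (cell) surface displacement is prescribed
#' as an affine contraction toward the cell centre achieving the stated
#' volume loss — isotropic scale \code{(1 - cvf)^(1/3)} on all coordinates,
#' or axial scale \code{(1 - cvf)} on z only for axial polarization. The
#' outer boundary is fixed; the z axis and midplane carry symmetry
#' conditions. Load is applied in increments with Newton iteration
#' (relative residual tolerance 1e-8) and automatic increment cutback on
#' divergence or element inversion.
#'
#' @param mesh an [build_mesh()] mesh.
#' @param params a [fibrous_params()] object.
#' @param cell a [cell_geometry()]; defaults to the mesh's cell.
#' @param increments initial number of load increments (>= 1).
#' @param tol relative Newton residual tolerance.
#' @param max_iter Newton iterations per increment before cutback.
#' @param verbose print per-increment convergence.
#' @return object of class \code{"contraction_field"}: \code{u} (N x 2 nodal
#'   displacements, micrometres), \code{mesh}, \code{params}, \code{cell},
#'   \code{converged}, \code{n_increments}.
#' @export
solve_contraction <- function(mesh, params, cell = mesh$cell,
                              increments = 4L, tol = 1e-8, max_iter = 30L,
                              verbose = FALSE) {
  stopifnot(inherits(mesh, "axisym_mesh"), inherits(params, "fibrous_params"))
  if (increments < 1) stop("'increments' must be >= 1")
  fe <- .fe_setup(mesh)
  nd <- mesh$nodes
  ndof <- 2L * nrow(nd)
  cvf <- cell$contraction_volume_fraction
  # full prescribed displacement on the cavity surface
  u_cav <- if (cell$polarization == "isotropic") {
    sc <- (1 - cvf)^(1 / 3) - 1
    cbind(sc * nd[mesh$cavity, 1], sc * nd[mesh$cavity, 2])
  } else {
    cbind(0 * nd[mesh$cavity, 1], ((1 - cvf) - 1) * nd[mesh$cavity, 2])
  }
  fixed <- c(2L * mesh$outer - 1L, 2L * mesh$outer,
             2L * mesh$axis - 1L,        # u_r = 0 on the axis
             2L * mesh$midplane)         # u_z = 0 on the midplane
  presc <- c(2L * mesh$cavity - 1L, 2L * mesh$cavity)
  presc_val <- c(u_cav[, 1], u_cav[, 2])
  # cavity nodes on the symmetry edges carry value 0 from both conditions
  constrained <- unique(c(fixed, presc))
  free <- setdiff(seq_len(ndof), constrained)
  tri6 <- cbind(2L * fe$tri - 1L, 2L * fe$tri)
  ii <- rep(seq_len(6), times = 6)
  jj <- rep(seq_len(6), each = 6)
  h_fd <- 1e-7 * max(mesh$spec$near_size, 1e-3)

  gather <- function(u) matrix(u[tri6], ncol = 6)

  assemble <- function(u) {
    Ue <- gather(u)
    f0 <- .fe_internal(Ue, fe, params)
    if (!f0$ok) return(NULL)
    res <- .fe_scatter(f0$f, fe)
    # element tangent by central differences of the element force
    M <- nrow(Ue)
    Ke <- matrix(0, M, 36)
    for (k in seq_len(6)) {
      Up <- Ue; Up[, k] <- Up[, k] + h_fd
      Um <- Ue; Um[, k] <- Um[, k] - h_fd
      fp <- .fe_internal(Up, fe, params)
      fm <- .fe_internal(Um, fe, params)
      if (!fp$ok || !fm$ok) return(NULL)
      Ke[, (k - 1L) * 6L + seq_len(6)] <- (fp$f - fm$f) / (2 * h_fd)
    }
    # triplets: Ke[, (j-1)*6 + i] = d f_i / d u_j
    I <- as.integer(tri6[, ii])
    Jc <- as.integer(tri6[, jj])
    X <- as.numeric(Ke[, (jj - 1L) * 6L + ii])
    K <- Matrix::sparseMatrix(i = I, j = Jc, x = X, dims = c(ndof, ndof))
    list(res = res, K = K)
  }

  u <- numeric(ndof)
  alpha <- 0; dalpha <- 1 / increments
  n_inc <- 0L
  while (alpha < 1 - 1e-12) {
    dalpha <- min(dalpha, 1 - alpha)
    target <- alpha + dalpha
    u_try <- u
    u_try[presc] <- presc_val * target
    ok <- FALSE
    ref <- NA_real_
    for (it in seq_len(max_iter)) {
      sys <- assemble(u_try)
      if (is.null(sys)) break
      rn <- sqrt(sum(sys$res[free]^2))
      if (it == 1) ref <- max(rn, sqrt(sum(sys$res[constrained]^2)), 1e-300)
      if (verbose)
        message(sprintf("inc %.3f it %d resid %.3e", target, it, rn / ref))
      # absolute floor catches the zero-load case where ref itself is ~ 0
      if (rn / ref < tol || rn < 1e-10) { ok <- TRUE; break }
      du <- tryCatch(
        as.numeric(Matrix::solve(sys$K[free, free, drop = FALSE],
                                 -sys$res[free])),
        error = function(e) NULL)
      if (is.null(du) || !all(is.finite(du))) break
      u_try[free] <- u_try[free] + du
    }
    if (ok) {
      u <- u_try; alpha <- target; n_inc <- n_inc + 1L
      dalpha <- dalpha * 1.5
    } else {
      dalpha <- dalpha / 2
      if (dalpha < 1e-4)
        stop("Newton failed to converge even after increment cutback ",
             sprintf("(reached load fraction %.3f)", alpha))
    }
  }
  structure(list(u = matrix(u, ncol = 2, byrow = TRUE), mesh = mesh,
                 params = params, cell = cell, converged = TRUE,
                 n_increments = n_inc),
            class = "contraction_field")
}

#' @export
print.contraction_field <- function(x, ...) {
  um <- sqrt(rowSums(x$u^2))
  cat(sprintf(
    "Contraction displacement field: %d nodes, max |u| = %.4g um (%d increments)\n",
    nrow(x$u), max(um), x$n_increments))
  invisible(x)
}

# linear interpolation of nodal values at arbitrary points (n x 2) in the
# mesh; returns n x k matrix (NA outside)
.fe_interp <- function(mesh, vals, pts) {
  nd <- mesh$nodes; tri <- mesh$tri
  P1 <- nd[tri[, 1], ]; P2 <- nd[tri[, 2], ]; P3 <- nd[tri[, 3], ]
  detA <- (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
    (P3[, 1] - P1[, 1]) * (P2[, 2] - P1[, 2])
  vals <- as.matrix(vals)
  out <- matrix(NA_real_, nrow(pts), ncol(vals))
  for (q in seq_len(nrow(pts))) {
    px <- pts[q, 1]; py <- pts[q, 2]
    w1 <- ((P2[, 1] - px) * (P3[, 2] - py) -
             (P3[, 1] - px) * (P2[, 2] - py)) / detA
    w2 <- ((P3[, 1] - px) * (P1[, 2] - py) -
             (P1[, 1] - px) * (P3[, 2] - py)) / detA
    w3 <- 1 - w1 - w2
    hit <- which(w1 >= -1e-9 & w2 >= -1e-9 & w3 >= -1e-9)
    if (length(hit) == 0) next
    e <- hit[1]
    out[q, ] <- w1[e] * vals[tri[e, 1], ] + w2[e] * vals[tri[e, 2], ] +
      w3[e] * vals[tri[e, 3], ]
  }
  out
}

#' Radial displacement-decay profile
#'
#' Samples the displacement magnitude along rays from the cell surface
#' outward, on a log-spaced grid of distances from the cell centre, and
#' forms the angular average. Sample points within one near-field element
#' of the cavity or one far-field element of the outer boundary are
#' excluded; rays that would exit the domain are truncated and flagged.
#'
#' @param field a \code{"contraction_field"} from [solve_contraction()], or
#'   a list with \code{mesh} and \code{u} for injected synthetic fields.
#' @param rays ray angles in degrees from the midplane (0 = equatorial,
#'   90 = axial).
#' @param n_r number of radial sample points per ray.
#' @return object of class \code{"displacement_profile"}: \code{profiles}
#'   (data.frame ray, r, r_surf, u), \code{mean} (data.frame r, u averaged
#'   over rays), cell radius \code{a} and \code{R_out}.
#' @export
radial_profile <- function(field, rays = c(5, 25, 45, 65, 85), n_r = 60L) {
  mesh <- field$mesh
  cellg <- if (!is.null(field$cell)) field$cell else mesh$cell
  a_r <- cellg$a_r; a_z <- cellg$a_z
  Rmax <- mesh$spec$R_out - mesh$spec$far_size
  umag_nodal <- sqrt(rowSums(field$u^2))
  prof <- lapply(rays, function(ang) {
    th <- ang * pi / 180
    dirv <- c(cos(th), sin(th))
    t0 <- 1 / sqrt((dirv[1] / a_r)^2 + (dirv[2] / a_z)^2)  # cavity hit
    r0 <- t0 + mesh$spec$near_size
    if (r0 >= Rmax) stop("ray exits domain before sampling can start")
    rr <- exp(seq(log(r0), log(Rmax), length.out = n_r))
    pts <- cbind(rr * dirv[1], rr * dirv[2])
    ui <- .fe_interp(mesh, field$u, pts)
    um <- sqrt(rowSums(ui^2))
    truncated <- any(!is.finite(um))
    keep <- is.finite(um)
    data.frame(ray = ang, r = rr[keep], r_surf = rr[keep] - t0,
               u = um[keep], truncated = truncated)
  })
  profiles <- do.call(rbind, prof)
  # angular average on the common log grid (by sample index)
  idx <- unlist(lapply(prof, function(p) seq_len(nrow(p))))
  mean_u <- tapply(profiles$u, idx, mean)
  mean_r <- tapply(profiles$r, idx, mean)
  structure(list(profiles = profiles,
                 mean = data.frame(r = as.numeric(mean_r),
                                   u = as.numeric(mean_u)),
                 a = cellg$a, R_out = mesh$spec$R_out),
            class = "displacement_profile")
}

#' @export
print.displacement_profile <- function(x, ...) {
  cat(sprintf(
    "Displacement profile: %d rays, r in [%.3g, %.3g] um, max |u| = %.4g um\n",
    length(unique(x$profiles$ray)), min(x$mean$r), max(x$mean$r),
    max(x$mean$u)))
  invisible(x)
}

#' @export
plot.displacement_profile <- function(x, ...) {
  graphics::plot(x$mean$r, x$mean$u, log = "xy", type = "b", pch = 16,
                 cex = 0.6, xlab = "r (um)", ylab = "|u| (um)", ...)
  invisible(x)
}

#' Fit the power-law displacement decay u(r) ~ r^(-eta)
#'
#' Ordinary least squares of \code{log u} on \code{log r} over the window
#' \code{[r_min_factor * a, r_max_factor * R_out]}. Non-positive
#' displacements inside the window are masked with a warning. The decay
#' exponent \code{eta} is minus the slope; smaller \code{eta} means
#' longer-range stress transmission.
#'
#' @param profile a \code{"displacement_profile"} (the angular mean is
#'   used) or a data.frame with columns \code{r} and \code{u}.
#' @param r_min_factor,r_max_factor fit window as multiples of the cell
#'   radius \code{a} and of \code{R_out}.
#' @param a,R_out required when \code{profile} is a plain data.frame.
#' @return object of class \code{"decay_fit"}: \code{eta}, \code{prefactor},
#'   \code{r_range}, \code{r_squared}, \code{n}.
#' @export
fit_power_law <- function(profile, r_min_factor = 1.2, r_max_factor = 0.5,
                          a = NULL, R_out = NULL) {
  if (inherits(profile, "displacement_profile")) {
    dat <- profile$mean; a <- profile$a; R_out <- profile$R_out
  } else {
    dat <- profile
    if (is.null(a) || is.null(R_out))
      stop("give 'a' and 'R_out' with a plain data.frame profile")
  }
  lo <- r_min_factor * a; hi <- r_max_factor * R_out
  sel <- dat$r >= lo & dat$r <= hi
  if (any(dat$u[sel] <= 0)) {
    warning("non-positive displacements in the fit window were masked")
    sel <- sel & dat$u > 0
  }
  if (sum(sel) < 10)
    stop("need at least 10 profile points inside the fit window")
  fit <- stats::lm(log(u) ~ log(r), data = dat[sel, ])
  co <- stats::coef(fit)
  ly <- log(dat$u[sel])
  r2 <- 1 - sum(stats::residuals(fit)^2) / max(sum((ly - mean(ly))^2),
                                               .Machine$double.eps)
  structure(list(eta = -as.numeric(co[2]),
                 prefactor = exp(as.numeric(co[1])),
                 r_range = c(lo, hi),
                 r_squared = r2,
                 n = sum(sel)),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law decay fit: eta = %.4f (R^2 = %.4f, %d points, r in [%.3g, %.3g] um)\n",
    x$eta, x$r_squared, x$n, x$r_range[1], x$r_range[2]))
  invisible(x)
}

#' @export
coef.decay_fit <- function(object, ...)
  c(eta = object$eta, prefactor = object$prefactor)

#' Cellularity-scaled effective decay exponent
#'
#' Rescales the decay exponent by the mean inter-cell spacing implied by
#' cellularity: for areal densities (cells per area) spacing scales as
#' \code{cellularity^(-1/2)}, for volumetric densities as \code{^(-1/3)},
#' giving \code{eta_eff = eta * (reference_cellularity / cellularity)^
#' (1/2 or 1/3)}. Denser tissue shortens the distance a signal must travel
#' to reach a neighbour, so high cellularity compensates a fast decay. The
#' spacing rule used is recorded in the \code{"formula"} attribute.
#'
#' @param eta fitted decay exponent.
#' @param cellularity cell density (> 0), cells per mm^2 (areal) or mm^3.
#' @param reference_cellularity density of the reference (uninjured) group.
#' @param dimension \code{"areal"} or \code{"volumetric"}.
#' @return eta_eff with attribute \code{"formula"}.
#' @export
effective_decay <- function(eta, cellularity, reference_cellularity,
                            dimension = c("areal", "volumetric")) {
  dimension <- match.arg(dimension)
  if (any(cellularity <= 0) || reference_cellularity <= 0)
    stop("cellularity must be > 0")
  p <- if (dimension == "areal") 0.5 else 1 / 3
  out <- eta * (reference_cellularity / cellularity)^p
  attr(out, "formula") <-
    sprintf("eta_eff = eta * (ref/cellularity)^(%s) [%s spacing rule]",
            format(p), dimension)
  out
}
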