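#' Spherically symmetric reduced contraction solver
#'
#' Independent one-dimensional check for spherical cells: under spherical
#' symmetry the contraction problem reduces to a two-point boundary-value
#' problem for the radial displacement u(rho), with radial stretch
#' \code{1 + du/drho} and two equal tangential stretches
#' \code{1 + u/rho} feeding the same fibrous-matrix law. The weak form is
#' discretized with 1-D linear elements (midpoint quadrature, graded grid)
#' and solved by Newton iteration with a finite-difference tangent. The
#' boundary conditions match the axisymmetric solver: prescribed isotropic
#' contraction at the cell surface, zero displacement at the outer radius.
#'
#' @param params a [fibrous_params()] object.
#' @param a cell radius, micrometres.
#' @param R_out outer domain radius, micrometres.
#' @param contraction_volume_fraction cell volume loss fraction.
#' @param n_elem number of radial elements.
#' @param grading ratio of last to first element length (geometric grading).
#' @param increments load increments.
#' @param tol relative Newton residual tolerance.
#' @return list with \code{rho} (node radii), \code{u} (radial
#'   displacement, negative inward), and \code{profile} (data.frame r, u
#'   with u = |displacement|, directly comparable to [radial_profile()]).
#' @export
solve_contraction_spherical <- function(params, a = 5, R_out = 100,
                                        contraction_volume_fraction = 0.05,
                                        n_elem = 400L, grading = 6,
                                        increments = 4L, tol = 1e-10) {
  stopifnot(inherits(params, "fibrous_params"))
  g <- grading^(1 / (n_elem - 1))
  h <- g^(0:(n_elem - 1)); h <- h / sum(h) * (R_out - a)
  rho <- a + c(0, cumsum(h))
  n <- length(rho)
  u_in <- ((1 - contraction_volume_fraction)^(1 / 3) - 1) * a

  residual <- function(u) {
    u1 <- u[-n]; u2 <- u[-1]
    r1 <- rho[-n]; r2 <- rho[-1]
    L <- r2 - r1; rm <- (r1 + r2) / 2
    lr <- 1 + (u2 - u1) / L          # radial stretch
    lt <- 1 + (u1 + u2) / 2 / rm     # tangential stretch (x2)
    if (any(lr <= 0) || any(lt <= 0)) return(NULL)
    s <- principal_cauchy(cbind(lr, lt, lt), params)
    J <- lr * lt^2
    Pr <- J * s[, 1] / lr            # radial 1st PK
    Pt <- J * s[, 2] / lt            # tangential 1st PK
    w <- L * rm^2
    fr1 <- w * (Pr * (-1 / L) + 2 * Pt * 0.5 / rm)
    fr2 <- w * (Pr * (1 / L) + 2 * Pt * 0.5 / rm)
    res <- numeric(n)
    res[1:(n - 1)] <- res[1:(n - 1)] + fr1
    res[2:n] <- res[2:n] + fr2
    res
  }

  u <- numeric(n)
  free <- 2:(n - 1)
  for (inc in seq_len(increments)) {
    u[1] <- u_in * inc / increments
    ref <- NA_real_
    for (it in 1:60) {
      r0 <- residual(u)
      if (is.null(r0)) stop("spherical solver: element inversion")
      rn <- sqrt(sum(r0[free]^2))
      if (it == 1) ref <- max(rn, 1e-300)
      if (rn / ref < tol || rn < 1e-14) break
      # tridiagonal FD Jacobian: Jm[i, ] = d res_i / d u_{i-1}, u_i, u_{i+1};
      # the coupling is nearest-neighbour, so every third dof can be
      # perturbed in the same residual evaluation
      hstep <- 1e-8 * max(a, 1)
      Jm <- matrix(0, n, 3)
      for (ph in 0:2) {
        idx <- free[seq(1 + ph, length(free), by = 3)]
        up <- u; up[idx] <- up[idx] + hstep
        rp <- residual(up)
        if (is.null(rp)) stop("spherical solver: element inversion")
        for (i in idx) for (dd in -1:1) {
          row <- i + dd
          if (row >= 1 && row <= n)
            Jm[row, 2 - dd] <- (rp[row] - r0[row]) / hstep
        }
      }
      # solve tridiagonal system on the free dofs (Thomas algorithm)
      m <- length(free)
      aa <- Jm[free, 1]; bb <- Jm[free, 2]; cc <- Jm[free, 3]
      dd <- -r0[free]
      for (i in 2:m) {
        wfac <- aa[i] / bb[i - 1]
        bb[i] <- bb[i] - wfac * cc[i - 1]
        dd[i] <- dd[i] - wfac * dd[i - 1]
      }
      du <- numeric(m)
      du[m] <- dd[m] / bb[m]
      for (i in (m - 1):1) du[i] <- (dd[i] - cc[i] * du[i + 1]) / bb[i]
      u[free] <- u[free] + du
    }
  }
  list(rho = rho, u = u,
       profile = data.frame(r = rho, u = abs(u)))
}
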