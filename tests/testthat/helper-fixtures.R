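# shared fixtures; expensive FE solves are computed once per test run
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

# coarse-but-adequate mesh/cell used by several FE tests
fe_linear_case <- function() {
  cached("fe_linear", {
    pm <- fibrous_params(E_b = 0.1, E_f = 0, lambda1 = 1.005,
                         lambda2 = 1.03)
    cellg <- cell_geometry(a = 5, contraction_volume_fraction = 0.003)
    mesh <- build_mesh(cellg, mesh_spec(1, 6, 100))
    field <- solve_contraction(mesh, pm, increments = 1)
    list(params = pm, cell = cellg, mesh = mesh, field = field,
         profile = radial_profile(field))
  })
}

# finite-domain linear-elastic spherical cavity closed form:
# u(r) = C1 r + C2 / r^2 with u(a) = u0, u(R) = 0
cavity_closed_form <- function(a, R, u0) {
  A <- matrix(c(a, 1 / a^2, R, 1 / R^2), 2, 2, byrow = TRUE)
  cc <- solve(A, c(u0, 0))
  function(r) abs(cc[1] * r + cc[2] / r^2)
}

# independent textbook compressible neo-Hookean (oracle for E_f = 0):
# sigma = (G/J) (B - I) ... using the same volumetric convention as the
# package is *not* assumed; this matches kappa (J-1) I + (G/J) dev(J^-2/3 B)
neo_hookean_oracle <- function(F, kappa, G) {
  J <- det(F)
  B <- F %*% t(F)
  Bbar <- J^(-2 / 3) * B
  kappa * (J - 1) * diag(3) + G * (Bbar - sum(diag(Bbar)) / 3 * diag(3)) / J
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-300)), tol)
}

# analytic ellipse rendered with sub-pixel (8x8) coverage weights; the
# oracle shape for nucleus-moment accuracy checks
render_ellipse <- function(size, cx, cy, a, b, ang_deg, ss = 8) {
  ct <- cos(ang_deg * pi / 180); st <- sin(ang_deg * pi / 180)
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  img <- matrix(0, size, size)
  for (dx in sub) for (dy in sub) {
    X <- outer(rep(1, size), seq_len(size) + dx) - cx
    Y <- outer(seq_len(size) + dy, rep(1, size)) - cy
    U <- X * ct + Y * st; V <- -X * st + Y * ct
    img <- img + ((U / a)^2 + (V / b)^2 <= 1) / ss^2
  }
  img
}

# bilinear rotation of a square image about its centre (out-of-domain
# pixels 0); used for rotation-equivariance checks
rotate_img <- function(img, ang_deg) {
  n <- nrow(img); c0 <- (n + 1) / 2
  th <- ang_deg * pi / 180; ct <- cos(th); st <- sin(th)
  X <- outer(rep(1, n), seq_len(n)) - c0
  Y <- outer(seq_len(n), rep(1, n)) - c0
  xs <- ct * X + st * Y + c0; ys <- -st * X + ct * Y + c0
  x0 <- floor(xs); y0 <- floor(ys); fx <- xs - x0; fy <- ys - y0
  ok <- x0 >= 1 & x0 < n & y0 >= 1 & y0 < n
  idx <- function(yy, xx) (xx - 1) * n + yy
  v <- rep(0, n * n)
  v[ok] <- (1 - fx[ok]) * (1 - fy[ok]) * img[idx(y0[ok], x0[ok])] +
    fx[ok] * (1 - fy[ok]) * img[idx(y0[ok], x0[ok] + 1)] +
    (1 - fx[ok]) * fy[ok] * img[idx(y0[ok] + 1, x0[ok])] +
    fx[ok] * fy[ok] * img[idx(y0[ok] + 1, x0[ok] + 1)]
  matrix(v, n, n)
}
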