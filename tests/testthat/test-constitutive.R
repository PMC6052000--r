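pm_ref <- fibrous_params(E_b = 0.1, E_f = 10, lambda1 = 1.01,
                         lambda2 = 1.05, n = 3, m = 2)

test_that("fiber branch is C0 and C1 continuous at both critical
           stretches", {
  l1 <- pm_ref$lambda1; l2 <- pm_ref$lambda2; Ef <- pm_ref$E_f
  expect_equal(fiber_stress_derivative(l1, pm_ref), 0)
  expect_lt(abs(fiber_stress_derivative(l1 - 1e-9, pm_ref)), 1e-12)
  expect_lt(abs(fiber_stress_derivative(l1 + 1e-9, pm_ref)), 1e-8 * Ef)
  v_lo <- fiber_stress_derivative(l2 - 1e-12, pm_ref)
  v_hi <- fiber_stress_derivative(l2, pm_ref)
  v_exp <- Ef * (l2 - l1) / (pm_ref$n + 1)
  expect_lt(abs(v_lo - v_exp), 1e-4 * Ef)
  expect_lt(abs(v_hi - v_exp), 1e-12 * Ef)
  # slope approaches E_f from both sides of lambda2 (central differences
  # straddling a point h away from the boundary on each side, h = 1e-6)
  h <- 1e-6
  slope_lo <- (fiber_stress_derivative(l2, pm_ref) -
                 fiber_stress_derivative(l2 - 2 * h, pm_ref)) / (2 * h)
  slope_hi <- (fiber_stress_derivative(l2 + 2 * h, pm_ref) -
                 fiber_stress_derivative(l2, pm_ref)) / (2 * h)
  expect_lt(abs(slope_lo - Ef), 1e-4 * Ef)
  expect_lt(abs(slope_hi - Ef), 1e-4 * Ef)
})

test_that("stress vanishes at identity and pure dilation below lambda1 is
           purely volumetric", {
  expect_equal(max(abs(cauchy_stress(diag(3), pm_ref))), 0)
  s <- 1.005  # below lambda1: no fiber engagement
  sig <- cauchy_stress(diag(3) * s, pm_ref)
  expect_equal(sig, pm_ref$kappa * (s^3 - 1) * diag(3), tolerance = 1e-12)
  expect_error(deformation_state(diag(c(-1, 1, 1))), "inverted")
})

test_that("E_f = 0 reduces exactly to the independent neo-Hookean oracle", {
  pm0 <- fibrous_params(kappa = 0.3, G = 0.12, E_f = 0, lambda1 = 1.01,
                        lambda2 = 1.05)
  set.seed(42)
  for (i in 1:5) {
    F <- diag(3) + 0.1 * matrix(stats::rnorm(9), 3, 3)
    if (det(F) <= 0) next
    expect_lt(max(abs(cauchy_stress(F, pm0) -
                        neo_hookean_oracle(F, 0.3, 0.12))), 1e-10)
  }
})

test_that("small-strain uniaxial tangent matches 9 kappa G/(3 kappa + G)
           within 0.1 %", {
  pm0 <- fibrous_params(kappa = 0.25, G = 0.1, E_f = 0, lambda1 = 1.01,
                        lambda2 = 1.05)
  E_iso <- 9 * 0.25 * 0.1 / (3 * 0.25 + 0.1)
  u <- uniaxial_response(c(1, 1 + 1e-5), pm0)
  expect_lt(abs(diff(u$stress) / 1e-5 - E_iso) / E_iso, 1e-3)
})

test_that("uniaxial stress is zero at stretch 1, continuous across
           lambda1, and stiffens only through the fiber branch", {
  u <- uniaxial_response(1, pm_ref)
  expect_equal(u$stress, 0, tolerance = 1e-12)
  # stress is continuous across lambda1: the difference across a small gap
  # is bounded by the local tangent times the gap
  h <- 5e-4
  l1_ax <- pm_ref$lambda1
  u2 <- uniaxial_response(c(l1_ax - 2 * h, l1_ax - h, l1_ax + h,
                            l1_ax + 2 * h), pm_ref)
  t_lo <- (u2$stress[2] - u2$stress[1]) / h
  expect_lt(abs(u2$stress[3] - u2$stress[2]), 3 * t_lo * 2 * h)
  # beyond lambda1 the fiber branch turns stiffening on: the tangent well
  # inside the stiffening regime exceeds the isotropic tangent below lambda1
  u3 <- uniaxial_response(c(l1_ax + 0.02, l1_ax + 0.02 + h), pm_ref)
  t_fib <- diff(u3$stress) / h
  expect_gt(t_fib, 1.5 * t_lo)
  # with E_f = 0 no such stiffening appears
  pm0 <- fibrous_params(kappa = pm_ref$kappa, G = pm_ref$G, E_f = 0,
                        lambda1 = pm_ref$lambda1, lambda2 = pm_ref$lambda2)
  u4 <- uniaxial_response(c(l1_ax + 0.02, l1_ax + 0.02 + h), pm0)
  expect_lt(diff(u4$stress) / h, 1.5 * t_lo)
})

test_that("objectivity: rotated deformations give rotated stresses", {
  set.seed(7)
  F <- diag(c(1.08, 0.97, 0.99)) + 0.02 * matrix(stats::rnorm(9), 3, 3)
  for (i in 1:5) {
    A <- matrix(stats::rnorm(9), 3, 3)
    Q <- qr.Q(qr(A)); if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    lhs <- cauchy_stress(Q %*% F, pm_ref)
    rhs <- Q %*% cauchy_stress(F, pm_ref) %*% t(Q)
    expect_lt(max(abs(lhs - rhs)), 1e-10 * max(abs(rhs)))
  }
})

test_that("stress eigenvectors coincide with the principal directions", {
  set.seed(3)
  F <- diag(c(1.06, 1.0, 0.96)) + 0.01 * matrix(stats::rnorm(9), 3, 3)
  st <- deformation_state(F)
  sig <- cauchy_stress(st, pm_ref)
  for (a in 1:3) {
    v <- st$directions[, a]
    w <- sig %*% v
    # w must be parallel to v
    expect_lt(sqrt(sum((w - as.numeric(crossprod(v, w)) * v)^2)),
              1e-10 * max(abs(sig)))
  }
})

test_that("hyperelasticity: work over a closed uniaxial loop vanishes
           within quadrature error", {
  # loading and unloading legs use *different* grids so the trapezoid sums
  # cannot cancel by construction; only path-independence makes them agree
  work <- function(lam) {
    u <- uniaxial_response(sort(lam), pm_ref)
    P <- u$stress * u$lateral^2 / u$stretch  # nominal (1st PK) stress
    s <- sum((P[-1] + P[-length(P)]) / 2 * diff(u$stretch))
    if (is.unsorted(lam)) -s else s
  }
  w_up <- work(seq(1, 1.08, length.out = 301))
  w_dn <- work(rev(seq(1, 1.08, length.out = 217)))
  expect_gt(w_up, 0)
  expect_lt(abs(w_up + w_dn) / w_up, 1e-3)
})

test_that("axial stress never decreases when E_f/E_b grows", {
  lam <- c(1.02, 1.05, 1.1)
  ratios <- c(0.1, 1, 10, 100)
  stress <- sapply(ratios, function(r) {
    p <- fibrous_params(E_b = 0.1, E_f = 0.1 * r, lambda1 = 1.01,
                        lambda2 = 1.05, n = 3, m = 2)
    uniaxial_response(lam, p)$stress
  })
  for (i in seq_along(lam))
    expect_true(all(diff(stress[i, ]) >= -1e-12))
})

test_that("numerical tangent: isotropic elasticity at identity, secant
           consistency, and major symmetry in branch interiors", {
  pm0 <- fibrous_params(kappa = 0.3, G = 0.12, E_f = 0, lambda1 = 1.01,
                        lambda2 = 1.05)
  D <- numerical_tangent(diag(3), pm0)
  lam_c <- 0.3 - 2 * 0.12 / 3
  D_exp <- matrix(0, 6, 6)
  D_exp[1:3, 1:3] <- lam_c
  diag(D_exp)[1:3] <- lam_c + 2 * 0.12
  diag(D_exp)[4:6] <- 0.12
  expect_lt(max(abs(D - D_exp)) / max(abs(D_exp)), 1e-4)
  expect_error(numerical_tangent(diag(3), pm0, h = 1e-2), "h")
  # secant check at a uniaxial state: D : dE ~ dS along a random direction
  st <- deformation_state(diag(c(1.06, 0.985, 0.985)))
  D1 <- numerical_tangent(st, pm_ref)
  expect_lt(max(abs(D1 - t(D1))) / max(abs(D1)), 1e-6)
  set.seed(11)
  dEv <- stats::rnorm(6); dEv <- dEv / sqrt(sum(dEv^2)) * 1e-5
  dE <- matrix(c(dEv[1], dEv[6] / 2, dEv[5] / 2,
                 dEv[6] / 2, dEv[2], dEv[4] / 2,
                 dEv[5] / 2, dEv[4] / 2, dEv[3]), 3, 3)
  S_of <- function(C) {
    ec <- eigen(C, symmetric = TRUE)
    lam <- sqrt(ec$values)
    s <- tendonscale:::principal_cauchy(matrix(lam, 1, 3), pm_ref)
    ec$vectors %*% diag(prod(lam) * as.numeric(s) / lam^2) %*% t(ec$vectors)
  }
  dS <- S_of(st$C + 2 * dE) - S_of(st$C)
  dS_v <- c(dS[1, 1], dS[2, 2], dS[3, 3], dS[2, 3], dS[1, 3], dS[1, 2])
  pred <- as.numeric(D1 %*% dEv)
  expect_lt(max(abs(pred - dS_v)) / max(abs(dS_v)), 1e-4)
})

test_that("parameter fit: noiseless round-trip within 2 %", {
  truth <- fibrous_params(E_b = 0.1, E_f = 5, lambda1 = 1.02,
                          lambda2 = 1.06, n = 3, m = 2)
  lam <- seq(1, 1.12, length.out = 120)
  curve <- uniaxial_response(lam, truth)
  fit <- fit_matrix_params(curve)
  est <- coef(fit)
  truth_v <- c(E_b = 0.1, E_f = 5, lambda1 = 1.02, lambda2 = 1.06,
               n = 3, m = 2)
  for (nm in names(truth_v))
    expect_lt(abs(est[nm] - truth_v[nm]) / truth_v[nm], 0.02)
})

test_that("parameter fit: median absolute error <= 15 % under 3 % noise", {
  truth <- fibrous_params(E_b = 0.1, E_f = 5, lambda1 = 1.02,
                          lambda2 = 1.06, n = 3, m = 2)
  lam <- seq(1, 1.2, length.out = 200)
  clean <- uniaxial_response(lam, truth)$stress
  truth_v <- c(E_b = 0.1, E_f = 5, lambda1 = 1.02, lambda2 = 1.06,
               n = 3, m = 2)
  errs <- sapply(1:9, function(s) {
    set.seed(s)
    noisy <- data.frame(stretch = lam,
                        stress = clean * (1 + 0.03 * stats::rnorm(200)))
    est <- coef(suppressWarnings(fit_matrix_params(noisy)))
    abs(est - truth_v) / truth_v
  })
  expect_lt(max(apply(errs, 1, stats::median)), 0.15)
})

test_that("curve that never engages fibers flags them unidentifiable", {
  truth <- fibrous_params(E_b = 0.1, E_f = 5, lambda1 = 1.05,
                          lambda2 = 1.1, n = 3, m = 2)
  lam <- seq(1, 1.03, length.out = 40)  # max stretch < lambda1
  curve <- uniaxial_response(lam, truth)
  fit <- suppressWarnings(
    fit_matrix_params(curve, fixed = list(lambda1 = 1.05, lambda2 = 1.1,
                                          n = 3, m = 2)))
  expect_true(all(c("lambda2", "m") %in% fit$unidentifiable))
})
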