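#' Fibrous-matrix constitutive parameters
#'
#' Parameter vector of the hyperelastic fibrous-matrix law used for ECM
#' stress transmission modeling. The Cauchy stress decomposes into an
#' isotropic neo-Hookean part with initial bulk modulus \code{kappa} and
#' shear modulus \code{G}, and a fibrous part applied along the principal
#' stretch directions with fiber modulus \code{E_f}, critical stretches
#' \code{lambda1 < lambda2} demarcating the zero / strain-stiffening /
#' post-transition regimes, and stiffening exponents \code{n} and \code{m}.
#'
#' The isotropic part may equivalently be given as a small-strain Young's
#' modulus \code{E_b} with Poisson ratio \code{nu} (default 0.30), mapped by
#' \code{kappa = E_b / (3 (1 - 2 nu))}, \code{G = E_b / (2 (1 + nu))}. The
#' fiber/matrix interaction is summarized by the ratio \code{E_f / E_b}.
#'
#' @param E_b isotropic small-strain modulus, MPa (alternative to kappa/G).
#' @param E_f fibrous modulus, MPa (> 0; 0 allowed for the isotropic limit).
#' @param lambda1,lambda2 critical stretches, \code{1 <= lambda1 < lambda2}.
#' @param n,m strain-stiffening exponents (> 0).
#' @param nu Poisson ratio used to map \code{E_b} to \code{(kappa, G)}.
#' @param kappa,G initial bulk and shear moduli, MPa (override \code{E_b}).
#' @return object of class \code{"fibrous_params"}.
#' @export
fibrous_params <- function(E_b = NULL, E_f, lambda1 = 1.005, lambda2 = 1.03,
                           n = 5, m = 2, nu = 0.30, kappa = NULL, G = NULL) {
  if (is.null(kappa) || is.null(G)) {
    if (is.null(E_b)) stop("give either E_b (with nu) or kappa and G")
    if (nu <= -1 || nu >= 0.5) stop("'nu' must be in (-1, 0.5)")
    kappa <- E_b / (3 * (1 - 2 * nu))
    G <- E_b / (2 * (1 + nu))
  } else if (is.null(E_b)) {
    E_b <- 9 * kappa * G / (3 * kappa + G)
    nu <- (3 * kappa - 2 * G) / (2 * (3 * kappa + G))
  }
  if (kappa <= 0 || G <= 0) stop("kappa and G must be > 0")
  if (E_f < 0) stop("E_f must be >= 0")
  if (lambda1 < 1 || lambda2 <= lambda1)
    stop("need 1 <= lambda1 < lambda2")
  if (n <= 0 || m <= 0) stop("exponents n, m must be > 0")
  structure(list(kappa = kappa, G = G, E_b = E_b, nu = nu, E_f = E_f,
                 lambda1 = lambda1, lambda2 = lambda2, n = n, m = m),
            class = "fibrous_params")
}

#' @export
print.fibrous_params <- function(x, ...) {
  cat("Fibrous-matrix constitutive parameters\n")
  cat(sprintf("  isotropic: kappa = %.4g MPa, G = %.4g MPa (E_b = %.4g, nu = %.3g)\n",
              x$kappa, x$G, x$E_b, x$nu))
  cat(sprintf("  fibrous:   E_f = %.4g MPa (E_f/E_b = %.3g), lambda1 = %.4g, lambda2 = %.4g, n = %.3g, m = %.3g\n",
              x$E_f, x$E_f / x$E_b, x$lambda1, x$lambda2, x$n, x$m))
  invisible(x)
}

#' Fiber stress derivative df/dlambda
#'
#' Piecewise fiber response along a principal stretch: zero below
#' \code{lambda1} (crimped), power-law stiffening on
#' \code{[lambda1, lambda2)}, and a post-transition branch above
#' \code{lambda2}. Continuous with continuous first derivative everywhere
#' (the slope approaches \code{E_f} from both sides of \code{lambda2}).
#'
#' @param lambda principal stretch(es), > 0.
#' @param params a [fibrous_params()] object.
#' @return df/dlambda in MPa, vectorized over \code{lambda}.
#' @export
fiber_stress_derivative <- function(lambda, params) {
  stopifnot(inherits(params, "fibrous_params"))
  if (any(lambda <= 0)) stop("stretches must be > 0")
  l1 <- params$lambda1; l2 <- params$lambda2
  n <- params$n; m <- params$m; Ef <- params$E_f
  out <- numeric(length(lambda))
  mid <- lambda >= l1 & lambda < l2
  hi <- lambda >= l2
  out[mid] <- Ef * ((lambda[mid] - l1) / (l2 - l1))^n *
    (lambda[mid] - l1) / (n + 1)
  out[hi] <- Ef * ((l2 - l1) / (n + 1) +
                     ((1 + lambda[hi] - l2)^(m + 1) - 1) / (m + 1))
  out
}

#' Kinematic state from a deformation gradient
#'
#' @param F 3x3 deformation gradient with \code{det(F) > 0}.
#' @return object of class \code{"deformation_state"}: list with \code{F},
#'   \code{J}, \code{B} (= F F'), \code{C} (= F' F), \code{Bbar}
#'   (= J^(-2/3) B), principal stretches \code{lambda} (decreasing) and
#'   principal directions \code{directions} (columns, eigenvectors of B).
#' @export
deformation_state <- function(F) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)))
  J <- det(F)
  if (J <= 0) stop("inverted element: det(F) <= 0")
  B <- F %*% t(F)
  eb <- eigen(B, symmetric = TRUE)
  structure(list(F = F, J = J, B = B, C = t(F) %*% F,
                 Bbar = J^(-2 / 3) * B,
                 lambda = sqrt(pmax(eb$values, 0)),
                 directions = eb$vectors),
            class = "deformation_state")
}

# principal Cauchy stresses for principal stretches lam (n x 3 matrix):
# sigma_a = kappa (J - 1) + G (Bbar_a - mean(Bbar)) / J + f'(lam_a) lam_a / J
principal_cauchy <- function(lam, params) {
  lam <- matrix(lam, ncol = 3)
  J <- lam[, 1] * lam[, 2] * lam[, 3]
  B <- lam^2
  Bbar <- B * J^(-2 / 3)
  dev <- Bbar - rowMeans(Bbar)
  fib <- matrix(fiber_stress_derivative(as.numeric(lam), params),
                ncol = 3) * lam
  params$kappa * (J - 1) + (params$G * dev + fib) / J
}

#' Cauchy stress of the fibrous-matrix law
#'
#' Evaluates the full Cauchy stress tensor: the isotropic part
#' \code{kappa (J - 1) I + G dev(Bbar) / J} plus the fibrous part
#' \code{(1/J) sum_a f'(lambda_a) lambda_a n_a (x) n_a} over the three
#' principal stretch directions. Symmetric, and zero at \code{F = I}.
#'
#' @param state a [deformation_state()] (or a 3x3 deformation gradient).
#' @param params a [fibrous_params()] object.
#' @return 3x3 Cauchy stress, MPa.
#' @export
cauchy_stress <- function(state, params) {
  if (!inherits(state, "deformation_state"))
    state <- deformation_state(state)
  s <- principal_cauchy(state$lambda, params)
  V <- state$directions
  V %*% diag(as.numeric(s)) %*% t(V)
}

#' Uniaxial stress-stretch response
#'
#' For each axial stretch, the lateral stretch is solved so that the
#' transverse Cauchy stress vanishes (uniaxial stress state), by Newton
#' iteration with a bisection fallback (tolerance 1e-10 on the transverse
#' stress relative to the isotropic modulus). The curve exhibits the
#' toe-to-linear strain-stiffening transition whenever \code{E_f > 0}.
#'
#' @param stretch_grid increasing axial stretches, all >= 1.
#' @param params a [fibrous_params()] object.
#' @return data.frame of class \code{"stress_stretch_curve"}:
#'   \code{stretch}, \code{stress} (axial Cauchy stress, MPa),
#'   \code{lateral} (lateral stretch).
#' @export
uniaxial_response <- function(stretch_grid, params) {
  stopifnot(inherits(params, "fibrous_params"))
  if (any(stretch_grid < 1)) stop("stretch_grid must be >= 1")
  if (is.unsorted(stretch_grid)) stop("stretch_grid must be increasing")
  tol <- 1e-10 * max(params$E_b, 1)
  lam <- as.numeric(stretch_grid)
  s22 <- function(ll) principal_cauchy(cbind(lam, ll, ll), params)[, 2]
  # damped Newton on the whole grid at once (the transverse-stress root is
  # simple and monotone in the lateral stretch)
  ll <- rep(1, length(lam))
  f0 <- s22(ll)
  for (it in 1:80) {
    if (max(abs(f0)) < tol) break
    h <- 1e-7
    d <- (s22(ll + h) - s22(ll - h)) / (2 * h)
    step <- f0 / d
    step[!is.finite(step)] <- 0
    ll_new <- ll - pmax(pmin(step, 0.2), -0.2)
    ll_new[ll_new <= 0.05] <- ll[ll_new <= 0.05] / 2
    ll <- ll_new
    f0 <- s22(ll)
  }
  bad <- which(abs(f0) >= tol)
  for (i in bad) {  # bracketing fallback for stragglers
    g <- function(x) principal_cauchy(cbind(lam[i], x, x), params)[2]
    r <- tryCatch(stats::uniroot(g, c(0.2, lam[i] + 1), tol = 1e-14),
                  error = function(e) NULL)
    if (is.null(r))
      stop("lateral-stretch solve failed at axial stretch ", lam[i])
    ll[i] <- r$root
  }
  s <- principal_cauchy(cbind(lam, ll, ll), params)
  out <- data.frame(stretch = lam, stress = s[, 1], lateral = ll)
  class(out) <- c("stress_stretch_curve", "data.frame")
  out
}

#' Fit fibrous-matrix parameters to a uniaxial stress-stretch curve
#'
#' Bounded nonlinear least squares of the uniaxial response over
#' \code{(E_b, E_f, lambda1, lambda2, n, m)} (Poisson ratio fixed, default
#' 0.30). Parameters are fit on transformed scales (logs for moduli and
#' exponents; \code{lambda1 = 1 + exp(.)}, \code{lambda2 = lambda1 +
#' exp(.)}) so constraints hold by construction. Identifiability is reported
#' via the condition number of the Jacobian at the optimum; when the curve
#' never reaches \code{lambda1} the fiber parameters are flagged
#' unidentifiable.
#'
#' @param curve data.frame with columns \code{stretch} and \code{stress}
#'   (MPa), e.g. a \code{"stress_stretch_curve"}.
#' @param fixed named list of parameters to hold fixed (any of E_b, E_f,
#'   lambda1, lambda2, n, m).
#' @param nu Poisson ratio (fixed during fitting).
#' @param start optional [fibrous_params()] used as the starting point.
#' @param weighting \code{"relative"} (default) divides residuals by the
#'   local stress magnitude — appropriate for multiplicative measurement
#'   noise and essential for resolving the toe-region exponents —
#'   or \code{"absolute"} for plain least squares.
#' @return object of class \code{"fibrous_fit"}: \code{params}
#'   ([fibrous_params()]), \code{coefficients}, \code{residuals},
#'   \code{fitted}, \code{condition_number}, \code{unidentifiable}
#'   (character vector of flagged parameters), \code{data}.
#' @export
fit_matrix_params <- function(curve, fixed = list(), nu = 0.30,
                              start = NULL,
                              weighting = c("relative", "absolute")) {
  weighting <- match.arg(weighting)
  stopifnot(all(c("stretch", "stress") %in% names(curve)))
  lam <- curve$stretch; sig <- curve$stress
  wts <- if (weighting == "relative")
    1 / pmax(abs(sig), 0.05 * stats::median(abs(sig))) else
      rep(1, length(sig))
  if (length(lam) < 8) stop("need at least 8 points on the curve")
  # initialization from the curve shape; with no user start, a small
  # deterministic multistart over the critical stretches guards against the
  # local minima this profile-shaped least-squares surface is prone to
  e_small <- (sig[2] - sig[1]) / (lam[2] - lam[1])
  e_big <- (sig[length(sig)] - sig[length(sig) - 1]) /
    (lam[length(lam)] - lam[length(lam) - 1])
  lam_span <- max(lam) - 1
  starts <- if (!is.null(start)) list(start) else {
    anchors <- expand.grid(f1 = c(0.05, 0.15, 0.35),
                           f2 = c(0.25, 0.55))
    lapply(seq_len(nrow(anchors)), function(i)
      fibrous_params(E_b = max(e_small, 1e-6),
                     E_f = max(e_big - e_small, 1e-6),
                     lambda1 = 1 + anchors$f1[i] * lam_span,
                     lambda2 = 1 + (anchors$f1[i] + anchors$f2[i]) *
                       lam_span,
                     n = 2, m = 2, nu = nu))
  }
  nm <- c("E_b", "E_f", "lambda1", "lambda2", "n", "m")
  free <- setdiff(nm, names(fixed))
  to_theta <- function(p) c(E_b = log(p$E_b), E_f = log(max(p$E_f, 1e-12)),
                            lambda1 = log(max(p$lambda1 - 1, 1e-8)),
                            lambda2 = log(max(p$lambda2 - p$lambda1, 1e-8)),
                            n = log(p$n), m = log(p$m))
  from_theta <- function(th) {
    v <- list(E_b = exp(th[["E_b"]]), E_f = exp(th[["E_f"]]),
              lambda1 = 1 + exp(th[["lambda1"]]))
    v$lambda2 <- v$lambda1 + exp(th[["lambda2"]])
    v$n <- exp(th[["n"]]); v$m <- exp(th[["m"]])
    for (f in names(fixed)) v[[f]] <- fixed[[f]]
    fibrous_params(E_b = v$E_b, E_f = v$E_f, lambda1 = v$lambda1,
                   lambda2 = v$lambda2, n = v$n, m = v$m, nu = nu)
  }
  fit <- NULL; th_full <- NULL
  for (st in starts) {
    th_try <- to_theta(st)
    resid_fun <- function(th_free) {
      th <- th_try; th[free] <- th_free
      p <- tryCatch(from_theta(th), error = function(e) NULL)
      if (is.null(p)) return(rep(1e6, length(sig)))
      pred <- tryCatch(uniaxial_response(lam, p)$stress,
                       error = function(e) rep(NA_real_, length(sig)))
      r <- (pred - sig) * wts
      r[!is.finite(r)] <- 1e6
      r
    }
    f <- tryCatch(
      minpack.lm::nls.lm(par = th_try[free], fn = resid_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 150, ptol = 1e-12, ftol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(f) && (is.null(fit) || f$deviance < fit$deviance)) {
      fit <- f; th_full <- th_try
    }
  }
  if (is.null(fit)) stop("constitutive fit failed from all starting points")
  pars <- from_theta(replace(th_full, free, fit$par))
  pred <- uniaxial_response(lam, pars)$stress
  res <- sig - pred
  cn <- tryCatch({
    sv <- svd(fit$hessian)$d
    sqrt(max(sv) / max(min(sv), .Machine$double.eps))
  }, error = function(e) Inf)
  unident <- character(0)
  if (max(lam) < pars$lambda1)
    unident <- c("E_f", "lambda1", "lambda2", "n", "m")
  else if (max(lam) < pars$lambda2)
    unident <- c("lambda2", "m")
  if (length(unident) || cn > 1e8)
    warning("fit may be under-determined",
            if (length(unident)) paste0(": ", paste(unident, collapse = ", "),
                                        " not constrained by the data"))
  est <- c(E_b = pars$E_b, E_f = pars$E_f, lambda1 = pars$lambda1,
           lambda2 = pars$lambda2, n = pars$n, m = pars$m)
  structure(list(params = pars, coefficients = est, residuals = res,
                 fitted = pred, condition_number = cn,
                 unidentifiable = unident,
                 data = data.frame(stretch = lam, stress = sig),
                 deviance = sum(res^2)),
            class = "fibrous_fit")
}

#' @export
coef.fibrous_fit <- function(object, ...) object$coefficients

#' @export
residuals.fibrous_fit <- function(object, ...) object$residuals

#' @export
predict.fibrous_fit <- function(object, newdata = NULL, ...) {
  lam <- if (is.null(newdata)) object$data$stretch else
    if (is.data.frame(newdata)) newdata$stretch else newdata
  uniaxial_response(lam, object$params)$stress
}

#' @export
print.fibrous_fit <- function(x, ...) {
  cat("Fibrous-matrix constitutive fit\n")
  print(round(x$coefficients, 5))
  cat(sprintf("RMSE %.4g MPa; Jacobian condition number %.3g\n",
              sqrt(mean(x$residuals^2)), x$condition_number))
  if (length(x$unidentifiable))
    cat("unidentifiable:", paste(x$unidentifiable, collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.fibrous_fit <- function(x, ...) {
  graphics::plot(x$data$stretch, x$data$stress, pch = 16, cex = 0.5,
                 xlab = "stretch", ylab = "stress (MPa)", ...)
  graphics::lines(x$data$stretch, x$fitted, col = 2, lwd = 2)
  invisible(x)
}

#' Numerical material tangent (6x6 Voigt)
#'
#' Central-difference material tangent \code{dS/dE} of the law, where S is
#' the second Piola-Kirchhoff stress and E the Green-Lagrange strain. Voigt
#' ordering (11, 22, 33, 23, 13, 12) with engineering shear strains, so the
#' matrix has major symmetry for any smooth hyperelastic state; loss of
#' symmetry beyond tolerance signals a non-smooth fiber-branch crossing and
#' raises a warning.
#'
#' @param state a [deformation_state()] or 3x3 deformation gradient.
#' @param params a [fibrous_params()] object.
#' @param h central-difference step on Green-Lagrange strain components
#'   (within [1e-8, 1e-4]).
#' @param sym_tol relative major-symmetry tolerance for the warning.
#' @return 6x6 tangent matrix, MPa.
#' @export
numerical_tangent <- function(state, params, h = 1e-6, sym_tol = 1e-6) {
  if (!inherits(state, "deformation_state"))
    state <- deformation_state(state)
  if (h < 1e-8 || h > 1e-4) stop("'h' must lie in [1e-8, 1e-4]")
  C0 <- state$C
  idx <- list(c(1, 1), c(2, 2), c(3, 3), c(2, 3), c(1, 3), c(1, 2))
  S_of_C <- function(C) {
    ec <- eigen(C, symmetric = TRUE)
    lam <- sqrt(pmax(ec$values, 1e-12))
    s <- as.numeric(principal_cauchy(matrix(lam, 1, 3), params))
    J <- prod(lam)
    # in the principal basis of C: S_a = J sigma_a / lambda_a^2
    ec$vectors %*% diag(J * s / lam^2) %*% t(ec$vectors)
  }
  voigt <- function(S) c(S[1, 1], S[2, 2], S[3, 3], S[2, 3], S[1, 3], S[1, 2])
  D <- matrix(0, 6, 6)
  for (j in 1:6) {
    ij <- idx[[j]]
    dC <- matrix(0, 3, 3)
    if (ij[1] == ij[2]) dC[ij[1], ij[2]] <- 2 * h  # dE_jj = h
    else { dC[ij[1], ij[2]] <- h; dC[ij[2], ij[1]] <- h }  # eng shear = h
    D[, j] <- (voigt(S_of_C(C0 + dC)) - voigt(S_of_C(C0 - dC))) / (2 * h)
  }
  asym <- max(abs(D - t(D))) / max(abs(D), .Machine$double.eps)
  if (asym > sym_tol)
    warning(sprintf(
      "tangent lost major symmetry (rel. %.2g): state may straddle a fiber branch",
      asym))
  dimnames(D) <- list(c("11", "22", "33", "23", "13", "12"),
                      c("11", "22", "33", "23", "13", "12"))
  D
}
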