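#' Fiber recruitment model of tendon strain stiffening
#'
#' Tendon's nonlinear toe region arises from crimped collagen fibers that
#' only begin to bear load once the tissue length exceeds their individual
#' slack length. The recruitment model treats slack lengths as Gaussian with
#' mean \code{mu} (mm) and standard deviation \code{sigma} (mm); each
#' recruited fiber is linear with average stiffness \code{K_avg} (N/mm), and
#' the total stiffness once all fibers are engaged is
#' \code{K_tot = K_avg * N_fibers}.
#'
#' @param mu mean fiber slack length, mm.
#' @param sigma slack-length standard deviation, mm (>= 0).
#' @param K_tot total recruited stiffness, N/mm (> 0).
#' @param N_fibers number of fibers (used by the discrete-sum mode).
#' @return an object of class \code{"recruitment_params"}.
#' @seealso [recruitment_cdf()], [recruitment_force()], [fit_recruitment()]
#' @export
recruitment_params <- function(mu, sigma, K_tot, N_fibers = 1000L) {
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (K_tot <= 0) stop("'K_tot' must be > 0")
  if (N_fibers < 1) stop("'N_fibers' must be >= 1")
  structure(list(mu = mu, sigma = sigma, K_tot = K_tot,
                 N_fibers = as.integer(N_fibers),
                 K_avg = K_tot / N_fibers),
            class = "recruitment_params")
}

#' @export
print.recruitment_params <- function(x, ...) {
  cat(sprintf(
    "Fiber recruitment parameters: mu = %.4g mm, sigma = %.4g mm, K_tot = %.4g N/mm\n",
    x$mu, x$sigma, x$K_tot))
  invisible(x)
}

#' Cumulative probability that a fiber is uncrimped
#'
#' Probability that a fiber's slack length is below \code{L0}, i.e. the
#' fraction of fibers recruited at tendon length \code{L0}: the Gaussian CDF
#' \code{pnorm((L0 - mu)/sigma)}. With \code{sigma = 0} the population is a
#' point mass at \code{mu} and the step branch (0 / 0.5 / 1) is returned.
#'
#' @param L0 tendon length(s), mm.
#' @param params a [recruitment_params()] object.
#' @return recruited fraction in \code{[0, 1]}, same length as \code{L0}.
#' @export
recruitment_cdf <- function(L0, params) {
  stopifnot(inherits(params, "recruitment_params"))
  if (params$sigma == 0) {
    p <- ifelse(L0 < params$mu, 0, ifelse(L0 > params$mu, 1, 0.5))
    return(p)
  }
  stats::pnorm((L0 - params$mu) / params$sigma)
}

#' Recruitment-model force at a given tendon length
#'
#' Total fiber force at tendon length \code{x}. In \code{"discrete"} mode the
#' force is the literal sum \code{K_avg * sum((x - L0_i) * H(x - L0_i))} over
#' \code{N_fibers} slack lengths sampled from the Gaussian population (H is
#' the Heaviside step). In \code{"expectation"} mode the population limit is
#' used: \code{K_tot * ((x - mu) * pnorm(z) + sigma * dnorm(z))} with
#' \code{z = (x - mu)/sigma}. Both are non-negative, non-decreasing and
#' convex in \code{x}.
#'
#' @param x tendon length(s), mm (>= 0).
#' @param params a [recruitment_params()] object.
#' @param mode \code{"expectation"} (default) or \code{"discrete"}.
#' @param seed RNG seed for the discrete slack-length sample.
#' @return force in N, same length as \code{x}.
#' @export
recruitment_force <- function(x, params, mode = c("expectation", "discrete"),
                              seed = 1L) {
  stopifnot(inherits(params, "recruitment_params"))
  mode <- match.arg(mode)
  if (any(x < 0)) stop("'x' must be >= 0")
  mu <- params$mu; sigma <- params$sigma
  if (mode == "expectation") {
    if (sigma == 0) return(params$K_tot * pmax(x - mu, 0))
    z <- (x - mu) / sigma
    return(params$K_tot * ((x - mu) * stats::pnorm(z) + sigma * stats::dnorm(z)))
  }
  L0 <- withr_seed(seed, stats::rnorm(params$N_fibers, mu, sigma))
  vapply(x, function(xi) params$K_avg * sum(pmax(xi - L0, 0)), numeric(1))
}

# evaluate expr under a local RNG seed without touching the global stream
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Fit the fiber recruitment model to a force-displacement curve
#'
#' Nonlinear least squares of the expectation-mode recruitment force against
#' measured force. The fit is parameterized in \code{(mu, log sigma, log
#' K_tot)} to keep \code{sigma} and \code{K_tot} positive, and is multistarted
#' from 5 deterministic initial guesses spanning the displacement range.
#' Wald confidence intervals come from the Jacobian at the optimum.
#'
#' The toe and linear regions must both be sampled: if the fitted
#' \code{mu + 2 sigma} exceeds the largest displacement the fit is an
#' extrapolation and a warning is attached (and raised).
#'
#' @param x displacement / tendon length, mm (or a 2-column matrix /
#'   data.frame with columns \code{x} and \code{force}).
#' @param force force, N (ignored when \code{x} is two-column).
#' @param gauge_length optional gauge length (mm); when given, \code{mu} is
#'   also reported as mean slack strain.
#' @param level confidence level for the intervals.
#' @return object of class \code{"recruitment_fit"} with elements
#'   \code{params} ([recruitment_params()]), \code{coefficients},
#'   \code{ci}, \code{fitted}, \code{residuals}, \code{converged},
#'   \code{extrapolated}, \code{slack_strain}, \code{data}.
#' @examples
#' p <- recruitment_params(mu = 1, sigma = 0.1, K_tot = 10)
#' x <- seq(0.5, 1.6, length.out = 200)
#' fit <- fit_recruitment(x, recruitment_force(x, p))
#' coef(fit)
#' @export
fit_recruitment <- function(x, force = NULL, gauge_length = NULL,
                            level = 0.95) {
  if (is.null(force)) {
    xy <- as.data.frame(x)
    x <- xy[[1]]; force <- xy[[2]]
  }
  ok <- is.finite(x) & is.finite(force)
  x <- x[ok]; force <- force[ok]
  if (length(x) < 5) stop("need at least 5 points to fit recruitment model")
  xr <- range(x)
  fmax <- max(force)
  if (fmax <= 0) stop("force curve carries no positive load")

  resid_fun <- function(theta) {
    p <- recruitment_params(theta[1], exp(theta[2]), exp(theta[3]))
    recruitment_force(x, p) - force
  }
  # deterministic multistart: mu across the displacement range, sigma a
  # fraction of the span, K_tot from the terminal secant slope
  span <- diff(xr)
  k0 <- max(fmax / max(span, 1e-12), 1e-6)
  starts <- lapply(c(0.15, 0.35, 0.5, 0.65, 0.85), function(f)
    c(xr[1] + f * span, log(0.1 * span), log(k0)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = s, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("recruitment fit failed from all starting points")
  th <- best$par
  pars <- recruitment_params(th[1], exp(th[2]), exp(th[3]))
  fitted <- recruitment_force(x, pars)
  res <- force - fitted
  n <- length(x); dof <- n - 3
  s2 <- sum(res^2) / max(dof, 1)
  J <- best$hessian  # J'J from nls.lm
  covth <- tryCatch(s2 * solve(J), error = function(e) matrix(NA, 3, 3))
  # delta method back to (mu, sigma, K_tot)
  g <- diag(c(1, pars$sigma, pars$K_tot))
  covp <- g %*% covth %*% t(g)
  se <- sqrt(pmax(diag(covp), 0))
  zq <- stats::qt(1 - (1 - level) / 2, max(dof, 1))
  est <- c(mu = pars$mu, sigma = pars$sigma, K_tot = pars$K_tot)
  ci <- cbind(lower = est - zq * se, upper = est + zq * se)
  # the toe must be inside the sampled range: above it the linear region was
  # never reached, below it the toe was never observed (e.g. purely linear
  # data with no toe at all)
  extrap <- (pars$mu + 2 * pars$sigma) > xr[2] ||
    (pars$mu - 2 * pars$sigma) < xr[1]
  if (extrap)
    warning("fitted toe region (mu +/- 2 sigma) extends beyond the sampled ",
            "displacement range; recruitment parameters are extrapolated")
  conv <- best$info %in% 1:4
  if (!conv) warning("recruitment fit did not formally converge (nls.lm info ",
                     best$info, ")")
  structure(list(params = pars, coefficients = est, se = se, ci = ci,
                 fitted = fitted, residuals = res, converged = conv,
                 extrapolated = extrap,
                 slack_strain = if (!is.null(gauge_length))
                   100 * (pars$mu - gauge_length) / gauge_length else NULL,
                 gauge_length = gauge_length,
                 data = data.frame(x = x, force = force),
                 deviance = best$deviance),
            class = "recruitment_fit")
}

#' @export
coef.recruitment_fit <- function(object, ...) object$coefficients

#' @export
residuals.recruitment_fit <- function(object, ...) object$residuals

#' @export
fitted.recruitment_fit <- function(object, ...) object$fitted

#' @export
predict.recruitment_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$data$x else
    if (is.data.frame(newdata)) newdata$x else newdata
  recruitment_force(x, object$params)
}

#' @export
print.recruitment_fit <- function(x, ...) {
  cat("Fiber recruitment model fit (expectation mode)\n")
  est <- cbind(estimate = x$coefficients, se = x$se, x$ci)
  print(round(est, 5))
  if (!is.null(x$slack_strain))
    cat(sprintf("mean slack strain: %.3f %%\n", x$slack_strain))
  if (x$extrapolated)
    cat("warning: mu + 2*sigma beyond data range (extrapolated toe)\n")
  invisible(x)
}

#' @export
summary.recruitment_fit <- function(object, ...) {
  object$rmse <- sqrt(mean(object$residuals^2))
  class(object) <- c("summary.recruitment_fit", class(object))
  object
}

#' @export
print.summary.recruitment_fit <- function(x, ...) {
  print.recruitment_fit(x)
  cat(sprintf("RMSE: %.5g N on %d points\n", x$rmse, nrow(x$data)))
  invisible(x)
}

#' @export
plot.recruitment_fit <- function(x, ...) {
  graphics::plot(x$data$x, x$data$force, pch = 16, cex = 0.5,
                 xlab = "displacement (mm)", ylab = "force (N)", ...)
  xs <- seq(min(x$data$x), max(x$data$x), length.out = 300)
  graphics::lines(xs, recruitment_force(xs, x$params), col = 2, lwd = 2)
  invisible(x)
}
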