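#' Circular statistics for axial orientation data
#'
#' Computes the circular mean and circular standard deviation (CSD) of a set
#' of angles living on a given period. Fiber and nucleus orientations are
#' axial (undirected) quantities: polarized-light fiber angles repeat every
#' 90 degrees, SHG fiber and nuclear orientations every 180 degrees. Angles
#' are mapped to the unit circle by scaling with \code{k = 360 / period}, so
#' the usual directional-statistics machinery applies.
#'
#' The CSD is \code{sqrt(-2 log Rbar) * (180 / pi) / k} degrees, where
#' \code{Rbar} is the mean resultant length of the scaled angles. Larger CSD
#' means more disorganization; identical angles give CSD 0.
#'
#' @param angles numeric vector of angles in degrees. \code{NA}s are dropped.
#' @param period period in degrees (90 for polarized-light fiber angles,
#'   180 for axial SHG/nuclear orientations, 360 for directional data).
#' @return an object of class \code{"circular_stats"}: a list with elements
#'   \code{mean} (circular mean, degrees, within one period centred on 0),
#'   \code{csd} (circular standard deviation, degrees; \code{Inf} and
#'   \code{degenerate = TRUE} when the resultant length is numerically 0),
#'   \code{rbar}, \code{period}, \code{n}.
#' @examples
#' circular_stats(c(10, 12, 8, 11), period = 180)
#' @export
circular_stats <- function(angles, period = 180) {
  angles <- angles[!is.na(angles)]
  if (length(angles) < 2L)
    stop("need at least 2 angles for circular statistics")
  if (!is.numeric(period) || period <= 0)
    stop("'period' must be a positive number of degrees")
  k <- 360 / period
  th <- angles * pi / 180 * k
  C <- mean(cos(th))
  S <- mean(sin(th))
  rbar <- sqrt(C^2 + S^2)
  degenerate <- rbar < 1e-12
  csd <- if (degenerate) Inf else sqrt(-2 * log(rbar)) * (180 / pi) / k
  mu <- if (degenerate) NA_real_ else atan2(S, C) / k * 180 / pi
  structure(list(mean = mu, csd = csd, rbar = rbar, period = period,
                 n = length(angles), degenerate = degenerate),
            class = "circular_stats")
}

#' @export
print.circular_stats <- function(x, ...) {
  cat(sprintf("Circular statistics (period %g deg, n = %d)\n", x$period, x$n))
  if (x$degenerate)
    cat("  degenerate: resultant length ~ 0 (antipodal / uniform angles)\n")
  else
    cat(sprintf("  mean = %.3f deg, CSD = %.3f deg, Rbar = %.4f\n",
                x$mean, x$csd, x$rbar))
  invisible(x)
}

#' Wrap angles into one period centred on a reference axis
#'
#' @param angles angles in degrees.
#' @param period period in degrees.
#' @return angles wrapped to \code{(-period/2, period/2]}.
#' @export
wrap_angle <- function(angles, period = 180) {
  a <- angles %% period
  a[a > period / 2] <- a[a > period / 2] - period
  # map exact -period/2 to +period/2 so the interval is half-open
  a[a == -period / 2] <- period / 2
  a
}

# von Mises sampler, Best & Fisher (1979) rejection algorithm.
# Returns angles in radians on the full circle, mean direction mu (radians).
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    nt <- sum(ok)
    if (nt > 0) {
      th <- sign(u3[ok] - 0.5) * acos(f[ok])
      out[(got + 1L):(got + nt)] <- th
      got <- got + nt
    }
  }
  wrap_angle((out + mu) * 180 / pi, 360) * pi / 180
}

#' Sample axial fiber angles from a von Mises distribution
#'
#' Draws undirected orientation angles whose doubled (or quadrupled) angle
#' follows a von Mises distribution — the standard circular analogue of a
#' Gaussian for axial data. \code{concentration} plays the role of the von
#' Mises kappa on the scaled circle; 0 gives the uniform (isotropic) limit.
#'
#' @param n number of angles.
#' @param mean_angle mean orientation, degrees.
#' @param concentration von Mises concentration (>= 0) on the scaled circle.
#' @param period axial period in degrees (180 for fibers/nuclei, 90 for
#'   polarized-light angle maps).
#' @return angles in degrees wrapped to \code{(-period/2, period/2]} about 0.
#' @export
r_axial_angles <- function(n, mean_angle, concentration, period = 180) {
  if (concentration < 0) stop("'concentration' must be >= 0")
  k <- 360 / period
  th <- rvonmises(n, wrap_angle(mean_angle, period) * pi / 180 * k,
                  concentration)
  wrap_angle(th * 180 / pi / k, period)
}

#' Analytic circular SD of the axial von Mises distribution
#'
#' Closed form used as the oracle for generator round-trip checks: for axial
#' angles whose scaled angle is von Mises with concentration \code{kappa},
#' the mean resultant length is \code{I1(kappa)/I0(kappa)} and the CSD on the
#' original angle scale is \code{sqrt(-2 log Rbar) / k} (in degrees).
#'
#' @param kappa von Mises concentration on the scaled circle.
#' @param period axial period in degrees.
#' @return CSD in degrees.
#' @export
vonmises_axial_csd <- function(kappa, period = 180) {
  k <- 360 / period
  rbar <- besselI(kappa, 1, expon.scaled = TRUE) /
    besselI(kappa, 0, expon.scaled = TRUE)
  sqrt(-2 * log(rbar)) * (180 / pi) / k
}

#' Concentration achieving a target axial circular SD
#'
#' Inverse of [vonmises_axial_csd()]: the von Mises concentration whose
#' axial circular standard deviation equals \code{csd} degrees. Solved by
#' monotone root bracketing.
#'
#' @param csd target CSD, degrees (within the period's attainable range).
#' @param period axial period in degrees.
#' @return concentration (kappa) on the scaled circle.
#' @export
kappa_for_csd <- function(csd, period = 180) {
  if (csd <= 0) stop("'csd' must be > 0")
  f <- function(k) vonmises_axial_csd(k, period) - csd
  if (f(1e5) > 0) return(1e5)   # tighter than kappa = 1e5 can express
  stats::uniroot(f, c(1e-4, 1e5), tol = 1e-10)$root
}
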