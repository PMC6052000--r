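#' Generate a synthetic polarized-light image stack
#'
#' Emulates a crossed-polarizer alignment-map series: the specimen is tiled
#' into square regions, each with a true fiber angle drawn from an axial von
#' Mises distribution (period 90 degrees, the degeneracy of crossed
#' polarizers), and each pixel responds to the polarizer angle as
#' \code{I = A * sin^2(2 * (theta_p - theta_f)) + B} plus Gaussian noise.
#'
#' @param mean_angle mean fiber angle, degrees (0 = loading axis).
#' @param concentration von Mises concentration of the region angles (>= 0;
#'   0 gives isotropy, large values near-perfect alignment).
#' @param n_angles number of polarizer angles (>= 4), evenly spaced over one
#'   90-degree period.
#' @param region_truth_grid integer c(rows, cols) of truth regions.
#' @param noise_sd pixel intensity noise SD.
#' @param seed integer RNG seed.
#' @param tile_px pixel side of one truth region tile.
#' @param A,B signal magnitude and offset of the polarizer response.
#' @param strain optional strain label (%) carried on the stack.
#' @return object of class \code{"polarizer_stack"}: list with
#'   \code{images} (list of matrices, one per polarizer angle),
#'   \code{angles} (degrees), \code{truth_angles} (rows x cols matrix of true
#'   fiber angles, degrees in (-45, 45]), \code{tile_px}, \code{strain}.
#' @export
gen_polarizer_stack <- function(mean_angle = 0, concentration = 4,
                                n_angles = 30L,
                                region_truth_grid = c(10L, 10L),
                                noise_sd = 0, seed = 1L, tile_px = 20L,
                                A = 100, B = 10, strain = NULL) {
  if (n_angles < 4)
    stop("insufficient sampling: need at least 4 polarizer angles")
  if (concentration < 0) stop("'concentration' must be >= 0")
  nr <- region_truth_grid[1]; nc <- region_truth_grid[2]
  withr_seed(seed, {
    th_f <- matrix(r_axial_angles(nr * nc, mean_angle, concentration,
                                  period = 90), nr, nc)
    angles <- seq(0, 90, length.out = n_angles + 1)[seq_len(n_angles)]
    big_truth <- th_f[rep(seq_len(nr), each = tile_px),
                      rep(seq_len(nc), each = tile_px)]
    images <- lapply(angles, function(tp) {
      img <- A * sin(2 * (tp - big_truth) * pi / 180)^2 + B
      if (noise_sd > 0)
        img <- img + matrix(stats::rnorm(length(img), 0, noise_sd),
                            nrow(img), ncol(img))
      img
    })
    structure(list(images = images, angles = angles, truth_angles = th_f,
                   tile_px = tile_px, strain = strain),
              class = "polarizer_stack")
  })
}

#' @export
print.polarizer_stack <- function(x, ...) {
  cat(sprintf(
    "Polarizer stack: %d images of %d x %d px, %d x %d truth regions\n",
    length(x$images), nrow(x$images[[1]]), ncol(x$images[[1]]),
    nrow(x$truth_angles), ncol(x$truth_angles)))
  if (!is.null(x$strain)) cat(sprintf("strain label: %g %%\n", x$strain))
  invisible(x)
}

#' Generate a synthetic SHG-like fiber texture
#'
#' Renders straight fiber segments with orientations drawn from an axial von
#' Mises distribution (period 180 degrees) onto a dark background. Segments
#' are splatted with bilinear weights at sub-pixel steps, giving smooth
#' (anti-aliased) lines suitable for Fourier orientation analysis.
#'
#' @param mean_angle mean fiber angle, degrees (0 = horizontal).
#' @param concentration von Mises concentration (>= 0).
#' @param fiber_density fibers per 1000 px^2 (> 0).
#' @param seed integer RNG seed.
#' @param size image side, px.
#' @param fiber_length mean segment length, px.
#' @param angles optional explicit vector of truth angles (overrides the von
#'   Mises draw; recycled/truncated to the fiber count).
#' @return list with \code{image} (size x size matrix) and
#'   \code{truth_angles} (degrees in (-90, 90]).
#' @export
gen_shg_image <- function(mean_angle = 0, concentration = 4,
                          fiber_density = 2, seed = 1L, size = 256L,
                          fiber_length = 60, angles = NULL) {
  if (fiber_density <= 0) stop("empty image: 'fiber_density' must be > 0")
  n_fib <- max(1L, round(fiber_density * size^2 / 1000))
  withr_seed(seed, {
    th <- if (is.null(angles))
      r_axial_angles(n_fib, mean_angle, concentration, period = 180)
    else rep_len(angles, n_fib)
    img <- matrix(0, size, size)
    cx <- stats::runif(n_fib, 1, size)
    cy <- stats::runif(n_fib, 1, size)
    len <- pmax(stats::rnorm(n_fib, fiber_length, fiber_length / 4), 5)
    step <- 0.5
    for (i in seq_len(n_fib)) {
      # image row index = y, col = x; angle measured from +x axis
      dx <- cos(th[i] * pi / 180); dy <- sin(th[i] * pi / 180)
      s <- seq(-len[i] / 2, len[i] / 2, by = step)
      px <- cx[i] + s * dx; py <- cy[i] + s * dy
      ok <- px >= 1 & px <= size - 1 & py >= 1 & py <= size - 1
      if (!any(ok)) next
      px <- px[ok]; py <- py[ok]
      x0 <- floor(px); y0 <- floor(py)
      fx <- px - x0; fy <- py - y0
      for (corner in 1:4) {
        xi <- x0 + (corner == 2 | corner == 4)
        yi <- y0 + (corner >= 3)
        w <- (ifelse(corner == 2 | corner == 4, fx, 1 - fx)) *
          (ifelse(corner >= 3, fy, 1 - fy))
        idx <- cbind(yi, xi)
        img[idx] <- img[idx] + w * step
      }
    }
    list(image = img, truth_angles = wrap_angle(th, 180))
  })
}

#' Generate a synthetic nuclei field
#'
#' Places non-overlapping ellipses ("nuclei") on a dark background with a
#' controlled aspect-ratio distribution and axial von Mises angular
#' dispersion, returning a labeled image and the exact truth table.
#'
#' @param count number of nuclei to place.
#' @param nAR_mean,nAR_sd mean and SD of the nuclear aspect ratio
#'   (major/minor axis; draws are truncated at 1).
#' @param angle_concentration von Mises concentration of nucleus
#'   orientations (period 180 degrees; >= 0).
#' @param seed integer RNG seed.
#' @param size image side, px.
#' @param mean_area mean nucleus area, px^2.
#' @param mean_angle mean orientation, degrees.
#' @param max_tries placement attempts before giving up.
#' @return list with \code{labels} (integer matrix, 0 = background),
#'   \code{image} (binary intensity matrix) and \code{truth}
#'   (data.frame: x, y, major, minor, angle, nAR; axes are semi-axes in px).
#' @export
gen_nuclei_image <- function(count, nAR_mean = 2.5, nAR_sd = 0.5,
                             angle_concentration = 6, seed = 1L,
                             size = 512L, mean_area = 150,
                             mean_angle = 0, max_tries = 200L) {
  withr_seed(seed, {
    ars <- pmax(stats::rnorm(count, nAR_mean, nAR_sd), 1)
    angs <- r_axial_angles(count, mean_angle, angle_concentration, 180)
    area <- pmax(stats::rnorm(count, mean_area, mean_area / 6), 20)
    # semi-axes: pi * a * b = area, a / b = nAR
    b <- sqrt(area / (pi * ars)); a <- b * ars
    placed <- matrix(numeric(0), 0, 3)  # x, y, bounding radius
    xs <- ys <- numeric(count)
    for (i in seq_len(count)) {
      ok <- FALSE
      for (k in seq_len(max_tries)) {
        x <- stats::runif(1, a[i] + 2, size - a[i] - 1)
        y <- stats::runif(1, a[i] + 2, size - a[i] - 1)
        if (nrow(placed) == 0 ||
            all(sqrt((placed[, 1] - x)^2 + (placed[, 2] - y)^2) >
                  placed[, 3] + a[i] + 1)) {
          ok <- TRUE; break
        }
      }
      if (!ok)
        stop(sprintf(
          "placement error: could not place %d non-overlapping nuclei (stopped at %d)",
          count, i - 1L))
      placed <- rbind(placed, c(x, y, a[i]))
      xs[i] <- x; ys[i] <- y
    }
    labels <- matrix(0L, size, size)
    ct <- cos(angs * pi / 180); st <- sin(angs * pi / 180)
    for (i in seq_len(count)) {
      r0 <- max(1, floor(ys[i] - a[i])); r1 <- min(size, ceiling(ys[i] + a[i]))
      c0 <- max(1, floor(xs[i] - a[i])); c1 <- min(size, ceiling(xs[i] + a[i]))
      cc <- (c0:c1); rr <- (r0:r1)
      X <- outer(rep(1, length(rr)), cc) - xs[i]
      Y <- outer(rr, rep(1, length(cc))) - ys[i]
      # rotate into the ellipse frame (x along major axis)
      U <- X * ct[i] + Y * st[i]
      V <- -X * st[i] + Y * ct[i]
      inside <- (U / a[i])^2 + (V / b[i])^2 <= 1
      sub <- labels[rr, cc]
      sub[inside] <- i
      labels[rr, cc] <- sub
    }
    list(labels = labels, image = (labels > 0) * 1,
         truth = data.frame(x = xs, y = ys, major = a, minor = b,
                            angle = angs, nAR = a / b))
  })
}
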