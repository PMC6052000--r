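#' Region grid for polarized-light noise filtering
#'
#' Tiles an image with square analysis regions of a given area whose
#' centres sit on a regular grid, and returns the mean intensity of each
#' region (per image when a stack is given). Averaging over regions filters
#' pixel noise before the polarizer-angle fit.
#'
#' @param dim image dimensions c(rows, cols), or a matrix whose dimensions
#'   are used.
#' @param region_area_px2 region area in px^2 (default 100, i.e. 10 x 10
#'   regions).
#' @param spacing_px centre-to-centre spacing, px.
#' @return data.frame with region \code{row}, \code{col} centres (px) and
#'   index ranges \code{r0, r1, c0, c1}.
#' @export
region_grid <- function(dim, region_area_px2 = 100, spacing_px = 20) {
  if (is.matrix(dim)) dim <- base::dim(dim)
  side <- round(sqrt(region_area_px2))
  if (side > min(dim)) stop("image smaller than one region")
  half <- side / 2
  centers_r <- seq(spacing_px / 2, dim[1] - half + half, by = spacing_px)
  centers_c <- seq(spacing_px / 2, dim[2] - half + half, by = spacing_px)
  centers_r <- centers_r[centers_r - half >= 0 & centers_r + half <= dim[1]]
  centers_c <- centers_c[centers_c - half >= 0 & centers_c + half <= dim[2]]
  g <- expand.grid(row = centers_r, col = centers_c)
  g$r0 <- round(g$row - half) + 1L; g$r1 <- round(g$row + half)
  g$c0 <- round(g$col - half) + 1L; g$c1 <- round(g$col + half)
  g
}

#' Mean region intensities of an image or stack
#'
#' @param images a matrix or list of matrices (a stack).
#' @param grid a [region_grid()] data.frame (defaults to the standard grid).
#' @return matrix of region means, regions x images.
#' @export
region_means <- function(images, grid = NULL) {
  if (is.matrix(images)) images <- list(images)
  if (is.null(grid)) grid <- region_grid(dim(images[[1]]))
  sapply(images, function(img)
    vapply(seq_len(nrow(grid)), function(i)
      mean(img[grid$r0[i]:grid$r1[i], grid$c0[i]:grid$c1[i]]), numeric(1)))
}

#' Fit the polarizer response of one region
#'
#' Fits \code{I(theta_p) = A sin^2(2 (theta_p - theta_f)) + B} to region
#' mean intensity versus polarizer angle. Using
#' \code{sin^2(x) = (1 - cos 2x)/2} the model is linear in
#' \code{(cos 4 theta_p, sin 4 theta_p)}, so the fit is exact least squares
#' with no iteration; \code{theta_f} is the angle of minimum intensity
#' (the mean fiber direction), wrapped to (-45, 45] about the loading axis.
#' Regions whose signal magnitude A is not significantly positive are
#' flagged low-signal and should be excluded from circular statistics.
#'
#' @param intensity region mean intensities, one per polarizer angle.
#' @param angles polarizer angles, degrees (>= 4 distinct values).
#' @param min_snr signal significance threshold: A must exceed
#'   \code{min_snr} residual SDs to count as signal.
#' @return list: \code{theta_f} (degrees), \code{A}, \code{B},
#'   \code{low_signal} (logical), \code{rmse}.
#' @export
fit_region_orientation <- function(intensity, angles, min_snr = 3) {
  if (length(unique(angles)) < 4)
    stop("need at least 4 distinct polarizer angles")
  th <- angles * pi / 180
  X <- cbind(1, cos(4 * th), sin(4 * th))
  cf <- stats::lm.fit(X, intensity)$coefficients
  # I = (B + A/2) - (A/2) cos(4(th - th_f))
  amp <- 2 * sqrt(cf[2]^2 + cf[3]^2)
  theta_f <- atan2(-cf[3], -cf[2]) / 4 * 180 / pi
  theta_f <- wrap_angle(theta_f, 90)
  res <- intensity - X %*% cf
  rmse <- sqrt(mean(res^2))
  low <- amp < min_snr * rmse | amp < .Machine$double.eps^0.5
  list(theta_f = as.numeric(theta_f), A = as.numeric(amp),
       B = as.numeric(cf[1] - amp / 2), low_signal = as.logical(low),
       rmse = rmse)
}

#' Orientation field of a polarizer stack
#'
#' Applies [region_means()] and [fit_region_orientation()] to every region
#' of a polarizer stack, and summarizes fiber disorganization as the
#' circular standard deviation (period 90 degrees) over regions with
#' adequate signal.
#'
#' @param stack a \code{"polarizer_stack"} (see [gen_polarizer_stack()]),
#'   or a list with \code{images} and \code{angles}.
#' @param grid optional [region_grid()]; default spans the image at the
#'   standard 100 px^2 / 20 px spacing.
#' @return object of class \code{"orientation_field"}: data.frame
#'   \code{regions} (row, col, theta_f, A, B, low_signal), \code{csd}
#'   ([circular_stats()] of the retained angles), \code{strain}.
#' @export
polarizer_orientation <- function(stack, grid = NULL) {
  if (is.null(grid)) grid <- region_grid(dim(stack$images[[1]]))
  rm_ <- region_means(stack$images, grid)
  fits <- lapply(seq_len(nrow(grid)), function(i)
    fit_region_orientation(rm_[i, ], stack$angles))
  regions <- data.frame(row = grid$row, col = grid$col,
                        theta_f = vapply(fits, `[[`, numeric(1), "theta_f"),
                        A = vapply(fits, `[[`, numeric(1), "A"),
                        B = vapply(fits, `[[`, numeric(1), "B"),
                        low_signal = vapply(fits, `[[`, logical(1),
                                            "low_signal"))
  keep <- !regions$low_signal
  cs <- if (sum(keep) >= 2)
    circular_stats(regions$theta_f[keep], period = 90) else NULL
  structure(list(regions = regions, csd = cs,
                 strain = stack$strain),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("Orientation field: %d regions (%d low-signal)\n",
              nrow(x$regions), sum(x$regions$low_signal)))
  if (!is.null(x$csd))
    cat(sprintf("  CSD = %.3f deg, circular mean = %.3f deg\n",
                x$csd$csd, x$csd$mean))
  invisible(x)
}

#' Collagen realignment transition from CSD versus strain
#'
#' Fiber realignment shows as a kink in the circular standard deviation
#' versus applied strain: CSD falls steeply once fibers begin reorienting.
#' The transition strain is the breakpoint of a continuous two-segment
#' (bilinear) least-squares fit, located by exhaustive search over an
#' interior grid followed by golden-section refinement of the residual sum
#' of squares.
#'
#' @param strain applied strains, % (>= 5 points).
#' @param csd CSD at each strain, degrees.
#' @param n_grid breakpoints tried in the exhaustive stage.
#' @return object of class \code{"bilinear_fit"}: \code{transition_strain},
#'   \code{slopes} (before/after), \code{intercept}, \code{sse},
#'   \code{degenerate} (TRUE when a single line explains the data as well,
#'   so the transition is undefined).
#' @export
realignment_transition <- function(strain, csd, n_grid = 50L) {
  if (length(strain) < 5) stop("need at least 5 strain points")
  if (length(csd) != length(strain)) stop("lengths differ")
  o <- order(strain); strain <- strain[o]; csd <- csd[o]
  sse_at <- function(br) {
    X <- cbind(1, strain, pmax(strain - br, 0))
    sum(stats::lm.fit(X, csd)$residuals^2)
  }
  lo <- strain[2]; hi <- strain[length(strain) - 1]
  grid <- seq(lo, hi, length.out = n_grid)
  sse_g <- vapply(grid, sse_at, numeric(1))
  b0 <- grid[which.min(sse_g)]
  # golden-section refinement around the best grid cell
  gold <- (sqrt(5) - 1) / 2
  aa <- max(lo, b0 - diff(range(grid)) / n_grid)
  bb <- min(hi, b0 + diff(range(grid)) / n_grid)
  x1 <- bb - gold * (bb - aa); x2 <- aa + gold * (bb - aa)
  f1 <- sse_at(x1); f2 <- sse_at(x2)
  for (i in 1:60) {
    if (f1 < f2) { bb <- x2; x2 <- x1; f2 <- f1
      x1 <- bb - gold * (bb - aa); f1 <- sse_at(x1)
    } else { aa <- x1; x1 <- x2; f1 <- f2
      x2 <- aa + gold * (bb - aa); f2 <- sse_at(x2) }
    if (bb - aa < 1e-10 * max(1, hi)) break
  }
  br <- (aa + bb) / 2
  X <- cbind(1, strain, pmax(strain - br, 0))
  fit <- stats::lm.fit(X, csd)
  sse <- sum(fit$residuals^2)
  # degenerate when a single line does essentially as well: the breakpoint
  # buys no meaningful share of the total variation
  lin <- stats::lm.fit(cbind(1, strain), csd)
  sse_lin <- sum(lin$residuals^2)
  tss <- sum((csd - mean(csd))^2)
  degenerate <- (sse_lin - sse) <= 1e-6 * tss + 1e-12 ||
    tss < .Machine$double.eps
  structure(list(transition_strain = br,
                 slopes = c(before = unname(fit$coefficients[2]),
                            after = unname(fit$coefficients[2] +
                                             fit$coefficients[3])),
                 intercept = unname(fit$coefficients[1]),
                 sse = sse, degenerate = degenerate,
                 data = data.frame(strain = strain, csd = csd)),
            class = "bilinear_fit")
}

#' @export
print.bilinear_fit <- function(x, ...) {
  if (x$degenerate)
    cat("Bilinear fit: degenerate (no detectable transition)\n")
  else
    cat(sprintf(
      "Realignment transition at %.3f %% strain (slopes %.3f -> %.3f deg/%%)\n",
      x$transition_strain, x$slopes[1], x$slopes[2]))
  invisible(x)
}

#' @export
coef.bilinear_fit <- function(object, ...)
  c(transition_strain = object$transition_strain, object$slopes)

#' Fiber orientation of an SHG image by Fourier analysis
#'
#' Dominant fiber orientation per window from the second moments of the
#' windowed power spectrum: the principal axis of spectral energy is
#' perpendicular to the fiber direction, so the reported angle is the
#' spectral principal axis rotated by 90 degrees (axial, period 180).
#' Windows whose spectral energy (DC excluded) falls below
#' \code{energy_floor} times the median window energy are masked. A
#' histogram of window angles and their circular statistics summarize the
#' image.
#'
#' @param image 2-D intensity matrix.
#' @param window window side, px (power of 2 recommended).
#' @param step window step, px (default \code{window}, i.e. no overlap).
#' @param energy_floor masking threshold relative to the median window
#'   energy.
#' @param hist_breaks histogram bin edges, degrees.
#' @return object of class \code{"shg_orientation"}: \code{windows}
#'   (data.frame row, col, angle, energy, masked), \code{csd}
#'   ([circular_stats()], period 180), \code{histogram} (\code{hist}
#'   object of retained angles).
#' @export
shg_orientation <- function(image, window = 64L, step = window,
                            energy_floor = 0.1,
                            hist_breaks = seq(-90, 90, by = 10)) {
  dims <- dim(image)
  if (any(dims < window)) stop("image smaller than the analysis window")
  rows <- seq(1, dims[1] - window + 1, by = step)
  cols <- seq(1, dims[2] - window + 1, by = step)
  han <- 0.5 - 0.5 * cos(2 * pi * seq_len(window) / (window + 1))
  W <- outer(han, han)
  # spectral frequency coordinates (centred)
  fr <- c(0:(window / 2), -(window / 2 - 1):-1)[1:window]
  FY <- matrix(fr, window, window)        # row frequency (y / image rows)
  FX <- t(FY)                             # column frequency (x)
  res <- list(); k <- 0L
  for (r0 in rows) for (c0 in cols) {
    blk <- image[r0:(r0 + window - 1), c0:(c0 + window - 1)]
    blk <- (blk - mean(blk)) * W
    P <- Mod(stats::fft(blk))^2
    P[1, 1] <- 0
    E <- sum(P)
    k <- k + 1L
    if (E <= 0) {
      res[[k]] <- data.frame(row = r0, col = c0, angle = NA, energy = 0)
      next
    }
    # second moments of spectral energy (axial: use doubled-angle sums)
    # angle of spectral point measured in (x, y) = (col, row) convention
    c2 <- sum(P * (FX^2 - FY^2)) / E
    s2 <- sum(P * (2 * FX * FY)) / E
    ang_spec <- 0.5 * atan2(s2, c2) * 180 / pi
    # fibers are perpendicular to the dominant spectral axis
    ang <- wrap_angle(ang_spec + 90, 180)
    res[[k]] <- data.frame(row = r0, col = c0, angle = ang, energy = E)
  }
  win <- do.call(rbind, res)
  med <- stats::median(win$energy)
  win$masked <- win$energy < energy_floor * med | is.na(win$angle)
  keep <- win$angle[!win$masked]
  cs <- if (length(keep) >= 2) circular_stats(keep, period = 180) else NULL
  h <- graphics::hist(wrap_angle(keep, 180), breaks = hist_breaks,
                      plot = FALSE)
  structure(list(windows = win, csd = cs, histogram = h),
            class = "shg_orientation")
}

#' @export
print.shg_orientation <- function(x, ...) {
  cat(sprintf("SHG orientation: %d windows (%d masked)\n",
              nrow(x$windows), sum(x$windows$masked)))
  if (!is.null(x$csd))
    cat(sprintf("  dominant angle = %.2f deg, CSD = %.2f deg\n",
                x$csd$mean, x$csd$csd))
  invisible(x)
}

# Otsu threshold on a numeric matrix (EBImage's otsu expects [0,1] images;
# computed here on a 256-bin histogram of the rescaled range)
.otsu <- function(img, n_bins = 256L) {
  rng <- range(img)
  if (diff(rng) == 0) return(rng[1])
  x <- (img - rng[1]) / diff(rng)
  h <- tabulate(pmin(floor(x * n_bins) + 1L, n_bins), n_bins)
  p <- h / sum(h)
  w <- cumsum(p)
  mu <- cumsum(p * (seq_len(n_bins) - 0.5))
  mu_t <- mu[n_bins]
  bc <- (mu_t * w - mu)^2 / (w * (1 - w))
  bc[!is.finite(bc)] <- 0
  t_star <- which.max(bc) / n_bins
  rng[1] + t_star * diff(rng)
}

# 4-connected component labeling by BFS flood fill
.label_components <- function(mask) {
  dims <- dim(mask)
  lab <- matrix(0L, dims[1], dims[2])
  cur <- 0L
  idx_all <- which(mask)
  for (start in idx_all) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue
      queue <- integer(0)
      r <- (q - 1L) %% dims[1] + 1L
      cc <- (q - 1L) %/% dims[1] + 1L
      for (d in 1:4) {
        rr <- r + c(-1L, 1L, 0L, 0L)[d]
        c2 <- cc + c(0L, 0L, -1L, 1L)[d]
        ok <- rr >= 1L & rr <= dims[1] & c2 >= 1L & c2 <= dims[2]
        nb <- (c2[ok] - 1L) * dims[1] + rr[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) { lab[nb] <- cur; queue <- c(queue, nb) }
      }
      queue <- unique(queue)
    }
  }
  lab
}

#' Segment nuclei and measure shape and organization
#'
#' Global threshold (Otsu by default), connected-component labeling, size
#' filter, and per-component second-moment ellipse: the eigenvalues of the
#' pixel covariance give semi-axes \code{major = 2 sqrt(l1)},
#' \code{minor = 2 sqrt(l2)} (exact for a filled ellipse), the eigenvector
#' the orientation. Nuclear aspect ratio nAR = major/minor; nuclear
#' disorganization nCSD is the circular SD (period 180) of orientations.
#'
#' @param image 2-D intensity matrix, or an integer label matrix (values
#'   > 0 are used as labels directly when \code{is_labeled = TRUE}).
#' @param threshold \code{"otsu"} or a numeric threshold.
#' @param min_area,max_area component size filter, px.
#' @param is_labeled treat \code{image} as a pre-labeled matrix.
#' @param weighted use intensity-weighted moments (grayscale input only):
#'   partial-coverage (anti-aliased) boundary pixels then contribute
#'   fractionally, which removes most of the pixelation bias on small
#'   nuclei. Ignored for label input, where all weights are 1.
#' @return object of class \code{"nuclei_shapes"}: \code{shapes}
#'   (data.frame label, x, y, major, minor, angle, nAR, area),
#'   \code{nAR_mean}, \code{nAR_sd}, \code{ncsd} (degrees, or NA when
#'   fewer than 2 nuclei).
#' @export
segment_nuclei <- function(image, threshold = "otsu", min_area = 20,
                           max_area = Inf, is_labeled = FALSE,
                           weighted = TRUE) {
  if (is_labeled) {
    lab <- image
    wimg <- NULL
  } else {
    thr <- if (identical(threshold, "otsu")) .otsu(image) else threshold
    lab <- .label_components(image > thr)
    wimg <- if (weighted) pmax(image - min(image), 0) else NULL
  }
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  rows <- lapply(ids, function(id) {
    px <- which(lab == id)
    area <- length(px)
    if (area < min_area || area > max_area) return(NULL)
    r <- (px - 1L) %% nrow(lab) + 1L
    cc <- (px - 1L) %/% nrow(lab) + 1L
    x <- cc; y <- r             # x along columns, y along rows
    w <- if (is.null(wimg)) rep(1, area) else wimg[px]
    w <- w / sum(w)
    mx <- sum(w * x); my <- sum(w * y)
    cxx <- sum(w * (x - mx)^2); cyy <- sum(w * (y - my)^2)
    cxy <- sum(w * (x - mx) * (y - my))
    if (!is.null(wimg)) {
      # intensity-as-coverage sampling convolves the shape with the unit
      # pixel box, inflating each axis variance by exactly 1/12
      cxx <- max(cxx - 1 / 12, 1e-9); cyy <- max(cyy - 1 / 12, 1e-9)
    }
    tr <- cxx + cyy; disc <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
    l1 <- tr / 2 + disc; l2 <- max(tr / 2 - disc, 1e-12)
    ang <- 0.5 * atan2(2 * cxy, cxx - cyy) * 180 / pi
    data.frame(label = id, x = mx, y = my,
               major = 2 * sqrt(l1), minor = 2 * sqrt(l2),
               angle = wrap_angle(ang, 180), nAR = sqrt(l1 / l2),
               area = area)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0) {
    warning("no nuclei retained after segmentation and size filtering")
    shapes <- data.frame(label = integer(0), x = numeric(0), y = numeric(0),
                         major = numeric(0), minor = numeric(0),
                         angle = numeric(0), nAR = numeric(0),
                         area = integer(0))
  } else shapes <- do.call(rbind, rows)
  ncsd <- if (nrow(shapes) >= 2)
    circular_stats(shapes$angle, period = 180)$csd else NA_real_
  structure(list(shapes = shapes,
                 nAR_mean = if (nrow(shapes)) mean(shapes$nAR) else NA_real_,
                 nAR_sd = if (nrow(shapes) > 1) stats::sd(shapes$nAR)
                 else NA_real_,
                 ncsd = ncsd),
            class = "nuclei_shapes")
}

#' @export
print.nuclei_shapes <- function(x, ...) {
  cat(sprintf("Nuclei: %d segmented, nAR = %.3f +/- %.3f, nCSD = %.3f deg\n",
              nrow(x$shapes), x$nAR_mean, x$nAR_sd, x$ncsd))
  invisible(x)
}

#' Percent F-actin positive staining in an ROI
#'
#' Contrast-stretches the ROI, applies an automatic (Otsu) or fixed
#' threshold, and reports positive pixels as a percentage of the ROI.
#'
#' @param image 2-D intensity matrix.
#' @param roi logical mask of the ROI (default: whole image).
#' @param threshold \code{"otsu"} or a numeric threshold applied to the
#'   contrast-stretched (0-1) intensities.
#' @return percent positive (0-100).
#' @export
factin_fraction <- function(image, roi = NULL, threshold = "otsu") {
  if (is.null(roi)) roi <- matrix(TRUE, nrow(image), ncol(image))
  if (!any(roi)) stop("empty ROI")
  v <- image[roi]
  rng <- range(v)
  if (diff(rng) == 0) return(0)
  v <- (v - rng[1]) / diff(rng)
  thr <- if (identical(threshold, "otsu")) .otsu(matrix(v)) else threshold
  100 * mean(v > thr)
}
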