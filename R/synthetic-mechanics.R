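#' Cyclic loading protocol description
#'
#' Encodes the tensile-testing protocol applied to a tendon explant:
#' preconditioning, dynamic (cyclic) loading at low or high magnitude for 0,
#' 10 or 1000 cycles at 1 Hz, a quasi-static ramp at 0.1 %strain/s to 1 % or
#' 10 % strain, a stress-relaxation hold, a frequency sweep at 0.125 % strain
#' amplitude (0.1, 1, 5, 10 Hz), and an optional recovery hold at 0 % strain.
#'
#' @param precondition_cycles number of preconditioning cycles.
#' @param cyclic_magnitude \code{"zero"}, \code{"low"} or \code{"high"}.
#' @param cycle_count number of dynamic loading cycles: 0, 10 or 1000.
#' @param frequency dynamic loading frequency, Hz.
#' @param ramp_rate quasi-static ramp rate, %strain/s.
#' @param target_strain ramp target strain, % (1 or 10).
#' @param relaxation_hold stress-relaxation hold duration at the target
#'   strain, s.
#' @param sweep_amplitude frequency-sweep strain amplitude, %.
#' @param sweep_frequencies frequency-sweep frequencies, Hz (all > 0).
#' @param sweep_cycles cycles recorded per sweep frequency.
#' @param recovery_hold recovery duration at 0 % strain, s (0 or 1000).
#' @return object of class \code{"loading_protocol"}.
#' @export
loading_protocol <- function(precondition_cycles = 10L,
                             cyclic_magnitude = c("zero", "low", "high"),
                             cycle_count = 0L,
                             frequency = 1,
                             ramp_rate = 0.1,
                             target_strain = 1,
                             relaxation_hold = 100,
                             sweep_amplitude = 0.125,
                             sweep_frequencies = c(0.1, 1, 5, 10),
                             sweep_cycles = 10L,
                             recovery_hold = 0) {
  cyclic_magnitude <- match.arg(cyclic_magnitude)
  if (!cycle_count %in% c(0L, 10L, 1000L))
    stop("'cycle_count' must be 0, 10 or 1000")
  if (!target_strain %in% c(1, 10))
    stop("'target_strain' must be 1 or 10 (% strain)")
  if (any(sweep_frequencies <= 0) || frequency <= 0)
    stop("frequencies must be strictly positive")
  if (ramp_rate <= 0) stop("'ramp_rate' must be > 0")
  structure(list(precondition_cycles = as.integer(precondition_cycles),
                 cyclic_magnitude = cyclic_magnitude,
                 cycle_count = as.integer(cycle_count),
                 frequency = frequency, ramp_rate = ramp_rate,
                 target_strain = target_strain,
                 relaxation_hold = relaxation_hold,
                 sweep_amplitude = sweep_amplitude,
                 sweep_frequencies = sweep_frequencies,
                 sweep_cycles = as.integer(sweep_cycles),
                 recovery_hold = recovery_hold),
            class = "loading_protocol")
}

#' Ground-truth container for the synthetic study
#'
#' Bundles every quantity the generators need: the fiber-recruitment
#' population, the fibrous-matrix constitutive parameters, fiber-angle and
#' nuclear distributions, specimen geometry, the injected viscoelastic
#' behaviour, and regression-table coefficients. All generated data derive
#' from these values, so estimator round-trips can be checked exactly.
#'
#' @param recruitment a [recruitment_params()] object (slack lengths in mm).
#' @param matrix a [fibrous_params()] object, or NULL.
#' @param fiber_angle list: \code{mean} (deg), \code{concentration} (>= 0).
#' @param nuclei list: \code{count}, \code{nAR_mean}, \code{nAR_sd},
#'   \code{angle_concentration} (>= 0).
#' @param geometry list: \code{gauge_length} (mm), \code{area} (mm^2).
#' @param visco list: \code{phase_lag} (rad, sweep stress-strain lag),
#'   \code{damping} (N s/mm, cyclic viscous damper), \code{relax_frac}
#'   (equilibrium/peak stress ratio of the relaxation hold), \code{tau}
#'   (relaxation time constant, s), \code{laxity_rate} (mm peak drift per
#'   cycle under dynamic loading).
#' @param regression list: \code{coefficients} (named, on model-matrix
#'   columns), \code{resid_sd}, \code{ar1_rho}.
#' @return object of class \code{"synthetic_truth"}.
#' @export
synthetic_truth <- function(recruitment = recruitment_params(5.05, 0.025, 30),
                            matrix = NULL,
                            fiber_angle = list(mean = 0, concentration = 8),
                            nuclei = list(count = 150, nAR_mean = 2.5,
                                          nAR_sd = 0.5,
                                          angle_concentration = 6),
                            geometry = list(gauge_length = 5, area = 1),
                            visco = list(phase_lag = 0.1, damping = 0.02,
                                         relax_frac = 0.6, tau = 10,
                                         laxity_rate = 0),
                            regression = list(coefficients = NULL,
                                              resid_sd = 1, ar1_rho = 0)) {
  stopifnot(inherits(recruitment, "recruitment_params"))
  if (fiber_angle$concentration < 0 || nuclei$angle_concentration < 0)
    stop("angle concentrations must be >= 0")
  if (nuclei$nAR_sd < 0) stop("nAR_sd must be >= 0")
  structure(list(recruitment = recruitment, matrix = matrix,
                 fiber_angle = fiber_angle, nuclei = nuclei,
                 geometry = geometry, visco = visco,
                 regression = regression),
            class = "synthetic_truth")
}

#' Generate a synthetic force-displacement record
#'
#' Forward model: displacement is prescribed segment by segment from the
#' loading protocol; quasi-static force follows the fiber-recruitment model
#' evaluated at tendon length \code{gauge_length + displacement}, a linear
#' viscous damper adds rate-dependent force during cyclic segments (producing
#' hysteresis), the relaxation hold decays exponentially toward
#' \code{relax_frac} of the peak force, and frequency-sweep segments carry a
#' pure injected stress-strain phase lag so that tan-delta extraction has a
#' known truth. Additive Gaussian noise of SD \code{noise_sd} is applied to
#' force. Deterministic given \code{seed}.
#'
#' @param truth a [synthetic_truth()] object.
#' @param protocol a [loading_protocol()] object.
#' @param noise_sd force noise SD, N (>= 0).
#' @param seed integer RNG seed.
#' @param sample_rate sampling rate, Hz (the instrument acquired at
#'   100-1000 Hz; default 100).
#' @return object of class \code{"fd_record"}: a list with \code{data}
#'   (data.frame time, displacement, force, segment), \code{gauge_length},
#'   \code{area}, \code{protocol} and the generating \code{truth}.
#' @export
gen_force_displacement <- function(truth, protocol, noise_sd = 0, seed = 1L,
                                   sample_rate = 100) {
  stopifnot(inherits(truth, "synthetic_truth"),
            inherits(protocol, "loading_protocol"))
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  gl <- truth$geometry$gauge_length
  rec <- truth$recruitment
  vis <- truth$visco
  qs_force <- function(d) recruitment_force(gl + d, rec)

  # peak displacements (mm) for cyclic loading magnitudes: low exercises the
  # toe (approx. 35 % recruitment), high reaches the linear region
  peak_toe <- (rec$mu - gl) + stats::qnorm(0.35) * rec$sigma
  peak_lin <- (rec$mu - gl) + 3 * rec$sigma
  d_peak <- switch(protocol$cyclic_magnitude,
                   zero = 0, low = max(peak_toe, 0.2 * (rec$mu - gl)),
                   high = peak_lin)

  seg_t <- list(); seg_d <- list(); seg_f <- list(); seg_lab <- list()
  push <- function(t, d, f, lab) {
    i <- length(seg_t) + 1L
    seg_t[[i]] <<- t; seg_d[[i]] <<- d; seg_f[[i]] <<- f
    seg_lab[[i]] <<- rep(lab, length(t))
  }
  dt <- 1 / sample_rate
  t0 <- 0

  sine_cycles <- function(ncyc, f, peak, drift = 0) {
    tt <- seq(0, ncyc / f, by = dt)
    cyc <- pmin(floor(tt * f), ncyc - 1)
    amp <- peak + drift * cyc
    d <- amp / 2 * (1 - cos(2 * pi * f * tt))
    v <- amp / 2 * 2 * pi * f * sin(2 * pi * f * tt)
    list(t = tt, d = d, v = v)
  }

  if (protocol$precondition_cycles > 0) {
    s <- sine_cycles(protocol$precondition_cycles, protocol$frequency,
                     0.25 * max(d_peak, peak_toe))
    push(t0 + s$t, s$d, qs_force(s$d) + vis$damping * s$v, "precondition")
    t0 <- t0 + s$t[length(s$t)] + dt
  }
  if (protocol$cycle_count > 0 && protocol$cyclic_magnitude != "zero") {
    s <- sine_cycles(protocol$cycle_count, protocol$frequency, d_peak,
                     drift = vis$laxity_rate)
    push(t0 + s$t, s$d, qs_force(s$d) + vis$damping * s$v, "cyclic")
    t0 <- t0 + s$t[length(s$t)] + dt
  }
  # quasi-static ramp at ramp_rate %strain/s to target strain
  d_target <- protocol$target_strain / 100 * gl
  ramp_dur <- protocol$target_strain / protocol$ramp_rate
  tt <- seq(0, ramp_dur, by = dt)
  d <- d_target * tt / ramp_dur
  push(t0 + tt, d, qs_force(d), "ramp")
  t0 <- t0 + ramp_dur + dt
  # stress-relaxation hold at target strain
  if (protocol$relaxation_hold > 0) {
    tt <- seq(0, protocol$relaxation_hold, by = dt)
    Fpk <- qs_force(d_target)
    f <- Fpk * (vis$relax_frac + (1 - vis$relax_frac) * exp(-tt / vis$tau))
    push(t0 + tt, rep(d_target, length(tt)), f, "hold")
    t0 <- t0 + protocol$relaxation_hold + dt
  }
  # frequency sweep about the target strain with injected phase lag
  Feq <- qs_force(d_target) * vis$relax_frac
  d_amp <- protocol$sweep_amplitude / 100 * gl
  h <- 1e-6
  k_local <- (qs_force(d_target + h) - qs_force(d_target - h)) / (2 * h)
  for (fr in protocol$sweep_frequencies) {
    tt <- seq(0, protocol$sweep_cycles / fr, by = dt)
    d <- d_target + d_amp * sin(2 * pi * fr * tt)
    f <- Feq + k_local * d_amp * sin(2 * pi * fr * tt + vis$phase_lag)
    push(t0 + tt, d, f, sprintf("sweep_%g", fr))
    t0 <- t0 + protocol$sweep_cycles / fr + dt
  }
  if (protocol$recovery_hold > 0) {
    tt <- seq(0, protocol$recovery_hold, by = dt)
    push(t0 + tt, rep(0, length(tt)), rep(0, length(tt)), "recovery")
    t0 <- t0 + protocol$recovery_hold + dt
  }

  df <- data.frame(time = unlist(seg_t), displacement = unlist(seg_d),
                   force = unlist(seg_f),
                   segment = unlist(seg_lab), stringsAsFactors = FALSE)
  if (noise_sd > 0)
    df$force <- df$force + withr_seed(seed, stats::rnorm(nrow(df), 0, noise_sd))
  fd_record(df, gauge_length = gl, area = truth$geometry$area,
            protocol = protocol, truth = truth)
}

#' Force-displacement record container
#'
#' @param data data.frame with columns \code{time} (s), \code{displacement}
#'   (mm), \code{force} (N) and \code{segment} (labels).
#' @param gauge_length specimen gauge length, mm (> 0).
#' @param area cross-sectional area, mm^2 (> 0).
#' @param protocol optional [loading_protocol()].
#' @param truth optional generating [synthetic_truth()].
#' @return object of class \code{"fd_record"}.
#' @export
fd_record <- function(data, gauge_length, area, protocol = NULL,
                      truth = NULL) {
  stopifnot(all(c("time", "displacement", "force", "segment") %in%
                  names(data)))
  if (is.unsorted(data$time)) stop("time must be monotone non-decreasing")
  if (gauge_length <= 0 || area <= 0)
    stop("gauge_length and area must be > 0")
  structure(list(data = data, gauge_length = gauge_length, area = area,
                 protocol = protocol, truth = truth),
            class = "fd_record")
}

#' @export
print.fd_record <- function(x, ...) {
  segs <- rle(x$data$segment)$values
  cat(sprintf(
    "Force-displacement record: %d samples, %.4g s, gauge %.3g mm, area %.3g mm^2\n",
    nrow(x$data), max(x$data$time), x$gauge_length, x$area))
  cat("segments:", paste(segs, collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a force-displacement record as CSV
#'
#' The CSV carries the sample table; geometry travels in comment header
#' lines (\code{# gauge_length}, \code{# area}).
#'
#' @param record an [fd_record()].
#' @param path file path.
#' @return \code{read_fd_record} returns an [fd_record()].
#' @export
write_fd_record <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# gauge_length %.10g", record$gauge_length), con)
  writeLines(sprintf("# area %.10g", record$area), con)
  utils::write.csv(record$data, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fd_record
#' @export
read_fd_record <- function(path) {
  hdr <- readLines(path, n = 2)
  gl <- as.numeric(sub("# gauge_length ", "", hdr[1]))
  ar <- as.numeric(sub("# area ", "", hdr[2]))
  df <- utils::read.csv(path, comment.char = "#")
  fd_record(df, gauge_length = gl, area = ar)
}
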