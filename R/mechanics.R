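#' Per-cycle mechanics metrics from a cyclic loading segment
#'
#' Detects individual cycles in a labeled segment of a force-displacement
#' record and computes, per cycle: maximum/minimum displacement and strain,
#' tangent stiffness (slope between the force/displacement extrema), dynamic
#' modulus (slope between the stress/strain extrema), hysteresis (energy
#' dissipated per cycle, the area enclosed by the stress-strain loop), and
#' laxity (peak displacement relative to the first cycle, normalized by
#' gauge length; identically 0 for cycle 1).
#'
#' Cycles are segmented at upward zero crossings of the detrended
#' displacement (moving-average detrend over one nominal period). Stress is
#' force / cross-sectional area (MPa for N and mm^2); strain is
#' displacement / gauge length. Hysteresis is the closed loop integral of
#' stress over strain, positive for dissipative (clockwise) loops; negative
#' values are flagged in the \code{flagged} column.
#'
#' @param record an [fd_record()].
#' @param segment segment label to analyze (default \code{"cyclic"}).
#' @param frequency nominal cycle frequency, Hz; defaults to the protocol
#'   frequency carried by the record.
#' @return data.frame of class \code{"cyclic_mechanics"}, one row per cycle:
#'   \code{cycle}, \code{d_max}, \code{d_min}, \code{strain_max},
#'   \code{strain_min} (%), \code{tangent_stiffness} (N/mm),
#'   \code{dynamic_modulus} (MPa), \code{hysteresis} (MPa),
#'   \code{laxity}, \code{flagged}.
#' @export
cycle_metrics <- function(record, segment = "cyclic", frequency = NULL) {
  stopifnot(inherits(record, "fd_record"))
  df <- record$data[record$data$segment == segment, ]
  if (nrow(df) == 0) stop("record has no segment labeled '", segment, "'")
  if (is.null(frequency)) {
    if (is.null(record$protocol)) stop("no frequency given and no protocol")
    frequency <- record$protocol$frequency
  }
  dt <- stats::median(diff(df$time))
  per <- round(1 / frequency / dt)
  if (per < 8)
    stop("undersampled record: fewer than 2 samples per quarter cycle")
  if (diff(range(df$displacement)) <= 0)
    stop("degenerate cycle: zero displacement range")
  # detrend with a centered moving average over one period, then cut at
  # upward zero crossings
  kern <- rep(1 / per, per)
  trend <- as.numeric(stats::filter(df$displacement, kern, sides = 2))
  # extend the trend into the half-window edges the filter cannot reach
  first_ok <- which(!is.na(trend))[1]
  last_ok <- max(which(!is.na(trend)))
  trend[seq_len(first_ok - 1)] <- trend[first_ok]
  trend[seq(last_ok + 1, length.out = length(trend) - last_ok)] <-
    trend[last_ok]
  x <- df$displacement - trend
  up <- which(x[-length(x)] <= 0 & x[-1] > 0)
  if (length(up) < 2) {  # fall back to fixed-period cuts
    up <- seq(1, nrow(df) - per, by = per)
  }
  # keep the trailing partial window when it spans most of a period (it
  # still contains the final displacement peak)
  if (nrow(df) - up[length(up)] >= 0.75 * per) up <- c(up, nrow(df) + 1L)
  cuts <- Map(function(a, b) seq(a, b), up[-length(up)], up[-1] - 1L)
  area <- record$area; gl <- record$gauge_length
  rows <- lapply(seq_along(cuts), function(i) {
    idx <- cuts[[i]]
    d <- df$displacement[idx]; f <- df$force[idx]
    if (diff(range(d)) <= .Machine$double.eps)
      stop("degenerate cycle: zero displacement range in cycle ", i)
    eps <- d / gl; sig <- f / area
    # closed-loop integral of sigma d(eps) (trapezoid, loop closed)
    e2 <- c(eps, eps[1]); s2 <- c(sig, sig[1])
    hyst <- sum((s2[-1] + s2[-length(s2)]) / 2 * diff(e2))
    data.frame(cycle = i,
               d_max = max(d), d_min = min(d),
               strain_max = 100 * max(eps), strain_min = 100 * min(eps),
               tangent_stiffness = (max(f) - min(f)) / (max(d) - min(d)),
               dynamic_modulus = (max(sig) - min(sig)) / (max(eps) - min(eps)),
               hysteresis = hyst,
               peak = max(d))
  })
  out <- do.call(rbind, rows)
  out$laxity <- (out$peak - out$peak[1]) / gl
  out$flagged <- out$hysteresis < 0
  out$peak <- NULL
  class(out) <- c("cyclic_mechanics", "data.frame")
  out
}

#' Dynamic modulus and loss tangent from frequency-sweep segments
#'
#' For each sweep frequency, fits a sinusoid at the known frequency to both
#' stress and strain by linear least squares (cos/sin basis plus offset) and
#' reports the amplitude ratio \code{|E*| = sigma_amp / eps_amp} (MPa) and
#' \code{tan_delta = tan(phase lag)} with the lag wrapped to [0, pi/2).
#'
#' @param record an [fd_record()] with segments labeled
#'   \code{"sweep_<freq>"}.
#' @param frequencies frequencies to analyze; default: all sweep segments
#'   present.
#' @param min_cycles minimum number of cycles required per frequency.
#' @return data.frame: \code{frequency} (Hz), \code{Estar} (MPa),
#'   \code{tan_delta}, \code{phase_lag} (rad), \code{eps_amp},
#'   \code{sigma_amp}.
#' @export
frequency_sweep_metrics <- function(record, frequencies = NULL,
                                    min_cycles = 5) {
  stopifnot(inherits(record, "fd_record"))
  labs <- unique(record$data$segment)
  sw <- labs[startsWith(labs, "sweep_")]
  if (length(sw) == 0) stop("record has no sweep segments")
  fr_all <- as.numeric(sub("sweep_", "", sw))
  if (is.null(frequencies)) frequencies <- sort(fr_all)
  out <- lapply(frequencies, function(fr) {
    lab <- sw[which.min(abs(fr_all - fr))]
    df <- record$data[record$data$segment == lab, ]
    tt <- df$time - df$time[1]
    if (max(tt) * fr < min_cycles)
      stop(sprintf("sweep at %g Hz has fewer than %g cycles", fr, min_cycles))
    eps <- df$displacement / record$gauge_length
    sig <- df$force / record$area
    X <- cbind(1, cos(2 * pi * fr * tt), sin(2 * pi * fr * tt))
    ce <- stats::lm.fit(X, eps)$coefficients
    cs <- stats::lm.fit(X, sig)$coefficients
    amp_e <- sqrt(ce[2]^2 + ce[3]^2)
    amp_s <- sqrt(cs[2]^2 + cs[3]^2)
    if (amp_e < 1e-12)
      stop("sinusoid fit failed: no strain oscillation at ", fr, " Hz")
    # y = a cos + b sin = amp * sin(wt + phi), phi = atan2(a, b)
    lag <- atan2(cs[2], cs[3]) - atan2(ce[2], ce[3])
    lag <- lag %% pi
    if (lag >= pi / 2) lag <- lag - pi   # wrap into (-pi/2, pi/2)
    lag <- abs(lag)                       # report magnitude in [0, pi/2)
    data.frame(frequency = fr, Estar = amp_s / amp_e,
               tan_delta = tan(lag), phase_lag = lag,
               eps_amp = amp_e, sigma_amp = amp_s)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Equilibrium stress from a stress-relaxation hold
#'
#' Mean stress (force / cross-sectional area) over the final part of the
#' relaxation hold. The averaging window is the trailing fraction
#' \code{window} of the hold (default last 10 %).
#'
#' @param record an [fd_record()] containing a \code{"hold"} segment.
#' @param window trailing fraction of the hold to average over.
#' @param segment hold segment label.
#' @return equilibrium stress, MPa (scalar). The held strain (%) is attached
#'   as attribute \code{"strain"}.
#' @export
equilibrium_stress <- function(record, window = 0.1, segment = "hold") {
  stopifnot(inherits(record, "fd_record"))
  df <- record$data[record$data$segment == segment, ]
  if (nrow(df) == 0)
    stop("missing segment: record has no '", segment, "' hold")
  t0 <- df$time[1]; t1 <- df$time[nrow(df)]
  keep <- df$time >= t1 - window * (t1 - t0)
  s_eq <- mean(df$force[keep]) / record$area
  attr(s_eq, "strain") <- 100 * mean(df$displacement) / record$gauge_length
  s_eq
}

#' Change in equilibrium stress between two strain levels
#'
#' Strain-stiffening index: \code{s_eq(10 %) - s_eq(1 %)}. Both the absolute
#' change (MPa) and the percent change relative to the low-strain value are
#' returned, since the normalization convention is a reporting choice.
#'
#' @param record_low record held at the lower strain (1 %).
#' @param record_high record held at the higher strain (10 %).
#' @param window trailing window fraction passed to [equilibrium_stress()].
#' @return list: \code{delta} (MPa), \code{percent} (%), \code{s_eq_low},
#'   \code{s_eq_high}.
#' @export
delta_equilibrium_stress <- function(record_low, record_high, window = 0.1) {
  lo <- equilibrium_stress(record_low, window)
  hi <- equilibrium_stress(record_high, window)
  list(delta = as.numeric(hi - lo),
       percent = 100 * as.numeric(hi - lo) / abs(as.numeric(lo)),
       s_eq_low = as.numeric(lo), s_eq_high = as.numeric(hi))
}

#' Secant modulus of the quasi-static ramp
#'
#' Stress at the end of the ramp divided by the target strain.
#'
#' @param record an [fd_record()] with a \code{"ramp"} segment.
#' @return secant modulus, MPa.
#' @export
ramp_secant_modulus <- function(record) {
  df <- record$data[record$data$segment == "ramp", ]
  if (nrow(df) == 0) stop("record has no 'ramp' segment")
  n <- nrow(df)
  eps <- df$displacement[n] / record$gauge_length
  if (eps <= 0) stop("ramp reaches zero strain")
  (df$force[n] / record$area) / eps
}
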