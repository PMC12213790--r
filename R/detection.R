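#' Detection configuration
#'
#' Parameters of the mini-like event detector. The same configuration
#' must be applied to real and simulated traces: the fitting loop relies
#' on detection biases canceling between the two.
#'
#' @param amplitude_range Accepted amplitude range (mV); default
#'   `c(0.02, 10)`.
#' @param baseline_duration Duration of the pre-event window averaged to
#'   give the baseline (ms).
#' @param max_rise_gap Maximum rise-time gap searched backwards from each
#'   peak for the rise start (ms).
#' @param peak_smoothing Boxcar smoothing width applied before peak
#'   finding (ms); 0 disables smoothing.
#' @param refractory Minimum separation between accepted peaks (ms).
#' @return An object of class `detection_config`.
#' @export
detection_config <- function(amplitude_range = c(0.02, 10),
                             baseline_duration = 2,
                             max_rise_gap = 10,
                             peak_smoothing = 0.5,
                             refractory = 1) {
  stopifnot(length(amplitude_range) == 2L,
            amplitude_range[1L] > 0,
            amplitude_range[1L] < amplitude_range[2L],
            baseline_duration > 0, max_rise_gap > 0,
            peak_smoothing >= 0, refractory >= 0)
  structure(list(amplitude_range = amplitude_range,
                 baseline_duration = baseline_duration,
                 max_rise_gap = max_rise_gap,
                 peak_smoothing = peak_smoothing,
                 refractory = refractory),
            class = "detection_config")
}

## centered boxcar smoothing; edges fall back to the raw samples
smooth_boxcar <- function(x, w) {
  if (w <= 1L) return(x)
  s <- as.numeric(stats::filter(x, rep(1 / w, w), sides = 2L))
  na <- is.na(s)
  s[na] <- x[na]
  s
}

#' Detect mini-like events in a voltage trace
#'
#' Operational detector: smooth with a short boxcar, locate local maxima
#' (ties broken to the earliest sample), walk back at most `max_rise_gap`
#' to the minimum defining the rise start, take the baseline as the mean
#' over `baseline_duration` ending at that minimum, and keep events whose
#' amplitude falls inside `amplitude_range`. Events overlapping excluded
#' segments are dropped entirely. Windows never cross sweep boundaries.
#'
#' @param trace A [voltage_trace()].
#' @param config A [detection_config()].
#' @param measure_decay Measure the effective decay time constant of
#'   each event (default `TRUE`); the fitting loop disables it since
#'   decay does not enter the scored histograms.
#' @return Data frame of events sorted by peak time, with columns
#'   `peak_time_ms`, `peak_vm`, `baseline_vm`, `amplitude_mV`,
#'   `rise_10_90_ms`, `decay_tc_ms` (NA when the decay never reaches 1/e
#'   of its start value within the sweep, or when not measured).
#' @export
detect_events <- function(trace, config = detection_config(),
                          measure_decay = TRUE) {
  stopifnot(inherits(trace, "voltage_trace"),
            inherits(config, "detection_config"))
  dt <- trace$dt
  gap_n <- as.integer(round(config$max_rise_gap / dt))
  if (gap_n < 2L)
    stop("sampling interval dt = ", dt,
         " ms is too coarse to resolve max_rise_gap = ",
         config$max_rise_gap, " ms")
  base_n <- max(1L, as.integer(round(config$baseline_duration / dt)))
  refr_n <- as.integer(round(config$refractory / dt))
  w <- max(1L, as.integer(round(config$peak_smoothing / dt)))
  x <- trace$samples
  n <- length(x)
  s <- smooth_boxcar(x, w)
  cs <- cumsum(s)
  excl <- trace$excluded
  any_excl <- any(excl)
  cex <- if (any_excl) cumsum(excl) else NULL
  starts0 <- trace$sweeps
  ends0 <- sweep_ends(trace)
  ## local maxima: strictly above previous, at or above next sample
  cand <- which(c(FALSE, s[-1L] > s[-n]) & c(s[-n] >= s[-1L], TRUE))
  out <- vector("list", length(cand))
  m <- 0L
  last_peak <- -Inf
  n8 <- as.integer(round(8 / dt))
  amin <- config$amplitude_range[1L]
  amax <- config$amplitude_range[2L]
  for (ip in cand) {
    if ((ip - last_peak) * dt < config$refractory && refr_n > 0L) next
    sweep <- findInterval(ip - 1L, starts0)            # ip is 1-based
    s_lo <- starts0[sweep] + 1L                        # first sample of sweep
    s_hi <- ends0[sweep]
    lo <- max(ip - gap_n, s_lo)
    ## rise start: walk back down the rising phase to the nearest
    ## preceding local minimum (at most max_rise_gap before the peak);
    ## keeps baselines local so events riding on the decay of a larger
    ## event are measured against their own foot, not the decay's floor
    ir <- ip
    while (ir > lo && s[ir - 1L] <= s[ir]) ir <- ir - 1L
    b_lo <- max(ir - base_n + 1L, s_lo)
    baseline <- (cs[ir] - if (b_lo > 1L) cs[b_lo - 1L] else 0) /
      (ir - b_lo + 1L)
    amp <- s[ip] - baseline
    if (amp < amin || amp > amax) next
    if (any_excl) {
      nex <- cex[ip] - if (ir > 1L) cex[ir - 1L] else 0L
      if (nex > 0L) next
    }
    ## 10-90% rise time with linear interpolation, within [ir, ip]
    rt <- rise_time_10_90_core(s, ir, ip, baseline, dt)
    if (is.na(rt)) next                                # clipped rise
    dtc <- if (measure_decay)
      decay_tc_core(s, ip, baseline, s_hi, n8, dt) else NA_real_
    m <- m + 1L
    out[[m]] <- c((ip - 1L) * dt, s[ip], baseline, amp, rt, dtc)
    last_peak <- ip
  }
  if (m == 0L) {
    return(data.frame(peak_time_ms = numeric(0), peak_vm = numeric(0),
                      baseline_vm = numeric(0), amplitude_mV = numeric(0),
                      rise_10_90_ms = numeric(0), decay_tc_ms = numeric(0)))
  }
  res <- do.call(rbind, out[seq_len(m)])
  res <- data.frame(peak_time_ms = res[, 1L], peak_vm = res[, 2L],
                    baseline_vm = res[, 3L], amplitude_mV = res[, 4L],
                    rise_10_90_ms = res[, 5L], decay_tc_ms = res[, 6L])
  res[order(res$peak_time_ms), , drop = FALSE]
}

## rise time between last upward 10% crossing before the peak and first
## 90% crossing, relative to baseline; NA if a threshold is never crossed
rise_time_10_90_core <- function(s, ir, ip, baseline, dt) {
  amp <- s[ip] - baseline
  thr10 <- baseline + 0.1 * amp
  thr90 <- baseline + 0.9 * amp
  seg <- s[ir:ip]
  k <- length(seg)
  below10 <- which(seg < thr10)
  if (length(below10) == 0L) {
    t10 <- 0
  } else {
    i <- max(below10)
    if (i >= k) return(NA_real_)
    t10 <- (i - 1 + (thr10 - seg[i]) / (seg[i + 1L] - seg[i])) * dt
  }
  above90 <- which(seg >= thr90)
  above90 <- above90[above90 > 1L]
  if (length(above90) == 0L) return(NA_real_)
  j <- min(above90)
  t90 <- (j - 2 + (thr90 - seg[j - 1L]) / (seg[j] - seg[j - 1L])) * dt
  max(t90 - t10, 0)
}

## effective decay time constant: start value read n8 samples after the
## peak; time for v - baseline to fall to 1/e of it (NA if never reached
## within the sweep)
decay_tc_core <- function(s, ip, baseline, s_hi, n8, dt) {
  i0 <- ip + n8
  if (i0 > s_hi) return(NA_real_)
  v0 <- s[i0] - baseline
  if (v0 <= 0) return(NA_real_)
  thr <- baseline + v0 / exp(1)
  seg <- s[i0:s_hi]
  idx <- which(seg <= thr)
  if (length(idx) == 0L) return(NA_real_)
  (min(idx) - 1L) * dt
}

#' 10-90% rise time of one event
#'
#' Time between the last upward crossing of baseline + 10% of the
#' amplitude before the peak and the first crossing of baseline + 90%,
#' with linear interpolation between samples.
#'
#' @param trace A [voltage_trace()].
#' @param peak_index 1-based sample index of the event peak.
#' @param baseline Baseline potential (mV), strictly below the peak value.
#' @param search_back How far before the peak to search for the 10%
#'   crossing (ms).
#' @return Rise time (ms); `NA` if a threshold is never crossed (clipped
#'   rise; such events are rejected by [detect_events()]).
#' @export
rise_time_10_90 <- function(trace, peak_index, baseline, search_back = 10) {
  stopifnot(inherits(trace, "voltage_trace"))
  if (baseline >= trace$samples[peak_index])
    stop("`baseline` must be below the peak value")
  ir <- max(1L, peak_index - as.integer(round(search_back / trace$dt)))
  rise_time_10_90_core(trace$samples, ir, peak_index, baseline, trace$dt)
}

#' Effective decay time constant of one event
#'
#' The starting value is read 8 ms after the peak (safely past the peak
#' and the upwardly convex part); the returned value is the time taken
#' for the potential (relative to baseline) to fall to 1/e of it.
#'
#' @param trace A [voltage_trace()].
#' @param peak_index 1-based sample index of the event peak.
#' @param baseline Baseline potential (mV).
#' @param start_delay Delay after the peak at which the start value is
#'   read (ms); default 8.
#' @return Decay time constant (ms); `NA` if the trace never falls to 1/e
#'   of the start value within the sweep (missing-value contract).
#' @export
effective_decay_tc <- function(trace, peak_index, baseline,
                               start_delay = 8) {
  stopifnot(inherits(trace, "voltage_trace"))
  sweep <- findInterval(peak_index - 1L, trace$sweeps)
  s_hi <- sweep_ends(trace)[sweep]
  decay_tc_core(trace$samples, peak_index, baseline, s_hi,
                as.integer(round(start_delay / trace$dt)), trace$dt)
}
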