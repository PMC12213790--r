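#' Waveform parameters for simulated miniature EPSPs
#'
#' Parameters of the analytical passive-cable response to a double
#' exponential synaptic current. The geometry is a uniform finite cable of
#' electrotonic length `L`, sealed at both ends, with the recording site
#' at the origin and the synaptic input at electrotonic distance
#' `electrotonic_distance`. The somatic response is the truncated series
#' of `n_terms` exponential equalization modes,
#' `tau_k = tau_m / (1 + (k*pi/L)^2)`, convolved with the synaptic
#' current `I(t) = A * (exp(-t/tau2) - exp(-t/tau1))` whose total charge
#' is `charge_scale`.
#'
#' @param tau1 Synaptic current rise time constant (ms); the fitted range
#'   is 0.15-3 ms.
#' @param tau2 Synaptic current decay time constant (ms); fixed at 2 ms.
#' @param tau_m Passive membrane time constant (ms).
#' @param n_terms Number of lumped series terms (default 100).
#' @param electrotonic_distance Dimensionless input location `X` in
#'   `[0, L]`.
#' @param charge_scale Injected charge (fC).
#' @param c_total Total membrane capacitance (pF); with `charge_scale` it
#'   sets the absolute voltage scale (fC / pF = mV).
#' @param L Electrotonic length of the cable (default 1).
#' @return An object of class `waveform_params`.
#' @export
waveform_params <- function(tau1 = 0.5, tau2 = 2, tau_m = 20,
                            n_terms = 100, electrotonic_distance = 0.5,
                            charge_scale = 50, c_total = 200, L = 1) {
  stopifnot(tau1 > 0, tau2 > 0, tau_m > 0, n_terms >= 1,
            electrotonic_distance >= 0, electrotonic_distance <= L,
            c_total > 0, L > 0)
  structure(list(tau1 = tau1, tau2 = tau2, tau_m = tau_m,
                 n_terms = as.integer(n_terms),
                 electrotonic_distance = electrotonic_distance,
                 charge_scale = charge_scale, c_total = c_total, L = L),
            class = "waveform_params")
}

#' Simulate a somatic smEPSP waveform
#'
#' Evaluates the passive-cable series solution at the soma for a double
#' exponential synaptic current injected at the configured electrotonic
#' distance.
#'
#' @param params A [waveform_params()].
#' @param dt Sampling interval (ms); must resolve `tau1`
#'   (`dt <= tau1 / 3`).
#' @param duration Waveform duration (ms).
#' @return Numeric vector of mV samples starting at the current onset
#'   (`t = 0`).
#' @export
simulate_psp <- function(params, dt, duration) {
  stopifnot(inherits(params, "waveform_params"), dt > 0, duration > dt)
  if (dt > params$tau1 / 3)
    stop("dt = ", dt, " ms does not resolve tau1 = ", params$tau1,
         " ms (need dt <= tau1/3); the mode series is unreliable at this ",
         "sampling interval")
  if (params$charge_scale == 0) return(numeric(floor(duration / dt)))
  t <- (seq_len(floor(duration / dt)) - 1) * dt
  with(params, {
    k <- 0:(n_terms - 1L)
    tau_k <- tau_m / (1 + (k * pi / L)^2)
    b_k <- ifelse(k == 0, 1, 2 * cos(k * pi * electrotonic_distance / L))
    ## guard exact equality of synaptic and mode time constants
    t1 <- tau1; t2 <- tau2
    if (abs(t1 - t2) < 1e-9) t2 <- t2 * (1 + 1e-9)
    eq <- abs(tau_k - t1) < 1e-12 * t1
    tau_k[eq] <- tau_k[eq] * (1 + 1e-9)
    eq <- abs(tau_k - t2) < 1e-12 * t2
    tau_k[eq] <- tau_k[eq] * (1 + 1e-9)
    A <- charge_scale / (t2 - t1)          # pA, so that total charge = Q
    g2 <- t2 * tau_k / (tau_k - t2)        # conv weights, ms
    g1 <- t1 * tau_k / (tau_k - t1)
    alpha <- b_k * (g2 - g1)
    ## V(t) = (A / C) * [ sum_k alpha_k e^{-t/tau_k}
    ##                    - (sum b g2) e^{-t/tau2} + (sum b g1) e^{-t/tau1} ]
    E <- exp(outer(t, -1 / tau_k))
    v <- as.vector(E %*% alpha) -
      sum(b_k * g2) * exp(-t / t2) + sum(b_k * g1) * exp(-t / t1)
    v * A / c_total
  })
}

#' Measure peak amplitude and 10-90% rise time of a clean waveform
#'
#' Threshold crossings are located by linear interpolation between
#' samples; the baseline is 0 (the waveform is assumed noiseless and
#' baseline-subtracted).
#'
#' @param v Waveform samples (mV), starting at onset.
#' @param dt Sampling interval (ms).
#' @return List with `peak` (mV), `peak_time` (ms) and `rise_10_90` (ms).
#' @export
measure_waveform <- function(v, dt) {
  ip <- which.max(v)
  peak <- v[ip]
  if (peak <= 0) return(list(peak = peak, peak_time = (ip - 1) * dt,
                             rise_10_90 = NA_real_))
  t10 <- interp_crossing_up(v, 0.1 * peak, ip, dt)
  t90 <- interp_crossing_up(v, 0.9 * peak, ip, dt)
  list(peak = peak, peak_time = (ip - 1) * dt, rise_10_90 = t90 - t10)
}

## time (ms) of last upward crossing of `thr` at or before sample ip
interp_crossing_up <- function(v, thr, ip, dt) {
  below <- which(v[seq_len(ip)] < thr)
  if (length(below) == 0L) return(0)
  i <- max(below)                          # v[i] < thr <= v[i+1]
  if (i >= ip) return((ip - 1) * dt)
  frac <- (thr - v[i]) / (v[i + 1L] - v[i])
  ((i - 1) + frac) * dt
}

#' Calibrate waveform shape to a target amplitude and rise time
#'
#' Finds the electrotonic input distance whose unit-charge waveform has
#' the requested 10-90% rise time (a monotone root-find in `X`), then
#' scales the injected charge linearly so the noiseless somatic peak
#' equals the requested amplitude.
#'
#' @param amplitude Target somatic peak (mV).
#' @param rise_time Target 10-90% rise time (ms).
#' @param tau1 Synaptic rise time constant (ms).
#' @param tau_m Passive membrane time constant (ms).
#' @param c_total Total membrane capacitance (pF).
#' @param dt Sampling interval used for the calibration (ms).
#' @param L Electrotonic cable length.
#' @param n_terms Series terms.
#' @param tau2 Synaptic decay time constant (ms).
#' @return A [waveform_params()] whose simulated waveform reproduces the
#'   requested shape (amplitude within 1%, rise time within
#'   `max(2%, dt)`).
#' @export
calibrate_shape <- function(amplitude, rise_time, tau1 = 0.5, tau_m = 20,
                            c_total = 200, dt = 0.05, L = 1,
                            n_terms = 100, tau2 = 2) {
  stopifnot(amplitude > 0, rise_time > 0)
  duration <- max(6 * tau_m, 40)
  rise_at <- function(X) {
    p <- waveform_params(tau1 = tau1, tau2 = tau2, tau_m = tau_m,
                         n_terms = n_terms, electrotonic_distance = X,
                         charge_scale = 100, c_total = c_total, L = L)
    measure_waveform(simulate_psp(p, dt, duration), dt)$rise_10_90
  }
  X_hi <- L * (1 - 1e-6)
  r_lo <- rise_at(0)
  r_hi <- rise_at(X_hi)
  if (rise_time < r_lo || rise_time > r_hi)
    stop(sprintf(
      "rise time %.3g ms is unreachable for tau1 = %.3g, tau_m = %.3g: achievable range is [%.3g, %.3g] ms",
      rise_time, tau1, tau_m, r_lo, r_hi))
  X <- if (rise_time == r_lo) 0
  else if (rise_time == r_hi) X_hi
  else stats::uniroot(function(X) rise_at(X) - rise_time, c(0, X_hi),
                      tol = 1e-6)$root
  p <- waveform_params(tau1 = tau1, tau2 = tau2, tau_m = tau_m,
                       n_terms = n_terms, electrotonic_distance = X,
                       charge_scale = 100, c_total = c_total, L = L)
  pk <- measure_waveform(simulate_psp(p, dt, duration), dt)$peak
  p$charge_scale <- 100 * amplitude / pk
  p
}

#' Superimpose simulated events on a noise trace
#'
#' Adds event waveforms linearly onto the samples of a noise trace.
#' Events straddling a sweep end are truncated at the sweep boundary; the
#' input trace is not modified.
#'
#' @param noise A [voltage_trace()].
#' @param events Data frame with columns `onset_ms`, `amplitude` (mV) and
#'   `waveform_id` (index into `waveforms`).
#' @param waveforms List of unit-peak waveform sample vectors at the
#'   trace's `dt` (e.g. built with [simulate_psp()] and normalized).
#' @return A new `voltage_trace` with the events added.
#' @export
superimpose <- function(noise, events, waveforms) {
  stopifnot(inherits(noise, "voltage_trace"))
  out <- noise
  if (NROW(events) == 0L) return(out)
  stopifnot(all(c("onset_ms", "amplitude", "waveform_id") %in%
                  names(events)))
  x <- out$samples
  dt <- out$dt
  n <- length(x)
  ends0 <- sweep_ends(noise)               # 0-based half-open sweep ends
  starts0 <- noise$sweeps
  for (i in seq_len(NROW(events))) {
    if (events$onset_ms[i] < 0 || events$onset_ms[i] > n * dt)
      stop("event onset outside trace")
    i0 <- min(as.integer(round(events$onset_ms[i] / dt)), n - 1L)
    w <- waveforms[[events$waveform_id[i]]] * events$amplitude[i]
    sweep <- findInterval(i0, starts0)
    hi <- min(i0 + length(w), ends0[sweep], n)         # truncate at sweep end
    len <- hi - i0
    if (len <= 0L) next
    idx <- (i0 + 1L):hi
    x[idx] <- x[idx] + w[seq_len(len)]
  }
  out$samples <- x
  out
}
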