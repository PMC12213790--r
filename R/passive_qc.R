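#' Passive membrane time constant from a pulse decay
#'
#' Fits a straight line to the natural logarithm of the
#' baseline-subtracted decay that follows a brief current pulse, after
#' skipping the initial rapid drop due to membrane charge redistribution.
#' The stabilization point is the first time the curvature of `ln(V)`
#' stays below a tolerance for 1 ms. Also returns the effective time
#' constant variant: the time taken to fall to 1/e of the value read
#' `effective_start` (default 4) ms after the pulse end.
#'
#' @param decay Numeric vector: baseline-subtracted decay samples (mV)
#'   starting at the pulse end, of one sign (use the absolute response).
#' @param dt Sampling interval (ms).
#' @param curvature_tol Stabilization tolerance on the second derivative
#'   of `ln(V)` (1/ms^2 per ms, default 0.01).
#' @param effective_start Start delay of the effective-time-constant
#'   read-out (ms).
#' @return List with `tau_m` (ms, slope fit), `tau_eff` (ms, 1/e
#'   variant), `v_inj` (mV, the back-extrapolated intercept of the slow
#'   component), `stabilization_ms`.
#' @export
estimate_tau_m <- function(decay, dt, curvature_tol = 0.01,
                           effective_start = 4) {
  decay <- as.numeric(decay)
  if (any(decay <= 0))
    stop("decay segment must be strictly positive inside the fit window ",
         "(baseline-subtract and rectify the response first)")
  lv <- log(decay)
  n <- length(lv)
  if (n * dt < 5) stop("decay segment too short to fit")
  ## curvature of ln(V) measured over 1 ms steps: coarse differencing
  ## keeps the second derivative estimate usable on noisy recordings
  k <- max(1L, as.integer(round(1 / dt)))
  if (n < 3L * k + 2L) stop("decay segment too short to fit")
  i_mid <- (k + 1L):(n - k)
  d2 <- abs(lv[i_mid + k] - 2 * lv[i_mid] + lv[i_mid - k]) / (k * dt)^2
  run <- k
  ok <- d2 <= curvature_tol
  ## first index where curvature stays below tolerance for 1 ms
  stab <- NA_integer_
  if (length(ok) >= run) {
    cons <- stats::filter(as.numeric(ok), rep(1, run), sides = 1L)
    hit <- which(cons == run)
    if (length(hit) > 0L) stab <- hit[1L] - run + 1L + k  # index into lv
  }
  if (is.na(stab))
    stop("stabilization point not found: ln(V) curvature never settles ",
         "below ", curvature_tol, " for 1 ms (min observed ",
         signif(min(d2), 3), ")")
  idx <- stab:n
  t <- (idx - 1) * dt
  fit <- stats::lm.fit(cbind(1, t), lv[idx])
  slope <- fit$coefficients[2L]
  if (slope >= 0) stop("decay slope is non-negative; not a decay")
  tau_m <- -1 / slope
  v_inj <- exp(fit$coefficients[1L])
  i4 <- as.integer(round(effective_start / dt)) + 1L
  tau_eff <- NA_real_
  if (i4 <= n) {
    v0 <- decay[i4]
    below <- which(decay[i4:n] <= v0 / exp(1))
    if (length(below) > 0L) tau_eff <- (min(below) - 1L) * dt
  }
  list(tau_m = unname(tau_m), tau_eff = tau_eff, v_inj = unname(v_inj),
       stabilization_ms = (stab - 1) * dt)
}

#' Total membrane capacitance from a brief pulse response
#'
#' The zeroth impulse-response component is
#' `A0 = V_inj / (I_inj * tau_m * (1 - exp(-t_pulse / tau_m)))` and the
#' total membrane capacitance is its inverse. With `V_inj` in mV,
#' `I_inj` in pA and times in ms, `A0` is in 1/pF and `C_total` in pF.
#' Estimates from depolarising and hyperpolarising pulses should be
#' computed separately (with positive magnitudes) and averaged.
#'
#' @param v_inj Response amplitude to the total injected current (mV),
#'   positive.
#' @param i_inj Total injected current (pA), positive magnitude.
#' @param tau_m Passive membrane time constant (ms).
#' @param t_pulse Pulse duration (ms).
#' @return List with `A0` (1/pF) and `C_total` (pF).
#' @export
estimate_capacitance <- function(v_inj, i_inj, tau_m, t_pulse) {
  stopifnot(v_inj > 0, i_inj > 0, tau_m > 0, t_pulse > 0)
  g <- 1 - exp(-t_pulse / tau_m)
  if (g == 0)
    stop("t_pulse/tau_m so small that (1 - exp(-x)) underflows")
  a0 <- v_inj / (i_inj * tau_m * g)
  list(A0 = a0, C_total = 1 / a0)
}

#' Bridge balance (series resistance) error from charging-curve jumps
#'
#' The instantaneous membrane-potential discontinuity at a pulse edge,
#' divided by the current step, gives the uncompensated series
#' resistance. The jump is measured by back-extrapolating a single
#' exponential fitted over a short post-edge window (default 0.2-2 ms,
#' robust to the pipette-capacitance artifact) to the edge time, and
#' averaging over the supplied edges.
#'
#' @param trace A [voltage_trace()].
#' @param edges Data frame with columns `index` (1-based sample index of
#'   the edge), `delta_i` (current step at the edge, pA; signed).
#' @param fit_window Post-edge fit window (ms), default `c(0.2, 2)`.
#' @return Bridge balance error (MOhm), averaged over usable edges;
#'   edges contaminated by excluded segments are skipped with a warning.
#' @export
estimate_bridge_error <- function(trace, edges, fit_window = c(0.2, 2)) {
  stopifnot(inherits(trace, "voltage_trace"))
  dt <- trace$dt
  i_lo <- as.integer(round(fit_window[1L] / dt))
  i_hi <- as.integer(round(fit_window[2L] / dt))
  vals <- numeric(0)
  for (r in seq_len(NROW(edges))) {
    i0 <- edges$index[r]
    idx <- (i0 + i_lo):(i0 + i_hi)
    if (max(idx) > length(trace$samples) || min(idx) < 1L) next
    if (any(trace$excluded[idx])) {
      warning("pulse edge at sample ", i0,
              " overlaps excluded segments; skipped")
      next
    }
    pre <- trace$samples[max(i0 - i_lo, 1L):(i0 - 1L)]
    v_pre <- mean(pre)
    y <- trace$samples[idx] - v_pre
    sgn <- sign(edges$delta_i[r])
    ya <- y * sgn
    if (any(ya <= 0)) {
      jump <- y[1L]                        # fall back to first sample
    } else {
      t <- (idx - i0) * dt
      fit <- stats::lm.fit(cbind(1, t), log(ya))
      jump <- sgn * exp(fit$coefficients[1L])
    }
    vals <- c(vals, 1000 * jump / edges$delta_i[r])   # mV/pA -> GOhm*1e3 = MOhm
  }
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

#' Longitudinal recording-quality indicators
#'
#' Computes the seven series used to select good recording segments:
#' per-sweep baseline membrane potential, potential SD over consecutive
#' 15 ms windows, per-sweep mean and median of the largest 10% of
#' detected event amplitudes, per-segment effective decay time constant
#' of those events, per-segment passive time constant and capacitance
#' (when pulse estimates are supplied), and per-segment bridge-error
#' change. A flag is raised when the bridge error exceeds the initial
#' estimate by more than two-fold, and on SD excursions beyond
#' `sd_flag_factor` times the median window SD.
#'
#' @param trace A [voltage_trace()].
#' @param events Detection results from [detect_events()] on the trace.
#' @param sd_window SD window (ms), default 15.
#' @param segment Segment length for the slower series (ms), default
#'   20000.
#' @param passive Optional data frame with per-segment `tau_m` and
#'   `c_total` estimates (from pulse analysis).
#' @param bridge Optional numeric vector of per-segment bridge errors
#'   (MOhm).
#' @param sd_flag_factor SD excursion flag threshold, default 5.
#' @return List of class `qc_series` with the seven series and `flags`.
#' @export
compute_qc <- function(trace, events, sd_window = 15, segment = 20000,
                       passive = NULL, bridge = NULL, sd_flag_factor = 5) {
  stopifnot(inherits(trace, "voltage_trace"))
  x <- trace$samples
  dt <- trace$dt
  n <- length(x)
  ## per-sweep baseline
  st <- trace$sweeps
  en <- sweep_ends(trace)
  baseline_vm <- vapply(seq_along(st), function(i) {
    idx <- (st[i] + 1L):en[i]
    idx <- idx[!trace$excluded[idx]]
    if (length(idx) == 0L) NA_real_ else mean(x[idx])
  }, 0)
  ## SD over consecutive windows
  wn <- max(2L, as.integer(round(sd_window / dt)))
  nw <- n %/% wn
  vm_sd <- vapply(seq_len(nw), function(i) {
    idx <- ((i - 1L) * wn + 1L):(i * wn)
    if (any(trace$excluded[idx])) NA_real_ else stats::sd(x[idx])
  }, 0)
  ## top-10% amplitudes per sweep
  sweep_of <- findInterval(events$peak_time_ms, st * dt)
  top10_mean <- top10_median <- rep(NA_real_, length(st))
  for (i in seq_along(st)) {
    a <- events$amplitude_mV[sweep_of == i]
    if (length(a) > 0L) {
      top <- a[a >= stats::quantile(a, 0.9, names = FALSE)]
      top10_mean[i] <- mean(top)
      top10_median[i] <- stats::median(top)
    }
  }
  ## per-segment decay tc of top-10% events
  seg_n <- max(1L, as.integer(round(segment / dt)))
  nseg <- max(1L, n %/% seg_n)
  seg_of <- pmin(floor(events$peak_time_ms / (seg_n * dt)) + 1L, nseg)
  top10_decay <- rep(NA_real_, nseg)
  for (i in seq_len(nseg)) {
    ev <- events[seg_of == i, , drop = FALSE]
    if (nrow(ev) > 0L) {
      top <- ev[ev$amplitude_mV >=
                  stats::quantile(ev$amplitude_mV, 0.9, names = FALSE), ]
      top10_decay[i] <- mean(top$decay_tc_ms, na.rm = TRUE)
    }
  }
  flags <- list()
  med_sd <- stats::median(vm_sd, na.rm = TRUE)
  sd_exc <- which(!is.na(vm_sd) & vm_sd > sd_flag_factor * med_sd)
  if (length(sd_exc) > 0L)
    flags$sd_excursions <- sd_exc
  if (!is.null(bridge) && length(bridge) > 1L) {
    b0 <- abs(bridge[1L])
    bad <- which(abs(bridge) > 2 * b0)
    if (length(bad) > 0L) flags$bridge_two_fold <- bad
  }
  structure(list(
    baseline_vm = baseline_vm,
    vm_sd = vm_sd, sd_window_ms = sd_window,
    top10_amp_mean = top10_mean, top10_amp_median = top10_median,
    top10_decay_tc = top10_decay,
    tau_m_series = if (!is.null(passive)) passive$tau_m,
    capacitance_series = if (!is.null(passive)) passive$c_total,
    bridge_series = bridge, segment_ms = segment,
    flags = flags), class = "qc_series")
}
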