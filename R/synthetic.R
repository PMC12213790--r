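#' Background-noise model
#'
#' Stationary colored noise standing in for the physiological background
#' of a somatic voltage recording. The default is an Ornstein-Uhlenbeck
#' process with a 5 ms correlation time and a 0.012 mV stationary SD
#' around a -70 mV baseline, the scale at which an 80 uV detection
#' threshold is "unreasonably high" for noise-alone fluctuations.
#'
#' @param kind `"ou"` or `"filtered_gaussian"`.
#' @param sd Stationary noise SD (mV).
#' @param correlation_time Autocorrelation time (ms).
#' @param baseline Resting potential (mV).
#' @param glitch_rate Rate of brief large glitches (events/s; 0
#'   disables).
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(kind = c("ou", "filtered_gaussian"), sd = 0.012,
                        correlation_time = 5, baseline = -70,
                        glitch_rate = 0) {
  kind <- match.arg(kind)
  stopifnot(sd >= 0, correlation_time > 0)
  structure(list(kind = kind, sd = sd,
                 correlation_time = correlation_time,
                 baseline = baseline, glitch_rate = glitch_rate),
            class = "noise_model")
}

#' Generate a noise-alone voltage trace
#'
#' @param model A [noise_model()].
#' @param duration Trace duration (ms).
#' @param dt Sampling interval (ms).
#' @param seed Integer seed; identical seeds give identical traces.
#' @param sweep_length Sweep duration (ms); `NULL` for a single sweep.
#' @param epoch Epoch label for the returned trace.
#' @return A [voltage_trace()].
#' @export
generate_noise <- function(model, duration, dt = 0.1, seed = 1L,
                           sweep_length = NULL, epoch = "noise_alone") {
  stopifnot(inherits(model, "noise_model"), duration > 0, dt > 0)
  set.seed(seed)
  n <- as.integer(round(duration / dt))
  phi <- exp(-dt / model$correlation_time)
  if (model$sd > 0) {
    eps <- stats::rnorm(n)
    if (model$kind == "ou") {
      innov <- model$sd * sqrt(1 - phi^2)
      x <- as.numeric(stats::filter(eps * innov, phi, method = "recursive"))
      ## start from the stationary distribution
      x0 <- stats::rnorm(1L, 0, model$sd)
      x <- x + x0 * phi^(seq_len(n))
    } else {
      ## white noise passed through the same single-pole filter, scaled
      ## back to the requested SD
      x <- as.numeric(stats::filter(eps, phi, method = "recursive"))
      x <- x * model$sd / stats::sd(x)
    }
  } else {
    x <- numeric(n)
  }
  if (model$glitch_rate > 0) {
    n_gl <- stats::rpois(1L, model$glitch_rate * duration / 1000)
    if (n_gl > 0L) {
      at <- sample.int(n, n_gl)
      wgl <- as.integer(round(1 / dt))
      for (g in at) {
        idx <- g:min(g + wgl, n)
        x[idx] <- x[idx] + sample(c(-1, 1), 1L) * stats::runif(1L, 4, 8) *
          max(model$sd, 0.01)
      }
    }
  }
  sweeps <- 0L
  if (!is.null(sweep_length)) {
    per <- as.integer(round(sweep_length / dt))
    sweeps <- as.integer(seq(0L, n - 1L, by = per))
  }
  voltage_trace(model$baseline + x, dt, sweeps = sweeps, epoch = epoch)
}

#' Specification of a synthetic cell
#'
#' Embodies the capacitor law: when built from a fixed per-event charge,
#' the cell's true mean somatic mini amplitude is
#' `true_charge / c_total`. Amplitudes are log-normal with coefficient
#' of variation `amp_cv`; rise times are log-normal with log-SD
#' `rise_sdlog`, whose skew satisfies the quarter-SD mean-median
#' constraint seen in real minis.
#'
#' @param c_total Total membrane capacitance (pF).
#' @param tau_m Passive membrane time constant (ms).
#' @param r_in Input resistance (MOhm); defaults to `tau_m`-consistent
#'   value `tau_m / c_total * 1000`.
#' @param true_charge Mean charge per mini (fC); with `c_total` it sets
#'   the mean amplitude. Give either this or `mean_amp`.
#' @param mean_amp True mean somatic amplitude (mV).
#' @param true_rate Minis incidence rate (minis/s).
#' @param amp_cv Amplitude coefficient of variation.
#' @param rise_mean Mean 10-90% rise time (ms).
#' @param rise_sdlog Log-SD of the rise-time distribution.
#' @param tau1 Synaptic rise time constant used for waveforms (ms).
#' @param layer Cortical layer label.
#' @return Object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(c_total = 200, tau_m = 20, r_in = NULL,
                                true_charge = NULL, mean_amp = NULL,
                                true_rate = 25, amp_cv = 0.35,
                                rise_mean = 2, rise_sdlog = 0.7,
                                tau1 = 0.75, layer = "L2/3") {
  if (is.null(mean_amp)) {
    if (is.null(true_charge))
      stop("give either `true_charge` or `mean_amp`")
    mean_amp <- true_charge / c_total
  } else if (is.null(true_charge)) {
    true_charge <- mean_amp * c_total
  }
  if (is.null(r_in)) r_in <- tau_m / c_total * 1000
  stopifnot(c_total > 0, tau_m > 0, mean_amp > 0, true_rate >= 0)
  structure(list(c_total = c_total, tau_m = tau_m, r_in = r_in,
                 true_charge = true_charge, mean_amp = mean_amp,
                 true_rate = true_rate, amp_cv = amp_cv,
                 rise_mean = rise_mean, rise_sdlog = rise_sdlog,
                 tau1 = tau1, layer = layer),
            class = "synthetic_cell_spec")
}

## draw true (amplitude, rise time) pairs for a cell
sample_true_minis <- function(cell, n) {
  sdlog_a <- sqrt(log(1 + cell$amp_cv^2))
  mulog_a <- log(cell$mean_amp) - sdlog_a^2 / 2
  mulog_r <- log(cell$rise_mean) - cell$rise_sdlog^2 / 2
  data.frame(amplitude = stats::rlnorm(n, mulog_a, sdlog_a),
             rise_time = stats::rlnorm(n, mulog_r, cell$rise_sdlog))
}

#' Generate a paired noise-with-minis / noise-alone recording
#'
#' Both epochs are independent realizations of the same noise model; the
#' minis epoch additionally carries simulated events drawn from the
#' cell's true source distribution at its true rate. Pulse-response
#' records embedding the cell's capacitance and time constant are
#' generated for passive-property estimation, and the ground-truth event
#' table is returned.
#'
#' @param cell A [synthetic_cell_spec()].
#' @param noise A [noise_model()].
#' @param durations Named vector `c(minis = ..., noise = ...)` (ms).
#' @param dt Sampling interval (ms).
#' @param seed Integer seed.
#' @param sweep_length Sweep duration (ms).
#' @param pulse_noise_sd SD of the residual noise on the averaged pulse
#'   response (mV); small because the response is an across-sweep
#'   average.
#' @return List with `minis` and `noise` traces, `pulses` (averaged
#'   pulse-response trace), `protocol`, `truth` (event table with
#'   `onset_ms`, `amplitude`, `rise_time`, `peak_time_ms`), and `cell`.
#' @export
generate_recording_pair <- function(cell, noise = noise_model(),
                                    durations = c(minis = 60000,
                                                  noise = 60000),
                                    dt = 0.1, seed = 1L,
                                    sweep_length = 3000,
                                    pulse_noise_sd = 5e-4) {
  minis_tr <- generate_noise(noise, durations[["minis"]], dt,
                             seed = seed, sweep_length = sweep_length,
                             epoch = "noise_with_minis")
  noise_tr <- generate_noise(noise, durations[["noise"]], dt,
                             seed = seed + 10000L,
                             sweep_length = sweep_length,
                             epoch = "noise_alone")
  set.seed(seed + 20000L)
  n_ev <- stats::rpois(1L, cell$true_rate * durations[["minis"]] / 1000)
  truth <- sample_true_minis(cell, n_ev)
  truth$onset_ms <- stats::runif(n_ev, 0, durations[["minis"]] - 1)
  ## waveforms: one per distinct rounded rise time (0.1 ms resolution)
  tbl <- build_shape_table(c(0.15, 3), c(1, 1) * cell$tau_m,
                           n_tau1 = 3L, n_tau_m = 1L)
  rkey <- round(truth$rise_time, 1L)
  uk <- sort(unique(rkey))
  wfs <- unit_waveforms(uk, cell$tau1, cell$tau_m, tbl, dt, cell$c_total)
  ev <- data.frame(onset_ms = truth$onset_ms,
                   amplitude = truth$amplitude,
                   waveform_id = match(rkey, uk))
  minis_tr <- superimpose(minis_tr, ev, wfs)
  ## peak times for event matching
  pk <- vapply(seq_len(nrow(ev)), function(i)
    (which.max(wfs[[ev$waveform_id[i]]]) - 1L) * dt, 0)
  truth$peak_time_ms <- truth$onset_ms + pk
  ## pulse response: single-compartment RC, both polarities, averaged
  protocol <- pulse_protocol(t_pulse = 0.5, amplitudes = c(100, -100),
                             pulse_onsets = c(10, 110))
  pulse_tr <- simulate_pulse_response(cell, protocol, dt,
                                      noise_sd = pulse_noise_sd,
                                      seed = seed + 30000L)
  list(minis = minis_tr, noise = noise_tr, pulses = pulse_tr,
       protocol = protocol, truth = truth, cell = cell)
}

#' Simulate the averaged response to brief current pulses
#'
#' Single-compartment RC response embedding the cell's true capacitance
#' and membrane time constant, for closed-loop validation of the
#' passive-property estimators.
#'
#' @param cell A [synthetic_cell_spec()].
#' @param protocol A [pulse_protocol()].
#' @param dt Sampling interval (ms).
#' @param duration Sweep duration (ms).
#' @param noise_sd Added Gaussian noise SD (mV).
#' @param seed Integer seed.
#' @return A [voltage_trace()] with `pulse_windows` set.
#' @export
simulate_pulse_response <- function(cell, protocol, dt = 0.05,
                                    duration = 220, noise_sd = 0,
                                    seed = 1L) {
  n <- as.integer(round(duration / dt))
  t <- (seq_len(n) - 1) * dt
  v <- numeric(n)
  pw <- NULL
  for (p in seq_along(protocol$amplitudes)) {
    on <- protocol$pulse_onsets[p]
    off <- on + protocol$t_pulse
    i_amp <- protocol$amplitudes[p]
    rise <- t >= on & t < off
    decay <- t >= off
    tau <- cell$tau_m
    r_eff <- tau / cell$c_total           # GOhm equivalent in mV/pA
    v[rise] <- v[rise] + i_amp * r_eff * (1 - exp(-(t[rise] - on) / tau))
    v_end <- i_amp * r_eff * (1 - exp(-protocol$t_pulse / tau))
    v[decay] <- v[decay] + v_end * exp(-(t[decay] - off) / tau)
    pw <- rbind(pw, c(round(on / dt), round(off / dt)))
  }
  if (noise_sd > 0) {
    set.seed(seed)
    v <- v + stats::rnorm(n, 0, noise_sd)
  }
  voltage_trace(v - 70, dt, pulse_windows = pw, epoch = "other")
}

#' Generate a synthetic multi-cell population
#'
#' Cells with capacitances spread geometrically over `c_range` (covering
#' a more-than-three-fold range by default) and a fixed per-event
#' charge, so that each cell's true mean amplitude is
#' `true_charge / c_total`.
#'
#' @param n_cells Number of cells (>= 3).
#' @param c_range Capacitance range (pF).
#' @param true_charge Mean charge per mini (fC).
#' @param noise A [noise_model()].
#' @param true_rate Minis rate (minis/s).
#' @param durations Epoch durations (ms).
#' @param dt Sampling interval (ms).
#' @param seed Integer seed.
#' @return List with `recordings` (list of recording pairs) and `truth`
#'   (data frame: `cell_id`, `c_total`, `true_mean_amp`, `true_rate`,
#'   `true_charge`).
#' @export
generate_population <- function(n_cells = 8, c_range = c(100, 400),
                                true_charge = 30, noise = noise_model(),
                                true_rate = 25,
                                durations = c(minis = 30000,
                                              noise = 30000),
                                dt = 0.1, seed = 1L) {
  stopifnot(n_cells >= 3)
  caps <- exp(seq(log(c_range[1L]), log(c_range[2L]),
                  length.out = n_cells))
  recs <- lapply(seq_len(n_cells), function(i) {
    cell <- synthetic_cell_spec(c_total = caps[i],
                                true_charge = true_charge,
                                true_rate = true_rate)
    generate_recording_pair(cell, noise, durations, dt,
                            seed = seed + i * 1000L)
  })
  truth <- data.frame(cell_id = seq_len(n_cells), c_total = caps,
                      true_mean_amp = true_charge / caps,
                      true_rate = true_rate, true_charge = true_charge)
  list(recordings = recs, truth = truth)
}
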