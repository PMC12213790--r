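#' Voltage trace container
#'
#' A uniformly sampled membrane-potential trace with sweep structure, an
#' epoch label, a per-sample exclusion mask and the sample-index windows of
#' injected current pulses. All potentials are in mV and all times in ms;
#' sample indices are 0-based and intervals half-open `[start, end)`.
#'
#' @param samples Numeric vector of membrane potential samples (mV).
#' @param dt Sampling interval (ms), strictly positive.
#' @param sweeps Integer vector of 0-based sweep start indices (first must
#'   be 0, strictly increasing, all within the trace).
#' @param epoch Epoch label, one of `"noise_with_minis"`, `"noise_alone"`,
#'   `"pre_block"`, `"other"`.
#' @param excluded Logical vector, same length as `samples`; `TRUE` marks
#'   samples excluded from analysis.
#' @param pulse_windows Integer matrix with columns `start`, `end` giving
#'   0-based half-open sample windows of injected-pulse periods.
#' @param current Optional co-recorded current channel (pA), same length
#'   as `samples`.
#'
#' @return An object of class `voltage_trace`.
#' @export
voltage_trace <- function(samples, dt, sweeps = 0L,
                          epoch = c("other", "noise_with_minis",
                                    "noise_alone", "pre_block"),
                          excluded = NULL, pulse_windows = NULL,
                          current = NULL) {
  epoch <- match.arg(epoch)
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (ms)")
  n <- length(samples)
  sweeps <- as.integer(sweeps)
  if (length(sweeps) == 0L) sweeps <- 0L
  if (sweeps[1L] != 0L)
    stop("first sweep boundary must be sample index 0")
  if (any(diff(sweeps) <= 0L))
    stop("sweep boundaries must be strictly increasing")
  if (any(sweeps < 0L) || any(sweeps >= max(n, 1L)))
    stop("sweep boundaries must lie within the trace")
  if (is.null(excluded)) excluded <- rep(FALSE, n)
  if (length(excluded) != n)
    stop("`excluded` must have the same length as `samples`")
  if (is.null(pulse_windows)) {
    pulse_windows <- matrix(integer(0), ncol = 2L,
                            dimnames = list(NULL, c("start", "end")))
  } else {
    pulse_windows <- matrix(as.integer(pulse_windows), ncol = 2L,
                            dimnames = list(NULL, c("start", "end")))
    if (any(pulse_windows[, 1L] < 0L) || any(pulse_windows[, 2L] > n) ||
        any(pulse_windows[, 2L] <= pulse_windows[, 1L]))
      stop("pulse windows must be non-empty half-open intervals within the trace")
  }
  if (!is.null(current) && length(current) != n)
    stop("`current` must have the same length as `samples`")
  structure(
    list(samples = samples, dt = dt, sweeps = sweeps, epoch = epoch,
         excluded = as.logical(excluded), pulse_windows = pulse_windows,
         current = current),
    class = "voltage_trace")
}

#' @export
print.voltage_trace <- function(x, ...) {
  cat(sprintf(
    "<voltage_trace> %d samples, dt = %g ms (%.3f s), %d sweep(s), epoch '%s'\n",
    length(x$samples), x$dt, trace_duration(x) / 1000, length(x$sweeps),
    x$epoch))
  if (any(x$excluded))
    cat(sprintf("  excluded: %.3f s (%.1f%%)\n",
                sum(x$excluded) * x$dt / 1000,
                100 * mean(x$excluded)))
  invisible(x)
}

#' Trace duration in ms
#' @param trace A [voltage_trace()].
#' @return Duration (ms).
#' @export
trace_duration <- function(trace) length(trace$samples) * trace$dt

#' Usable (non-excluded) duration in ms
#' @param trace A [voltage_trace()].
#' @return Retained duration (ms).
#' @export
retained_duration <- function(trace) sum(!trace$excluded) * trace$dt

## sweep end indices (half-open), 0-based
sweep_ends <- function(trace) {
  c(trace$sweeps[-1L], length(trace$samples))
}

#' Current-pulse stimulation protocol
#'
#' Describes the brief depolarising and hyperpolarising current pulses
#' delivered at the start of each sweep for passive-property estimation.
#'
#' @param t_pulse Pulse duration (ms), positive.
#' @param amplitudes Numeric vector of injected currents (pA), one per
#'   pulse polarity; a depolarising (positive) and a hyperpolarising
#'   (negative) pulse are expected per sweep.
#' @param pulse_onsets Pulse onset times (ms) relative to sweep start,
#'   one per entry of `amplitudes`.
#' @return An object of class `pulse_protocol`.
#' @export
pulse_protocol <- function(t_pulse, amplitudes, pulse_onsets) {
  if (!is.numeric(t_pulse) || length(t_pulse) != 1L || t_pulse <= 0)
    stop("`t_pulse` must be a single positive duration (ms)")
  if (length(amplitudes) != length(pulse_onsets))
    stop("`amplitudes` and `pulse_onsets` must have the same length")
  if (!(any(amplitudes > 0) && any(amplitudes < 0)))
    stop("protocol must contain both a depolarising and a hyperpolarising pulse")
  structure(list(t_pulse = t_pulse, amplitudes = as.numeric(amplitudes),
                 pulse_onsets = as.numeric(pulse_onsets)),
            class = "pulse_protocol")
}

## union of half-open integer intervals given as 2-column matrix
interval_union <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L], iv[, 2L]), , drop = FALSE]
  out <- iv[1L, , drop = FALSE]
  if (nrow(iv) > 1L) for (i in 2L:nrow(iv)) {
    k <- nrow(out)
    if (iv[i, 1L] <= out[k, 2L]) {
      out[k, 2L] <- max(out[k, 2L], iv[i, 2L])
    } else {
      out <- rbind(out, iv[i, , drop = FALSE])
    }
  }
  out
}

#' Mark current-pulse periods as excluded
#'
#' Marks every pulse window of the protocol, extended by a settle margin,
#' as excluded in each sweep. Overlapping margins are merged so no time is
#' double counted.
#'
#' @param trace A [voltage_trace()].
#' @param protocol A [pulse_protocol()]; if `NULL`, the trace's own
#'   `pulse_windows` are used.
#' @param settle_margin Margin (ms) appended after (and a fifth of it
#'   before) each pulse to let the membrane settle; default 50 ms.
#' @return The trace with the pulse periods excluded. The attribute
#'   `"retained_ms"` reports the total retained duration.
#' @export
excise_pulse_periods <- function(trace, protocol = NULL, settle_margin = 50) {
  stopifnot(inherits(trace, "voltage_trace"))
  dt <- trace$dt
  n <- length(trace$samples)
  if (is.null(protocol)) {
    iv <- trace$pulse_windows
    if (nrow(iv) > 0L) {
      iv[, 1L] <- iv[, 1L] - as.integer(round(settle_margin / 5 / dt))
      iv[, 2L] <- iv[, 2L] + as.integer(round(settle_margin / dt))
    }
  } else {
    stopifnot(inherits(protocol, "pulse_protocol"))
    starts <- ends <- integer(0)
    for (s0 in trace$sweeps) {
      on <- s0 + round(protocol$pulse_onsets / dt)
      off <- on + round(protocol$t_pulse / dt)
      starts <- c(starts, as.integer(on - round(settle_margin / 5 / dt)))
      ends <- c(ends, as.integer(off + round(settle_margin / dt)))
    }
    iv <- cbind(start = starts, end = ends)
    if (any(starts > n) || any(ends < 0))
      stop("pulse window outside trace")
  }
  if (nrow(iv) > 0L) {
    iv[, 1L] <- pmax(iv[, 1L], 0L)
    iv[, 2L] <- pmin(iv[, 2L], n)
    iv <- iv[iv[, 2L] > iv[, 1L], , drop = FALSE]
    iv <- interval_union(iv)
    for (i in seq_len(nrow(iv)))
      trace$excluded[(iv[i, 1L] + 1L):iv[i, 2L]] <- TRUE
    trace$pulse_windows <- interval_union(rbind(trace$pulse_windows, iv))
  }
  attr(trace, "retained_ms") <- retained_duration(trace)
  trace
}

#' Split a trace into equal-duration files
#'
#' Divides the trace into consecutive, non-overlapping segments of exactly
#' `target_duration` each, dropping the trailing remainder. Used to build
#' the set of equal-length "real" distribution files that the fitted
#' simulated distribution is compared against.
#'
#' @param trace A [voltage_trace()].
#' @param target_duration Segment duration (ms); must not exceed the trace
#'   duration.
#' @return A list of `voltage_trace` objects.
#' @export
split_into_files <- function(trace, target_duration) {
  stopifnot(inherits(trace, "voltage_trace"))
  n <- length(trace$samples)
  n_per <- as.integer(round(target_duration / trace$dt))
  if (n_per <= 0L || n_per > n)
    stop("`target_duration` must be positive and no longer than the trace")
  k <- n %/% n_per
  ends0 <- sweep_ends(trace)
  lapply(seq_len(k), function(i) {
    lo <- (i - 1L) * n_per  # 0-based
    hi <- i * n_per
    idx <- (lo + 1L):hi
    sw <- trace$sweeps[trace$sweeps >= lo & trace$sweeps < hi] - lo
    if (length(sw) == 0L || sw[1L] != 0L) sw <- c(0L, sw)
    pw <- trace$pulse_windows
    keep <- pw[, 1L] < hi & pw[, 2L] > lo
    pw <- pw[keep, , drop = FALSE]
    if (nrow(pw) > 0L) {
      pw[, 1L] <- pmax(pw[, 1L] - lo, 0L)
      pw[, 2L] <- pmin(pw[, 2L] - lo, n_per)
    }
    voltage_trace(trace$samples[idx], trace$dt, sweeps = unique(sw),
                  epoch = trace$epoch, excluded = trace$excluded[idx],
                  pulse_windows = pw,
                  current = if (!is.null(trace$current)) trace$current[idx])
  })
}
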