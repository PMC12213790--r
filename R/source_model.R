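#' Binned amplitude-by-rise-time event histogram
#'
#' The currency of all scoring: a 2-D histogram of event counts with
#' amplitude bins of 10 uV and 10-90% rise-time bins of 0.5 ms by
#' default.
#'
#' @param amplitudes Event amplitudes (mV); values outside the grid are
#'   clipped into the edge bins.
#' @param rise_times Event 10-90% rise times (ms).
#' @param amp_edges Amplitude bin edges (mV).
#' @param rise_edges Rise-time bin edges (ms).
#' @return Object of class `event_histogram2d`: a list with `counts`
#'   (amplitude bins by rise bins), `amp_edges`, `rise_edges`.
#' @export
event_histogram2d <- function(amplitudes, rise_times,
                              amp_edges = default_amp_edges(),
                              rise_edges = default_rise_edges()) {
  stopifnot(length(amplitudes) == length(rise_times))
  na <- length(amp_edges) - 1L
  nr <- length(rise_edges) - 1L
  counts <- matrix(0, na, nr)
  if (length(amplitudes) > 0L) {
    ok <- is.finite(amplitudes) & is.finite(rise_times)
    ia <- pmin(pmax(findInterval(amplitudes[ok], amp_edges,
                                 rightmost.closed = TRUE), 1L), na)
    ir <- pmin(pmax(findInterval(rise_times[ok], rise_edges,
                                 rightmost.closed = TRUE), 1L), nr)
    tab <- tabulate(ia + (ir - 1L) * na, nbins = na * nr)
    counts <- matrix(tab, na, nr)
  }
  new_hist2d(counts, amp_edges, rise_edges)
}

new_hist2d <- function(counts, amp_edges, rise_edges) {
  structure(list(counts = counts, amp_edges = amp_edges,
                 rise_edges = rise_edges),
            class = "event_histogram2d")
}

#' Default amplitude bin edges: 10 uV bins over 0-10 mV
#' @return Numeric vector of edges (mV).
#' @export
default_amp_edges <- function() seq(0, 10, by = 0.01)

#' Default rise-time bin edges: 0.5 ms bins over 0-10 ms
#' @return Numeric vector of edges (ms).
#' @export
default_rise_edges <- function() seq(0, 10, by = 0.5)

bin_centers <- function(edges) (edges[-1L] + edges[-length(edges)]) / 2

#' Marginal distributions of a 2-D event histogram
#' @param hist An [event_histogram2d()].
#' @return List with `amplitude` and `rise_time` marginal count vectors.
#' @export
hist2d_marginals <- function(hist) {
  list(amplitude = rowSums(hist$counts), rise_time = colSums(hist$counts))
}

#' Mean amplitude and total count of a histogram
#' @param hist An [event_histogram2d()].
#' @return List with `total`, `mean_amplitude` (mV), `mean_rise_time`
#'   (ms).
#' @export
hist2d_moments <- function(hist) {
  tot <- sum(hist$counts)
  ac <- bin_centers(hist$amp_edges)
  rc <- bin_centers(hist$rise_edges)
  list(total = tot,
       mean_amplitude = if (tot > 0) sum(rowSums(hist$counts) * ac) / tot
       else NA_real_,
       mean_rise_time = if (tot > 0) sum(colSums(hist$counts) * rc) / tot
       else NA_real_)
}

#' One rotated bivariate normal mixture component
#'
#' @param mu_x,sigma_x Amplitude mean and SD (mV); `sigma_x > 0`.
#' @param mu_y,sigma_y Rise-time mean and SD (ms); `sigma_y > 0`.
#' @param rho Correlation in (-1, 1).
#' @param n Count scale; may be negative for the sculpting components.
#' @return Object of class `bivariate_component`.
#' @export
bivariate_component <- function(mu_x, sigma_x, mu_y, sigma_y, rho, n) {
  stopifnot(sigma_x > 0, sigma_y > 0, abs(rho) < 1)
  structure(list(mu_x = mu_x, sigma_x = sigma_x, mu_y = mu_y,
                 sigma_y = sigma_y, rho = rho, n = n),
            class = "bivariate_component")
}

#' Simulated-minis source distribution
#'
#' Mixture of four rotated bivariate (amplitude x 10-90% rise time)
#' normal components. The first component carries a non-negative count
#' scale; the remaining three may carry negative counts used to "sculpt"
#' the base distribution. Together with the synaptic rise constant
#' `tau1`, the membrane constant `tau_m` and the amplitude lower limit
#' this is the genetic algorithm's 26-parameter genome.
#'
#' @param components List of 4 [bivariate_component()]s; the first must
#'   have `n >= 0`.
#' @param amp_lower_limit Amplitude lower limit (mV, >= 0); realized mass
#'   below it is zeroed.
#' @param tau1 Synaptic current rise time constant (ms).
#' @param tau_m Passive membrane time constant (ms).
#' @param reference_duration Duration (ms) to which the realized total
#'   count refers; sampled event counts scale linearly with trace
#'   duration relative to this. Default 100 s, the typical length of a
#'   selected noise-alone file.
#' @return Object of class `minis_source_distribution`.
#' @export
minis_source_distribution <- function(components, amp_lower_limit = 0,
                                      tau1 = 0.5, tau_m = 20,
                                      reference_duration = 1e5) {
  stopifnot(length(components) == 4L,
            all(vapply(components, inherits, TRUE, "bivariate_component")),
            amp_lower_limit >= 0, tau1 > 0, tau_m > 0,
            reference_duration > 0)
  if (components[[1L]]$n < 0)
    stop("component 1 must have a non-negative count scale")
  structure(list(components = components,
                 amp_lower_limit = amp_lower_limit,
                 tau1 = tau1, tau_m = tau_m,
                 reference_duration = reference_duration),
            class = "minis_source_distribution")
}

## bin-integrated mass of one component on the grid: exact normal mass in
## the amplitude marginal times the exact conditional rise-time mass at
## the amplitude bin midpoint
component_mass <- function(comp, amp_edges, rise_edges) {
  px <- diff(stats::pnorm(amp_edges, comp$mu_x, comp$sigma_x))
  na <- length(px)
  out <- matrix(0, na, length(rise_edges) - 1L)
  live <- which(px > 1e-13)               # restrict to the support
  if (length(live) == 0L) return(out)
  xc <- bin_centers(amp_edges)[live]
  mu_c <- comp$mu_y + comp$rho * comp$sigma_y / comp$sigma_x *
    (xc - comp$mu_x)
  sd_c <- comp$sigma_y * sqrt(1 - comp$rho^2)
  P <- stats::pnorm(outer(-mu_c, rise_edges, `+`) / sd_c)
  out[live, ] <- comp$n * px[live] *
    (P[, -1L, drop = FALSE] - P[, -ncol(P), drop = FALSE])
  out
}

#' Realize the source distribution on a histogram grid
#'
#' Sums the bin-integrated masses of the four components, zeroes any
#' negative totals, and zeroes bins below the amplitude lower limit or at
#' negative rise times.
#'
#' @param dist A [minis_source_distribution()].
#' @param amp_edges,rise_edges Bin edges of the target grid.
#' @return An [event_histogram2d()] of non-negative expected counts.
#' @export
realize_histogram <- function(dist, amp_edges = default_amp_edges(),
                              rise_edges = default_rise_edges()) {
  stopifnot(inherits(dist, "minis_source_distribution"))
  counts <- 0
  for (comp in dist$components)
    counts <- counts + component_mass(comp, amp_edges, rise_edges)
  counts[counts < 0] <- 0
  ac <- bin_centers(amp_edges)
  rc <- bin_centers(rise_edges)
  counts[ac < dist$amp_lower_limit, ] <- 0
  counts[, rc < 0] <- 0
  new_hist2d(counts, amp_edges, rise_edges)
}

#' Sample events from a realized source distribution
#'
#' Draws event (amplitude, rise time) pairs from the realized (zeroed)
#' histogram and uniform onset times over the trace. The expected event
#' count is the realized total scaled by `trace_duration` relative to the
#' distribution's reference duration; the drawn count is the rounded
#' expectation.
#'
#' @param dist A [minis_source_distribution()].
#' @param trace_duration Duration of the target trace (ms).
#' @param seed Integer seed; fixed seed gives identical event lists.
#' @param realized Optional pre-computed [realize_histogram()] output.
#' @return Data frame with `onset_ms`, `amplitude` (mV), `rise_time`
#'   (ms, the center of the drawn rise bin), `rise_bin`.
#' @export
sample_events <- function(dist, trace_duration, seed = NULL,
                          realized = NULL) {
  stopifnot(inherits(dist, "minis_source_distribution"))
  if (is.null(realized)) realized <- realize_histogram(dist)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  tot <- sum(realized$counts)
  n_ev <- as.integer(round(tot * trace_duration / dist$reference_duration))
  empty <- data.frame(onset_ms = numeric(0), amplitude = numeric(0),
                      rise_time = numeric(0), rise_bin = integer(0))
  if (tot <= 0 || n_ev == 0L) return(empty)
  na <- nrow(realized$counts)
  bins <- sample.int(length(realized$counts), n_ev, replace = TRUE,
                     prob = as.vector(realized$counts))
  ia <- (bins - 1L) %% na + 1L
  ir <- (bins - 1L) %/% na + 1L
  aw <- diff(realized$amp_edges)
  amp <- realized$amp_edges[ia] + stats::runif(n_ev) * aw[ia]
  rc <- bin_centers(realized$rise_edges)
  data.frame(onset_ms = stats::runif(n_ev, 0, trace_duration),
             amplitude = amp, rise_time = rc[ir], rise_bin = ir)
}

#' Shape constraints on the realized source distribution
#'
#' Four penalties applied to candidate source distributions: (1) the
#' realized 2-D distribution must be unimodal, (2) the rise-time mean
#' must not exceed 5 ms, (3) the rise-time mean must exceed the median by
#' at least a quarter of the SD (the skewness seen in real minis), and
#' (4) the amplitude marginal must not have a sharp cliff at its lower
#' end.
#'
#' @param dist A [minis_source_distribution()].
#' @param realized Optional pre-computed realized histogram.
#' @return List with logical flags `non_unimodal`, `rise_mean_high`,
#'   `rise_skew_low`, `amp_cliff`, a combined `violations` count, and
#'   `penalties` (magnitudes of each violation).
#' @export
check_shape_constraints <- function(dist, realized = NULL) {
  if (is.null(realized)) realized <- realize_histogram(dist)
  cts <- realized$counts
  tot <- sum(cts)
  rc <- bin_centers(realized$rise_edges)
  ac <- bin_centers(realized$amp_edges)
  if (tot <= 0) {
    flags <- c(non_unimodal = FALSE, rise_mean_high = FALSE,
               rise_skew_low = TRUE, amp_cliff = FALSE)
    return(list(non_unimodal = FALSE, rise_mean_high = FALSE,
                rise_skew_low = TRUE, amp_cliff = FALSE,
                violations = 1L,
                penalties = c(0, 0, 0.25, 0)))
  }
  ## (1) unimodality: local maxima of the 3x3 mean-smoothed 2-D histogram
  sm <- smooth2d_3x3(cts)
  nmax <- count_local_maxima(sm, 0.05 * max(sm))
  non_unimodal <- nmax > 1L
  ## (2)-(3) rise-time moments
  rmarg <- colSums(cts)
  rmean <- sum(rmarg * rc) / tot
  rsd <- sqrt(max(sum(rmarg * rc^2) / tot - rmean^2, 0))
  rmed <- binned_median(realized$rise_edges, rmarg)
  rise_mean_high <- rmean > 5
  skew <- if (rsd > 0) (rmean - rmed) / rsd else 0
  rise_skew_low <- skew < 0.25
  ## (4) sharp cliff: first nonzero amplitude bin above half the peak bin
  amarg <- rowSums(cts)
  nz <- which(amarg > 0)
  amp_cliff <- length(nz) > 0 && amarg[nz[1L]] > 0.5 * max(amarg)
  list(non_unimodal = non_unimodal, rise_mean_high = rise_mean_high,
       rise_skew_low = rise_skew_low, amp_cliff = amp_cliff,
       violations = sum(non_unimodal, rise_mean_high, rise_skew_low,
                        amp_cliff),
       penalties = c(
         non_unimodal = if (non_unimodal) nmax - 1 else 0,
         rise_mean_high = max(rmean - 5, 0),
         rise_skew_low = max(0.25 - skew, 0),
         amp_cliff = if (amp_cliff) amarg[nz[1L]] / max(amarg) - 0.5
         else 0))
}

smooth2d_3x3 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  acc <- matrix(0, nr, nc)
  cnt <- matrix(0, nr, nc)
  ones <- matrix(1, nr + 2L, nc + 2L) * 0
  ones[2:(nr + 1L), 2:(nc + 1L)] <- 1
  for (di in 0:2) for (dj in 0:2) {
    acc <- acc + p[(1:nr) + di, (1:nc) + dj]
    cnt <- cnt + ones[(1:nr) + di, (1:nc) + dj]
  }
  acc / cnt
}

## count local maxima above `floor` (8-neighborhood, plateaus counted once
## via strict comparison against earlier neighbors)
count_local_maxima <- function(m, floor) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(-Inf, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  is_max <- matrix(TRUE, nr, nc)
  for (di in 0:2) for (dj in 0:2) {
    if (di == 1L && dj == 1L) next
    nb <- p[(1:nr) + di, (1:nc) + dj]
    if (di < 1L || (di == 1L && dj < 1L)) {
      is_max <- is_max & (m > nb)        # strict vs earlier neighbors
    } else {
      is_max <- is_max & (m >= nb)
    }
  }
  sum(is_max & m > floor)
}

## histogram median with linear interpolation inside the median bin
## (counts treated as uniform within each bin)
binned_median <- function(edges, w) {
  cw <- cumsum(w) / sum(w)
  i <- min(which(cw >= 0.5))
  prev <- if (i > 1L) cw[i - 1L] else 0
  frac <- (0.5 - prev) / (cw[i] - prev)
  edges[i] + frac * (edges[i + 1L] - edges[i])
}

#' Serialize a source distribution to JSON
#' @param dist A [minis_source_distribution()].
#' @param path Output path; if `NULL`, the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_source_distribution <- function(dist, path = NULL) {
  x <- list(components = lapply(dist$components, unclass),
            amp_lower_limit = dist$amp_lower_limit,
            tau1 = dist$tau1, tau_m = dist$tau_m,
            reference_duration = dist$reference_duration)
  if (is.null(path))
    return(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a source distribution from JSON
#' @param path Path written by [write_source_distribution()].
#' @return A [minis_source_distribution()].
#' @export
read_source_distribution <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  comps <- lapply(seq_len(nrow(x$components)), function(i)
    do.call(bivariate_component, as.list(x$components[i, ])))
  minis_source_distribution(comps, x$amp_lower_limit, x$tau1, x$tau_m,
                            x$reference_duration)
}
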