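#' Genetic-algorithm configuration
#'
#' @param population Individuals per generation; the full-scale default
#'   is 260 (10 per optimized parameter).
#' @param elite_fraction Fraction of top individuals copied unchanged
#'   into the next generation (default 0.05).
#' @param max_generations Generation cap (default 1000).
#' @param stall_generations Stop after this many generations without
#'   improvement (default 100; improvement compared with absolute
#'   tolerance 1e-9 on the total cost).
#' @param param_ranges 26 x 2 matrix of per-parameter lower/upper
#'   bounds; see [default_param_ranges()].
#' @param reseed_shrink Reseeded runs draw the population within
#'   `reseed_shrink` times the original range width around the seed
#'   genome (default 0.25).
#' @param threshold_step Amplitude-lower-limit step of the forward and
#'   backward procedures (mV; default 0.01, one amplitude bin).
#' @param seed Integer seed; all GA randomness (operators and
#'   per-individual event placement) derives from it.
#' @param mutation_rate Per-gene mutation probability.
#' @param mutation_sd Mutation SD as a fraction of the parameter range.
#' @param tournament Tournament size for parent selection.
#' @return Object of class `ga_config`.
#' @export
ga_config <- function(population = 260, elite_fraction = 0.05,
                      max_generations = 1000, stall_generations = 100,
                      param_ranges = default_param_ranges(),
                      reseed_shrink = 0.25, threshold_step = 0.01,
                      seed = 1L, mutation_rate = 0.15,
                      mutation_sd = 0.1, tournament = 3L) {
  stopifnot(population >= 2, nrow(param_ranges) == 26L)
  structure(list(population = as.integer(population),
                 elite_fraction = elite_fraction,
                 max_generations = as.integer(max_generations),
                 stall_generations = as.integer(stall_generations),
                 param_ranges = param_ranges,
                 reseed_shrink = reseed_shrink,
                 threshold_step = threshold_step, seed = as.integer(seed),
                 mutation_rate = mutation_rate, mutation_sd = mutation_sd,
                 tournament = as.integer(tournament)),
            class = "ga_config")
}

#' Initial GA parameter ranges
#'
#' Per bivariate component: amplitude mean -0.1 to 1 mV, amplitude SD
#' 0.01-1 mV, rise-time mean -1 to 10 ms, rise-time SD 0.25-10 ms,
#' correlation -1 to 1, and count scale 0-10000 for the first component
#' and -10000 to 10000 for the three sculpting components. The synaptic
#' rise constant ranges over 0.15-3 ms and the membrane time constant
#' over 0.9-1.1 times its initial estimate.
#'
#' @param tau_m_est Initial membrane time constant estimate (ms).
#' @return 26 x 2 numeric matrix of bounds, with row names.
#' @export
default_param_ranges <- function(tau_m_est = 20) {
  comp <- function(first) rbind(
    mu_x = c(-0.1, 1), sigma_x = c(0.01, 1),
    mu_y = c(-1, 10), sigma_y = c(0.25, 10), rho = c(-1, 1),
    n = if (first) c(0, 10000) else c(-10000, 10000))
  rng <- rbind(comp(TRUE), comp(FALSE), comp(FALSE), comp(FALSE),
               tau1 = c(0.15, 3),
               tau_m = c(0.9, 1.1) * tau_m_est)
  rownames(rng) <- c(paste(rep(c("mu_x", "sigma_x", "mu_y", "sigma_y",
                                 "rho", "n"), 4),
                           rep(1:4, each = 6), sep = "_"),
                     "tau1", "tau_m")
  rng
}

#' Decode a 26-parameter genome into a source distribution
#'
#' @param genome Numeric vector of length 26 in the order of
#'   [default_param_ranges()].
#' @param amp_lower_limit Amplitude lower limit (mV).
#' @param reference_duration Reference duration of the count scales (ms).
#' @return A [minis_source_distribution()].
#' @export
decode_genome <- function(genome, amp_lower_limit = 0,
                          reference_duration = 1e5) {
  stopifnot(length(genome) == 26L)
  comps <- lapply(0:3, function(c4) {
    g <- genome[c4 * 6L + 1:6]
    n <- if (c4 == 0L) max(g[6L], 0) else g[6L]
    bivariate_component(g[1L], max(g[2L], 1e-6), g[3L],
                        max(g[4L], 1e-6), max(min(g[5L], 0.999), -0.999),
                        n)
  })
  minis_source_distribution(comps, amp_lower_limit,
                            tau1 = genome[25L], tau_m = genome[26L],
                            reference_duration = reference_duration)
}

## ---------------------------------------------------------------------
## waveform shape table: 10-90% rise time of the unit waveform as a
## function of (X, tau1, tau_m), used to map sampled rise times to input
## distances without per-event root finding

build_shape_table <- function(tau1_range, tau_m_range, L = 1,
                              n_terms = 100, n_x = 13L, n_tau1 = 7L,
                              n_tau_m = 3L) {
  xg <- seq(0, L * (1 - 1e-6), length.out = n_x)
  t1g <- seq(tau1_range[1L], tau1_range[2L], length.out = n_tau1)
  tmg <- seq(tau_m_range[1L], tau_m_range[2L], length.out = n_tau_m)
  rise <- array(NA_real_, c(n_x, n_tau1, n_tau_m))
  for (j in seq_len(n_tau1)) for (k in seq_len(n_tau_m)) {
    dtf <- min(0.05, t1g[j] / 3)
    dur <- max(5 * tmg[k], 40)
    for (i in seq_len(n_x)) {
      p <- waveform_params(tau1 = t1g[j], tau_m = tmg[k],
                           n_terms = n_terms, electrotonic_distance = xg[i],
                           charge_scale = 100, c_total = 200, L = L)
      rise[i, j, k] <- measure_waveform(simulate_psp(p, dtf, dur),
                                        dtf)$rise_10_90
    }
  }
  list(x = xg, tau1 = t1g, tau_m = tmg, rise = rise, L = L,
       n_terms = n_terms)
}

## rise(X) curve at given tau1/tau_m via bilinear interpolation between
## table nodes
shape_rise_curve <- function(tbl, tau1, tau_m) {
  grid_pos <- function(val, g) {
    if (length(g) == 1L) return(c(1L, 0))
    i <- min(max(findInterval(val, g), 1L), length(g) - 1L)
    f <- (val - g[i]) / (g[i + 1L] - g[i])
    c(i, min(max(f, 0), 1))
  }
  pj <- grid_pos(tau1, tbl$tau1)
  pk <- grid_pos(tau_m, tbl$tau_m)
  j <- pj[1L]; fj <- pj[2L]
  k <- pk[1L]; fk <- pk[2L]
  r <- tbl$rise[, j, k] * (1 - fj) * (1 - fk)
  if (fj > 0) r <- r + tbl$rise[, j + 1L, k] * fj * (1 - fk)
  if (fk > 0) r <- r + tbl$rise[, j, k + 1L] * (1 - fj) * fk
  if (fj > 0 && fk > 0) r <- r + tbl$rise[, j + 1L, k + 1L] * fj * fk
  r
}

## unit-peak waveforms (at the trace dt) for a set of rise-time targets;
## targets outside the achievable range are clamped to the end points
unit_waveforms <- function(rise_targets, tau1, tau_m, tbl, dt, c_total) {
  curve <- shape_rise_curve(tbl, tau1, tau_m)
  xs <- stats::approx(curve, tbl$x, xout = rise_targets, rule = 2)$y
  dur <- max(5 * tau_m, 40)
  t <- seq(0, dur, by = dt)
  lapply(xs, function(X) {
    p <- waveform_params(tau1 = tau1, tau_m = tau_m, n_terms = tbl$n_terms,
                         electrotonic_distance = X, charge_scale = 100,
                         c_total = c_total, L = tbl$L)
    v <- psp_series_eval(p, t)
    v / max(v)
  })
}

## series evaluation at arbitrary sample times (no dt-resolution check;
## the closed form is exact at any t)
psp_series_eval <- function(params, t) {
  saved <- params
  dt_fine <- min(diff(t)[1L], params$tau1 / 3)
  n <- length(t)
  ## reuse simulate_psp's algebra by direct evaluation
  with(params, {
    k <- 0:(n_terms - 1L)
    tau_k <- tau_m / (1 + (k * pi / L)^2)
    b_k <- ifelse(k == 0, 1, 2 * cos(k * pi * electrotonic_distance / L))
    t1 <- tau1; t2 <- tau2
    if (abs(t1 - t2) < 1e-9) t2 <- t2 * (1 + 1e-9)
    eq <- abs(tau_k - t1) < 1e-12 * t1
    tau_k[eq] <- tau_k[eq] * (1 + 1e-9)
    eq <- abs(tau_k - t2) < 1e-12 * t2
    tau_k[eq] <- tau_k[eq] * (1 + 1e-9)
    A <- charge_scale / (t2 - t1)
    g2 <- t2 * tau_k / (tau_k - t2)
    g1 <- t1 * tau_k / (tau_k - t1)
    alpha <- b_k * (g2 - g1)
    E <- exp(outer(t, -1 / tau_k))
    v <- as.vector(E %*% alpha) -
      sum(b_k * g2) * exp(-t / t2) + sum(b_k * g1) * exp(-t / t1)
    v * A / c_total
  })
}

## ---------------------------------------------------------------------

#' Prepare the fitting context from a recording pair
#'
#' Splits the noise-with-minis epoch into equal-length comparison files,
#' detects events in each, selects the reference distribution (the last
#' file, closest in time to the noise-alone epoch), estimates the
#' combined centile from single-sweep pairings and the score cutoffs
#' from the comparison-file pairings, and precomputes the waveform shape
#' table.
#'
#' @param minis_trace Noise-with-minis [voltage_trace()].
#' @param noise_trace Noise-alone [voltage_trace()]; its leading segment
#'   of `file_length` is the superposition target.
#' @param detection A [detection_config()] applied identically to real
#'   and simulated traces.
#' @param file_length Comparison-file duration (ms).
#' @param sweep_length Single-sweep duration for the centile estimate
#'   (ms); defaults to half of `file_length`.
#' @param tau_m_est Initial membrane time constant estimate (ms).
#' @param c_total Total membrane capacitance (pF), for waveform scaling.
#' @param amp_edges,rise_edges Histogram grid.
#' @return List of class `minis_fit_setup`.
#' @export
prepare_fitting <- function(minis_trace, noise_trace,
                            detection = detection_config(),
                            file_length = 10000,
                            sweep_length = file_length / 2,
                            tau_m_est = 20, c_total = 200,
                            amp_edges = default_amp_edges(),
                            rise_edges = default_rise_edges()) {
  real_files <- split_into_files(minis_trace, file_length)
  if (length(real_files) < 3L)
    stop("need at least 3 comparison files; shorten `file_length`")
  real_hists <- lapply(real_files, function(tr) {
    ev <- detect_events(tr, detection)
    event_histogram2d(ev$amplitude_mV, ev$rise_10_90_ms, amp_edges,
                      rise_edges)
  })
  ref_idx <- length(real_hists)
  ref_hist <- real_hists[[ref_idx]]
  tail_idx <- amplitude_tail_cutoffs(ref_hist)
  norm <- score_normalization(real_hists, tail_idx)
  ## combined centile from single-sweep pairings
  sweep_files <- split_into_files(minis_trace, sweep_length)
  sweep_hists <- lapply(sweep_files, function(tr) {
    ev <- detect_events(tr, detection)
    event_histogram2d(ev$amplitude_mV, ev$rise_10_90_ms, amp_edges,
                      rise_edges)
  })
  snorm <- score_normalization(sweep_hists, tail_idx)
  pair_matrix <- function(hists, nrm) {
    k <- length(hists)
    rows <- list()
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k)
      rows[[length(rows) + 1L]] <-
        score_vector15(hists[[i]], hists[[j]], tail_idx, nrm)
    do.call(rbind, rows)
  }
  q <- combined_centile(pair_matrix(sweep_hists, snorm))$centile
  cutoffs <- cutoffs_at_centile(pair_matrix(real_hists, norm), q)
  env_baseline <- worst_real_envelope(real_hists, tail_idx, norm)
  scoring <- make_scoring_context(ref_hist, real_hists, cutoffs,
                                  tail_idx = tail_idx, norm = norm,
                                  env_baseline = env_baseline)
  noise_file <- split_into_files(noise_trace, file_length)[[1L]]
  tbl <- build_shape_table(c(0.15, 3), c(0.9, 1.1) * tau_m_est)
  structure(list(
    real_hists = real_hists, ref_hist = ref_hist, ref_idx = ref_idx,
    cutoffs = cutoffs, centile = q, tail_idx = tail_idx, norm = norm,
    env_baseline = env_baseline, scoring = scoring,
    noise_file = noise_file, wf_cache = new.env(parent = emptyenv()),
    detection = detection, amp_edges = amp_edges, rise_edges = rise_edges,
    shape_table = tbl, tau_m_est = tau_m_est, c_total = c_total,
    file_length = file_length), class = "minis_fit_setup")
}

## evaluate one genome: realize -> sample -> superimpose -> detect ->
## histogram -> cost
evaluate_genome <- function(genome, setup, amp_lower_limit, eval_seed) {
  dist <- decode_genome(genome, amp_lower_limit)
  realized <- realize_histogram(dist, setup$amp_edges, setup$rise_edges)
  dur <- trace_duration(setup$noise_file)
  ev <- sample_events(dist, dur, seed = eval_seed, realized = realized)
  if (nrow(ev) > 0L) {
    bins <- sort(unique(ev$rise_bin))
    rc <- bin_centers(setup$rise_edges)
    ## waveforms cached on a quantized (tau1, tau_m) grid (0.05 / 0.25
    ## ms steps): shape sensitivity below that resolution is negligible
    ## and the cache keeps the evaluation loop cheap
    t1q <- round(dist$tau1 / 0.05) * 0.05
    tmq <- round(dist$tau_m / 0.25) * 0.25
    cache <- setup$wf_cache
    wfs <- lapply(bins, function(b) {
      key <- sprintf("%d_%g_%g", b, t1q, tmq)
      if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
      w <- unit_waveforms(rc[b], t1q, tmq, setup$shape_table,
                          setup$noise_file$dt, setup$c_total)[[1L]]
      if (!is.null(cache)) cache[[key]] <- w
      w
    })
    ev$waveform_id <- match(ev$rise_bin, bins)
    sim_trace <- superimpose(setup$noise_file, ev, wfs)
  } else {
    sim_trace <- setup$noise_file
  }
  det <- detect_events(sim_trace, setup$detection, measure_decay = FALSE)
  sim_hist <- event_histogram2d(det$amplitude_mV, det$rise_10_90_ms,
                                setup$amp_edges, setup$rise_edges)
  cost <- cost_from_context(sim_hist, setup$scoring, dist, realized)
  mom <- hist2d_moments(realized)
  list(cost = cost,
       total = if (is.finite(cost$total_cost)) cost$total_cost else Inf,
       sim_hist = sim_hist,
       mean_amplitude = mom$mean_amplitude,
       rate = mom$total / (dist$reference_duration / 1000))
}

#' Run a single genetic-algorithm fit
#'
#' Each individual is evaluated by realizing its source distribution,
#' sampling events, superimposing their waveforms on the noise-alone
#' file, detecting with the shared detection settings, and scoring the
#' resulting histogram against the reference real distribution. The top
#' `elite_fraction` of individuals survive unchanged; offspring are
#' produced by tournament selection, uniform crossover and clipped
#' Gaussian mutation. The run stops at zero cost, after
#' `stall_generations` without improvement, or at the generation cap.
#' Fully deterministic under the configuration seed.
#'
#' @param setup A [prepare_fitting()] context.
#' @param config A [ga_config()].
#' @param amp_lower_limit Simulated-amplitude lower limit (mV).
#' @param init_ranges Optional 26 x 2 matrix overriding the initial
#'   sampling ranges (used by [reseed_run()]).
#' @param seed_genome Optional genome injected unchanged into the
#'   initial population.
#' @return List of class `minis_ga_run`: `best_genome`, `best_dist`,
#'   `cost` (breakdown), `mean_amplitude` (mV), `rate` (minis/s),
#'   `generations_run`, `log` (per-generation best cost and verdict),
#'   `sim_hist`.
#' @export
run_ga <- function(setup, config, amp_lower_limit = 0,
                   init_ranges = NULL, seed_genome = NULL) {
  stopifnot(inherits(setup, "minis_fit_setup"),
            inherits(config, "ga_config"))
  rng <- config$param_ranges
  init <- if (is.null(init_ranges)) rng else init_ranges
  pop_n <- config$population
  set.seed(config$seed)
  pop <- t(replicate(pop_n, stats::runif(26L, init[, 1L], init[, 2L])))
  if (!is.null(seed_genome)) pop[1L, ] <- seed_genome
  n_elite <- max(1L, ceiling(config$elite_fraction * pop_n))
  best <- NULL
  best_total <- Inf
  stall <- 0L
  log_rows <- list()
  gen <- 0L
  evals <- vector("list", pop_n)
  while (gen < config$max_generations) {
    gen <- gen + 1L
    op_state <- .Random.seed
    for (i in seq_len(pop_n)) {
      es <- (config$seed %% 100000L) * 10000L + gen * pop_n + i
      evals[[i]] <- evaluate_genome(pop[i, ], setup, amp_lower_limit,
                                    eval_seed = es %% .Machine$integer.max)
    }
    assign(".Random.seed", op_state, envir = globalenv())
    totals <- vapply(evals, `[[`, 0, "total")
    ord <- order(totals)
    if (totals[ord[1L]] < best_total - 1e-9) {
      best_total <- totals[ord[1L]]
      best <- list(genome = pop[ord[1L], ], eval = evals[[ord[1L]]])
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    log_rows[[gen]] <- data.frame(
      generation = gen, best_cost = best_total,
      gen_best_cost = totals[ord[1L]],
      verdict = best$eval$cost$verdict)
    if (best_total <= 0 || stall >= config$stall_generations) break
    ## next generation
    new_pop <- pop
    new_pop[seq_len(n_elite), ] <- pop[ord[seq_len(n_elite)], ,
                                       drop = FALSE]
    for (i in (n_elite + 1L):pop_n) {
      pick <- function() {
        cand <- sample.int(pop_n, config$tournament)
        cand[which.min(totals[cand])]
      }
      p1 <- pop[pick(), ]
      p2 <- pop[pick(), ]
      mask <- stats::runif(26L) < 0.5
      child <- ifelse(mask, p1, p2)
      mut <- stats::runif(26L) < config$mutation_rate
      if (any(mut)) {
        sdv <- config$mutation_sd * (rng[, 2L] - rng[, 1L])
        child[mut] <- child[mut] + stats::rnorm(sum(mut), 0, sdv[mut])
      }
      new_pop[i, ] <- pmin(pmax(child, rng[, 1L]), rng[, 2L])
    }
    pop <- new_pop
  }
  structure(list(best_genome = best$genome,
                 best_dist = decode_genome(best$genome, amp_lower_limit),
                 cost = best$eval$cost,
                 mean_amplitude = best$eval$mean_amplitude,
                 rate = best$eval$rate,
                 amp_lower_limit = amp_lower_limit,
                 generations_run = gen,
                 log = do.call(rbind, log_rows),
                 sim_hist = best$eval$sim_hist),
            class = "minis_ga_run")
}

#' Reseeded parameter ranges around a previous best genome
#'
#' Population genetic diversity is reset by drawing the next run's
#' initial population within plus or minus `reseed_shrink` (default
#' 25%) of the original range widths around the seed genome, clipped to
#' the legal bounds.
#'
#' @param seed_genome Best genome of the previous run.
#' @param config A [ga_config()].
#' @return 26 x 2 matrix of initial ranges for the next run.
#' @export
reseed_ranges <- function(seed_genome, config) {
  rng <- config$param_ranges
  half <- config$reseed_shrink * (rng[, 2L] - rng[, 1L])
  lo <- pmax(seed_genome - half, rng[, 1L])
  hi <- pmin(seed_genome + half, rng[, 2L])
  cbind(lo, hi)
}

#' Run-with-restarts at a fixed amplitude lower limit
#'
#' Runs the GA, then reinitiates it around the best genome with shrunken
#' ranges until the best-possible verdict is reached, an acceptable fit
#' stops improving, or there is no improvement for two consecutive runs.
#'
#' @inheritParams run_ga
#' @param max_runs Restart cap (default 4).
#' @return The best `minis_ga_run`, with `runs` and `good_enough`
#'   fields added.
#' @export
run_with_reseeds <- function(setup, config, amp_lower_limit = 0,
                             max_runs = 4L) {
  run <- run_ga(setup, config, amp_lower_limit)
  best <- run
  runs <- 1L
  no_improve <- 0L
  while (runs < max_runs && best$cost$verdict != "best_possible") {
    cfg <- config
    cfg$seed <- config$seed + runs
    nxt <- run_ga(setup, cfg, amp_lower_limit,
                  init_ranges = reseed_ranges(best$best_genome, config),
                  seed_genome = best$best_genome)
    runs <- runs + 1L
    if (nxt$cost$total_cost < best$cost$total_cost - 1e-9) {
      best <- nxt
      no_improve <- 0L
    } else {
      no_improve <- no_improve + 1L
    }
    if (best$cost$verdict %in% c("best_possible", "acceptable") &&
        no_improve >= 1L) break
    if (no_improve >= 2L) break
  }
  best$runs <- runs
  best$good_enough <- best$cost$verdict %in% c("best_possible",
                                               "acceptable")
  best
}

#' Forward (upward) amplitude-lower-limit procedure
#'
#' Starting from a low simulated-amplitude lower limit, repeats the
#' fitting cycle, raising the limit by one amplitude bin (10 uV) after
#' every good-enough fit, until fits stop converging; the last
#' good-enough fit (the upper-bound genome) is returned.
#'
#' @param setup A [prepare_fitting()] context.
#' @param config A [ga_config()].
#' @param start_limit Starting lower limit (mV).
#' @param max_steps Step cap.
#' @param runner Fitting function `(setup, config, amp_lower_limit)`
#'   returning an object with `good_enough`; defaults to
#'   [run_with_reseeds()]. Injectable for cheap procedure-level testing.
#' @return The final fit with `attempted_limits` recorded; errors with
#'   class `minisfit_no_initial_fit` when no acceptable fit exists at
#'   the starting limit (the caller should fall back to
#'   [fit_backward()]).
#' @export
fit_forward <- function(setup, config, start_limit = 0, max_steps = 100L,
                        runner = run_with_reseeds) {
  limit <- start_limit
  fit <- runner(setup, config, limit)
  if (!isTRUE(fit$good_enough))
    stop(structure(class = c("minisfit_no_initial_fit", "error",
                             "condition"),
                   list(message = paste0(
                     "no acceptable fit at the starting lower limit ",
                     start_limit, " mV; use fit_backward()"),
                     call = sys.call())))
  limits <- limit
  repeat {
    if (length(limits) > max_steps) break
    nxt_limit <- limit + config$threshold_step
    nxt <- runner(setup, config, nxt_limit)
    limits <- c(limits, nxt_limit)
    if (!isTRUE(nxt$good_enough)) break
    fit <- nxt
    limit <- nxt_limit
  }
  fit$attempted_limits <- limits
  fit$amp_lower_limit_final <- limit
  fit
}

#' Backward (downward) amplitude-lower-limit procedure
#'
#' Starting from a high simulated-amplitude lower limit (200 uV by
#' default), lowers the limit by one amplitude bin per step until a
#' good-enough fit first appears.
#'
#' @inheritParams fit_forward
#' @param start_limit Starting lower limit (mV; default 0.2).
#' @return The first good-enough fit with `attempted_limits`; a hard
#'   error when no fit is found down to limit 0.
#' @export
fit_backward <- function(setup, config, start_limit = 0.2,
                         runner = run_with_reseeds) {
  limit <- start_limit
  limits <- numeric(0)
  while (limit >= -1e-12) {
    limit <- max(limit, 0)
    fit <- runner(setup, config, limit)
    limits <- c(limits, limit)
    if (isTRUE(fit$good_enough)) {
      fit$attempted_limits <- limits
      fit$amp_lower_limit_final <- limit
      return(fit)
    }
    if (limit == 0) break
    limit <- limit - config$threshold_step
  }
  stop("backward procedure found no acceptable fit down to limit 0; ",
       "attempted limits: ", paste(signif(limits, 3), collapse = ", "))
}
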