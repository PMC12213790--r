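# Shared fixtures built in code: small histogram grids, a reusable
# noiseless waveform set, and a cached reduced-scale recovery experiment
# used by several acceptance properties.

small_amp_edges <- seq(0, 1, by = 0.01)
small_rise_edges <- seq(0, 10, by = 0.5)

# histogram from explicit counts (for hand-computed scoring oracles)
hist_from_counts <- function(counts, amp_edges = NULL, rise_edges = NULL) {
  counts <- as.matrix(counts)
  if (is.null(amp_edges)) amp_edges <- seq(0, nrow(counts)) * 0.01
  if (is.null(rise_edges)) rise_edges <- seq(0, ncol(counts)) * 0.5
  minisfit:::new_hist2d(counts, amp_edges, rise_edges)
}

# random small histogram for the score-oracle checks
random_hist <- function(nbin_a = 6L, nbin_r = 3L, lambda = 3) {
  hist_from_counts(matrix(stats::rpois(nbin_a * nbin_r, lambda),
                          nbin_a, nbin_r))
}

# standard quick cell used across detection / GA tests
quick_cell <- function(...) {
  args <- utils::modifyList(list(c_total = 200, tau_m = 20,
                                 mean_amp = 0.35, true_rate = 25),
                            list(...))
  do.call(synthetic_cell_spec, args)
}

# reduced-scale parameter-recovery experiment: one synthetic cell
# (true mean amplitude 0.35 mV, rate 25 minis/s, 60 s epochs), GA with
# population 60 and at most 80 generations at a fixed 0.05 mV amplitude
# lower limit. Computed once per test session and cached, because both
# the recovery and the rate-ordering properties consume it.
recovery_experiment <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    cell <- quick_cell()
    rec <- generate_recording_pair(cell, noise_model(), seed = 42L)
    setup <- prepare_fitting(rec$minis, rec$noise, file_length = 6000,
                             sweep_length = 3000, tau_m_est = 20,
                             c_total = 200)
    cfg <- ga_config(population = 60, max_generations = 80,
                     stall_generations = 25,
                     param_ranges = default_param_ranges(20), seed = 7L)
    run <- run_ga(setup, cfg, amp_lower_limit = 0.05)
    dcfg <- detection_config()
    dm <- detect_events(rec$minis, dcfg, measure_decay = FALSE)
    dn <- detect_events(rec$noise, dcfg, measure_decay = FALSE)
    hm <- event_histogram2d(dm$amplitude_mV, dm$rise_10_90_ms)
    hn <- event_histogram2d(dn$amplitude_mV, dn$rise_10_90_ms)
    cache <<- list(cell = cell, rec = rec, setup = setup, run = run,
                   det_minis = dm, det_noise = dn,
                   hist_minis = hm, hist_noise = hn)
    cache
  }
})
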