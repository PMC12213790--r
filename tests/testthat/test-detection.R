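# unit-peak waveform set shared across detection tests
det_waveforms <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tbl <- build_shape_table(c(0.15, 3), c(20, 20), n_tau1 = 3L,
                               n_tau_m = 1L)
      cache <<- minisfit:::unit_waveforms(c(1.7, 3), 0.75, 20, tbl, 0.1,
                                          200)
    }
    cache
  }
})

test_that("a constant trace yields no events", {
  tr <- voltage_trace(rep(-70, 10000), 0.1)
  expect_identical(nrow(detect_events(tr)), 0L)
})

test_that("well-separated noiseless events are each detected within tolerance", {
  wf <- det_waveforms()
  tr <- voltage_trace(rep(0, 120000), 0.1)    # 12 s
  set.seed(17)
  for (rep in 1:5) {
    k <- sample(3:8, 1)
    onsets <- sort(sample(seq(200, 11000, by = 300), k))
    amps <- runif(k, 0.1, 2)
    ev <- data.frame(onset_ms = onsets, amplitude = amps,
                     waveform_id = sample(1:2, k, replace = TRUE))
    d <- detect_events(superimpose(tr, ev, wf))
    expect_identical(nrow(d), k)
    expect_true(all(abs(d$amplitude_mV - amps) / amps <= 0.02))
  }
})

test_that("rise times match the waveform and refine consistently with dt", {
  # linear ramp 0 -> 1 mV over 1 ms: 10-90% time is 0.8 ms
  dt <- 0.05
  ramp <- c(rep(0, 100), seq(0, 1, length.out = 21), 1 - seq(0, 1,
            length.out = 200) * 0.001)
  tr <- voltage_trace(ramp, dt)
  ip <- which.max(tr$samples)
  expect_equal(rise_time_10_90(tr, ip, 0), 0.8, tolerance = 1e-6)
  # double-exponential waveform: detection matches root-finding on the
  # closed form within dt/2
  p <- waveform_params(tau1 = 0.5, tau2 = 2, tau_m = 20,
                       electrotonic_distance = 0, L = 1e-3,
                       charge_scale = 100, c_total = 200)
  rt_ref <- NULL
  for (dt2 in c(0.05, 0.01)) {
    v <- simulate_psp(p, dt2, 150)
    tr2 <- voltage_trace(v, dt2)
    rt <- rise_time_10_90(tr2, which.max(v), 0, search_back = 50)
    # closed-form oracle: uniroot on the analytic waveform
    h <- function(ta, tk, t) ta * tk / (tk - ta) *
      (exp(-t / tk) - exp(-t / ta))
    f <- function(t) (100 / 1.5) / 200 * (h(2, 20, t) - h(0.5, 20, t))
    pk <- stats::optimize(f, c(0, 30), maximum = TRUE)
    t10 <- stats::uniroot(function(t) f(t) - 0.1 * pk$objective,
                          c(0, pk$maximum))$root
    t90 <- stats::uniroot(function(t) f(t) - 0.9 * pk$objective,
                          c(0, pk$maximum))$root
    expect_equal(rt, t90 - t10, tolerance = dt2 / 2 / (t90 - t10))
    if (is.null(rt_ref)) rt_ref <- rt
  }
  # estimates at dt 0.05 and 0.01 agree within 0.05 ms
  v1 <- simulate_psp(p, 0.05, 150); v2 <- simulate_psp(p, 0.01, 150)
  r1 <- rise_time_10_90(voltage_trace(v1, 0.05), which.max(v1), 0, 50)
  r2 <- rise_time_10_90(voltage_trace(v2, 0.01), which.max(v2), 0, 50)
  expect_lt(abs(r1 - r2), 0.05)
})

test_that("effective decay constant is exact on exponentials and missing when truncated", {
  dt <- 0.1
  t <- seq(0, 200, by = dt)
  tr <- voltage_trace(c(rep(0, 100), exp(-t / 15)), dt)
  expect_equal(effective_decay_tc(tr, 101L, 0), 15, tolerance = 0.01)
  # truncated before 1/e: missing
  tr2 <- voltage_trace(c(rep(0, 100), exp(-seq(0, 10, by = dt) / 15)), dt)
  expect_true(is.na(effective_decay_tc(tr2, 101L, 0)))
})

test_that("overshadowing hides or shrinks a small event on a large decay", {
  wf <- det_waveforms()
  tr <- voltage_trace(rep(0, 60000), 0.1)
  pk1 <- (which.max(wf[[1L]]) - 1L) * 0.1
  ev <- data.frame(onset_ms = c(1000, 1000 + 5),
                   amplitude = c(1, 0.1), waveform_id = c(1L, 1L))
  d <- detect_events(superimpose(tr, ev, wf))
  second <- d[d$peak_time_ms > 1000 + pk1 + 2, , drop = FALSE]
  expect_true(nrow(second) == 0L ||
                all(second$amplitude_mV < 0.1))
})

test_that("detection is deterministic and respects exclusion masks", {
  cell <- quick_cell()
  rec <- generate_recording_pair(cell, noise_model(),
                                 durations = c(minis = 10000,
                                               noise = 10000),
                                 seed = 23L)
  d1 <- detect_events(rec$minis)
  d2 <- detect_events(rec$minis)
  expect_identical(d1, d2)
  expect_gt(nrow(d1), 0L)
  # excluding a window removes exactly the events inside it
  tr <- rec$minis
  tr$excluded[20001:40000] <- TRUE             # 2-4 s
  d3 <- detect_events(tr)
  expect_true(!any(d3$peak_time_ms >= 2000 & d3$peak_time_ms <= 4000))
  outside <- d1[d1$peak_time_ms < 1990 | d1$peak_time_ms > 4010, ]
  expect_equal(nrow(d3), nrow(outside), tolerance = 0.02)
})

test_that("a too-coarse sampling interval is a config error", {
  tr <- voltage_trace(rep(0, 100), dt = 8)
  expect_error(detect_events(tr, detection_config(max_rise_gap = 10)),
               "too coarse")
})
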