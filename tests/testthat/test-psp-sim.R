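test_that("zero charge gives an identically zero waveform", {
  p <- waveform_params(charge_scale = 0)
  expect_true(all(simulate_psp(p, 0.1, 50) == 0))
})

test_that("somatic input in the isopotential limit matches the RC convolution", {
  dt <- 0.05
  p <- waveform_params(tau1 = 0.5, tau2 = 2, tau_m = 20,
                       electrotonic_distance = 0, L = 1e-3,
                       charge_scale = 100, c_total = 200)
  v <- simulate_psp(p, dt, 120)
  t <- (seq_along(v) - 1) * dt
  # closed-form convolution of the double-exponential current with the
  # single RC mode
  h <- function(ta, tk) ta * tk / (tk - ta) * (exp(-t / tk) - exp(-t / ta))
  v_rc <- (100 / (2 - 0.5)) / 200 * (h(2, 20) - h(0.5, 20))
  expect_lt(max(abs(v - v_rc)) / max(v_rc), 0.005)
})

test_that("peak approaches Q/C in the capacitor limit", {
  p <- waveform_params(tau1 = 0.15, tau2 = 0.3, tau_m = 5000,
                       electrotonic_distance = 0, L = 1e-3,
                       charge_scale = 100, c_total = 200)
  v <- simulate_psp(p, 0.01, 60)
  expect_equal(max(v), 100 / 200, tolerance = 0.02)
})

test_that("peak decreases and rise time increases with input distance", {
  dt <- 0.05
  xs <- seq(0, 1, by = 0.125)
  m <- vapply(xs, function(X) {
    p <- waveform_params(tau1 = 0.5, tau_m = 20,
                         electrotonic_distance = X, L = 1,
                         charge_scale = 100, c_total = 200)
    w <- measure_waveform(simulate_psp(p, dt, 150), dt)
    c(w$peak, w$rise_10_90)
  }, numeric(2))
  expect_true(all(diff(m[1L, ]) < 0))
  expect_true(all(diff(m[2L, ]) > 0))
})

test_that("dt too coarse for tau1 is rejected", {
  p <- waveform_params(tau1 = 0.15)
  expect_error(simulate_psp(p, 0.1, 50), "resolve tau1")
})

test_that("calibrate_shape round-trips amplitude and rise time", {
  dt <- 0.05
  for (target in list(c(0.3, 1.8), c(0.5, 2.5), c(0.1, 4))) {
    p <- calibrate_shape(target[1L], target[2L], tau1 = 0.5, tau_m = 20,
                         c_total = 200, dt = dt)
    w <- measure_waveform(simulate_psp(p, dt, 150), dt)
    expect_equal(w$peak, target[1L], tolerance = 0.01)
    expect_equal(w$rise_10_90, target[2L],
                 tolerance = max(0.02 * target[2L], dt) / target[2L])
  }
})

test_that("unreachable rise times produce an informative error", {
  expect_error(calibrate_shape(0.3, 40, tau1 = 0.5, tau_m = 20),
               "achievable range")
  expect_error(calibrate_shape(0.3, 0.05, tau1 = 0.5, tau_m = 20),
               "achievable range")
})

test_that("superimpose is linear, leaves the input untouched, and truncates at sweep ends", {
  tr <- voltage_trace(rep(0, 5000), 0.1, sweeps = c(0L, 2500L))
  p <- waveform_params(tau1 = 0.5, tau_m = 20, electrotonic_distance = 0.3,
                       charge_scale = 100, c_total = 200)
  w <- simulate_psp(p, 0.1, 100)
  w <- w / max(w)
  # empty event list: bit-exact identity
  out0 <- superimpose(tr, data.frame(), list(w))
  expect_identical(out0$samples, tr$samples)
  # one event on a zero trace equals the waveform
  ev1 <- data.frame(onset_ms = 0, amplitude = 0.4, waveform_id = 1L)
  out1 <- superimpose(tr, ev1, list(w))
  expect_equal(out1$samples[seq_along(w)], 0.4 * w)
  # two synchronous co-located events add linearly
  ev2 <- rbind(ev1, data.frame(onset_ms = 0, amplitude = 0.2,
                               waveform_id = 1L))
  out2 <- superimpose(tr, ev2, list(w))
  expect_equal(max(out2$samples), 0.6 * max(w), tolerance = 1e-12)
  # event straddling the sweep boundary is truncated there
  ev3 <- data.frame(onset_ms = 245, amplitude = 1, waveform_id = 1L)
  out3 <- superimpose(tr, ev3, list(w))
  expect_true(all(out3$samples[2501:5000] == 0))
  expect_gt(max(out3$samples[1:2500]), 0)
})
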