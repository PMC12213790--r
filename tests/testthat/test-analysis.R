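test_that("histogram subtraction is signed, anti-symmetric, and mass-conserving", {
  a <- hist_from_counts(matrix(c(5, 3, 1, 0), 4, 1))
  b <- hist_from_counts(matrix(c(7, 2, 0, 0), 4, 1))
  s <- subtract_histograms(a, b, 1000, 1000)
  expect_equal(as.vector(s$diff), c(-2, 1, 1, 0))
  expect_equal(sum(s$diff), sum(a$counts) - sum(b$counts))
  expect_equal(s$negative_bins$rate_deficit, -2)
  expect_equal(s$negative_bins$amp_lo, 0)
  s2 <- subtract_histograms(b, a, 1000, 1000)
  expect_equal(s2$diff, -s$diff)
  # identical inputs: all zero
  s0 <- subtract_histograms(a, a, 1000, 1000)
  expect_true(all(s0$diff == 0))
  # rate normalization: halving the noise epoch doubles its weight
  s3 <- subtract_histograms(a, b, 1000, 2000)
  expect_equal(as.vector(s3$diff), c(5, 3, 1, 0) - c(7, 2, 0, 0) / 2)
})

test_that("incidence-rate estimators cover the three methods and degenerate input", {
  empty <- hist_from_counts(matrix(0, 4, 1))
  s <- subtract_histograms(empty, empty, 1000, 1000)
  expect_equal(incidence_rate(s, method = "subtracted"), 0)
  ev <- data.frame(amplitude_mV = c(0.05, 0.1, 0.3))
  expect_equal(incidence_rate(ev, 1000, method = "thresholded"), 2)
  expect_equal(incidence_rate(ev, 1000, method = "thresholded",
                              threshold = 0.8), 0)
  d <- minis_source_distribution(
    list(bivariate_component(0.3, 0.05, 2, 0.5, 0, 1000),
         bivariate_component(0.3, 0.05, 2, 0.5, 0, 0),
         bivariate_component(0.3, 0.05, 2, 0.5, 0, 0),
         bivariate_component(0.3, 0.05, 2, 0.5, 0, 0)))
  expect_equal(incidence_rate(d, method = "fitted"), 10, tolerance = 0.01)
})

test_that("charge regression recovers a noiseless linear law exactly", {
  caps <- c(100, 150, 220, 330, 400)
  df <- data.frame(c_total = caps, mean_amp = 30 / caps)
  cr <- charge_regression(df)
  expect_equal(cr$slope_origin, 30, tolerance = 1e-12)
  expect_equal(cr$Q_estimate, 30, tolerance = 1e-12)
  expect_equal(cr$intercept_free, 0, tolerance = 1e-10)
  expect_equal(cr$r, 1, tolerance = 1e-12)
  # unit sanity: scaling amplitudes scales the charge estimate
  df2 <- df; df2$mean_amp <- df$mean_amp * 2
  expect_equal(charge_regression(df2)$Q_estimate, 60, tolerance = 1e-12)
  expect_error(charge_regression(data.frame(c_total = c(100, 100, 100),
                                            mean_amp = c(1, 2, 3))),
               "singular")
})

test_that("charge regression tolerates amplitude noise over seeded repeats", {
  errs <- vapply(1:100, function(s) {
    set.seed(s)
    caps <- exp(runif(8, log(100), log(400)))
    y <- 30 / caps * (1 + rnorm(8, 0, 0.05))
    cr <- charge_regression(data.frame(c_total = caps, mean_amp = y))
    abs(cr$Q_estimate - 30) / 30
  }, 0)
  expect_lt(stats::quantile(errs, 0.9, names = FALSE), 0.1)
})

test_that("generic distribution rescales to the target mean and keeps shape", {
  d1 <- minis_source_distribution(
    list(bivariate_component(0.1, 0.015, 2, 0.5, 0, 500),
         bivariate_component(0.1, 0.015, 2, 0.5, 0, 0),
         bivariate_component(0.1, 0.015, 2, 0.5, 0, 0),
         bivariate_component(0.1, 0.015, 2, 0.5, 0, 0)))
  d2 <- minis_source_distribution(
    list(bivariate_component(0.2, 0.03, 2, 0.5, 0, 500),
         bivariate_component(0.2, 0.03, 2, 0.5, 0, 0),
         bivariate_component(0.2, 0.03, 2, 0.5, 0, 0),
         bivariate_component(0.2, 0.03, 2, 0.5, 0, 0)))
  h1 <- realize_histogram(d1); h2 <- realize_histogram(d2)
  g <- generic_distribution(list(h1, h2), target_mean = 0.15)
  expect_equal(hist2d_moments(g)$mean_amplitude, 0.15, tolerance = 0.01)
  # identical shapes after normalization: averaging preserves the CV
  cv <- function(h) {
    ac <- (h$amp_edges[-1] + h$amp_edges[-length(h$amp_edges)]) / 2
    w <- rowSums(h$counts) / sum(h$counts)
    m <- sum(w * ac)
    sqrt(sum(w * ac^2) - m^2) / m
  }
  expect_equal(cv(g), cv(h1), tolerance = 0.05)
  # single input at its own mean is the identity up to rebinning
  g1 <- generic_distribution(list(h1),
                             target_mean = hist2d_moments(h1)$mean_amplitude)
  expect_equal(hist2d_moments(g1)$mean_amplitude,
               hist2d_moments(h1)$mean_amplitude, tolerance = 0.005)
})

test_that("shortcut calibration applies the published linear map", {
  expect_equal(as.numeric(shortcut_mean(120)), 98.5, tolerance = 1e-12)
  expect_true(attr(shortcut_mean(120), "heuristic"))
  expect_equal(as.numeric(shortcut_mean(120, c(1, 0))), 120)
})
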