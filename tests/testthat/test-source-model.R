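make_dist <- function(comps, ...) {
  while (length(comps) < 4L)
    comps <- c(comps, list(bivariate_component(0.3, 0.05, 2, 0.5, 0, 0)))
  minis_source_distribution(comps, ...)
}

test_that("a single component realizes its nominal mass with symmetric marginals", {
  d <- make_dist(list(bivariate_component(0.5, 0.05, 3, 0.5, 0, 100)))
  h <- realize_histogram(d)
  expect_equal(sum(h$counts), 100, tolerance = 0.01)
  m <- hist2d_moments(h)
  expect_equal(m$mean_amplitude, 0.5, tolerance = 0.01)
  expect_equal(m$mean_rise_time, 3, tolerance = 0.01)
})

test_that("negative sculpting components zero out overlap bins", {
  base <- bivariate_component(0.5, 0.05, 3, 0.5, 0, 100)
  carve <- bivariate_component(0.5, 0.02, 3, 0.3, 0, -200)
  d <- make_dist(list(base, carve))
  h <- realize_histogram(d)
  expect_true(all(h$counts >= 0))
  # overlap region is fully zeroed
  ac <- (h$amp_edges[-1] + h$amp_edges[-length(h$amp_edges)]) / 2
  core <- abs(ac - 0.5) < 0.01
  expect_true(all(h$counts[core, 6:7] == 0))
  # per-bin oracle: counts equal the clipped sum of component masses
  m1 <- minisfit:::component_mass(base, h$amp_edges, h$rise_edges)
  m2 <- minisfit:::component_mass(carve, h$amp_edges, h$rise_edges)
  expect_equal(h$counts, pmax(m1 + m2, 0) *
                 (matrix(ac, nrow(h$counts), ncol(h$counts)) >=
                    d$amp_lower_limit))
})

test_that("an amplitude lower limit at the component mean halves the mass", {
  d <- make_dist(list(bivariate_component(0.5, 0.05, 3, 0.5, 0, 100)),
                 amp_lower_limit = 0.5)
  h <- realize_histogram(d)
  expect_equal(sum(h$counts), 50, tolerance = 0.02)
})

test_that("realization is linear in n before zeroing and zeroing never increases bins", {
  c1 <- bivariate_component(0.4, 0.1, 2, 1, 0.3, 100)
  m1 <- minisfit:::component_mass(c1, default_amp_edges(),
                                  default_rise_edges())
  c2 <- c1; c2$n <- 250
  m2 <- minisfit:::component_mass(c2, default_amp_edges(),
                                  default_rise_edges())
  expect_equal(m2, m1 * 2.5)
  d <- make_dist(list(c1, bivariate_component(0.4, 0.1, 2, 1, 0, -50)))
  h <- realize_histogram(d)
  raw <- m1 + minisfit:::component_mass(
    bivariate_component(0.4, 0.1, 2, 1, 0, -50),
    default_amp_edges(), default_rise_edges())
  expect_true(all(h$counts <= pmax(raw, 0) + 1e-12))
})

test_that("sampling is deterministic under seed and converges to the realized law", {
  d <- make_dist(list(bivariate_component(0.3, 0.06, 2.5, 0.8, 0.4, 5000)))
  e1 <- sample_events(d, 60000, seed = 99L)
  e2 <- sample_events(d, 60000, seed = 99L)
  expect_identical(e1, e2)
  # empty distribution
  d0 <- make_dist(list(bivariate_component(0.3, 0.05, 2, 0.5, 0, 0)))
  expect_identical(nrow(sample_events(d0, 60000, seed = 1L)), 0L)
  # 1e5 samples: total-variation distance to the normalized realized
  # histogram below 0.02
  h <- realize_histogram(d)
  big <- sample_events(d, 2e6, seed = 7L)     # 20x reference duration
  emp <- event_histogram2d(big$amplitude, big$rise_time,
                           h$amp_edges, h$rise_edges)
  p <- h$counts / sum(h$counts)
  q <- emp$counts / sum(emp$counts)
  expect_lt(sum(abs(p - q)) / 2, 0.02)
  # mean amplitude converges to the realized mean
  expect_equal(mean(big$amplitude), hist2d_moments(h)$mean_amplitude,
               tolerance = 0.01)
})

test_that("shape constraints flag symmetry, slow rise means, and cliffs", {
  # symmetric gaussian: mean = median, skew constraint violated
  sym <- make_dist(list(bivariate_component(0.5, 0.08, 3, 0.5, 0, 100)))
  cs <- check_shape_constraints(sym)
  expect_true(cs$rise_skew_low)
  expect_false(cs$non_unimodal)
  expect_false(cs$rise_mean_high)
  # rise-time mean above 5 ms
  slow <- make_dist(list(bivariate_component(0.5, 0.08, 6, 0.5, 0, 100)))
  expect_true(check_shape_constraints(slow)$rise_mean_high)
  # log-normal-like rise marginal with (mean - median)/SD ~ 0.3 passes
  # the skew constraint: oracle via moments of a constructed log-normal
  sdlog <- 1.0
  meanlog <- log(2) - sdlog^2 / 2
  skew_oracle <- (exp(meanlog + sdlog^2 / 2) - exp(meanlog)) /
    (exp(meanlog + sdlog^2 / 2) * sqrt(exp(sdlog^2) - 1))
  expect_gt(skew_oracle, 0.25)
  set.seed(3)
  amps <- rlnorm(20000, log(0.35) - 0.06, 0.35)
  rises <- rlnorm(20000, meanlog, sdlog)
  h <- event_histogram2d(amps, rises)
  d <- make_dist(list(bivariate_component(0.3, 0.05, 2, 0.5, 0, 100)))
  cs3 <- check_shape_constraints(d, realized = h)
  expect_false(cs3$rise_skew_low)
  # two far-apart components: non-unimodal
  bim <- make_dist(list(bivariate_component(0.2, 0.02, 1, 0.3, 0, 100),
                        bivariate_component(0.7, 0.02, 6, 0.3, 0, 100)))
  expect_true(check_shape_constraints(bim)$non_unimodal)
  # sharp cliff: lower limit slicing through the mode
  cliff <- make_dist(list(bivariate_component(0.3, 0.05, 2, 0.5, 0, 100)),
                     amp_lower_limit = 0.3)
  expect_true(check_shape_constraints(cliff)$amp_cliff)
})

test_that("source distributions serialize to JSON and back", {
  d <- make_dist(list(bivariate_component(0.4, 0.1, 2, 1, 0.3, 120)),
                 amp_lower_limit = 0.05, tau1 = 0.8, tau_m = 21)
  f <- file.path(tempdir(), "dist.json")
  write_source_distribution(d, f)
  back <- read_source_distribution(f)
  expect_equal(back, d)
})
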