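test_that("genome decoding respects ranges and the sculpting sign rules", {
  rng <- default_param_ranges(20)
  expect_identical(dim(rng), c(26L, 2L))
  expect_equal(unname(rng["tau_m", ]), c(18, 22))
  expect_equal(unname(rng["n_1", ]), c(0, 10000))
  expect_equal(unname(rng["n_2", ]), c(-10000, 10000))
  set.seed(61)
  g <- runif(26, rng[, 1], rng[, 2])
  d <- decode_genome(g, amp_lower_limit = 0.05)
  expect_s3_class(d, "minis_source_distribution")
  expect_gte(d$components[[1L]]$n, 0)
  expect_equal(d$tau1, g[25])
  # negative first-component draw is clamped to zero
  g2 <- g; g2[6] <- -5
  expect_equal(decode_genome(g2)$components[[1L]]$n, 0)
})

test_that("reseeded ranges shrink to 25% of the original width around the seed", {
  cfg <- ga_config(population = 10, param_ranges = default_param_ranges(20))
  seed_g <- rep(0, 26)
  seed_g[8] <- 0.2                        # sigma_x of component 2
  rr <- reseed_ranges(seed_g, cfg)
  # range (0.01, 1): half-width 0.25 * 0.99 = 0.2475, clipped at 0.01
  expect_equal(unname(rr[8, ]), c(max(0.2 - 0.2475, 0.01), 0.2 + 0.2475))
  expect_true(all(rr[, 1] >= cfg$param_ranges[, 1] - 1e-12))
  expect_true(all(rr[, 2] <= cfg$param_ranges[, 2] + 1e-12))
})

test_that("forward and backward threshold procedures walk the limit correctly", {
  # cheap stub runner standing in for the GA: fits are good enough
  # exactly when the lower limit does not exceed the truth-determined
  # ceiling of 0.2 mV
  calls <- new.env()
  calls$limits <- numeric(0)
  stub <- function(setup, config, amp_lower_limit, ...) {
    calls$limits <- c(calls$limits, amp_lower_limit)
    list(good_enough = amp_lower_limit <= 0.2 + 1e-12,
         amp_lower_limit = amp_lower_limit,
         cost = list(total_cost = amp_lower_limit, verdict = "acceptable"))
  }
  cfg <- ga_config(population = 10)
  fit <- fit_forward(NULL, cfg, start_limit = 0.05, runner = stub)
  expect_equal(fit$amp_lower_limit_final, 0.2, tolerance = 1e-9)
  expect_true(all(diff(fit$attempted_limits) > 0))
  # backward: first good fit appears once the limit drops to 0.12
  stub_b <- function(setup, config, amp_lower_limit, ...) {
    list(good_enough = amp_lower_limit <= 0.12 + 1e-12,
         amp_lower_limit = amp_lower_limit,
         cost = list(total_cost = 1, verdict = "acceptable"))
  }
  fitb <- fit_backward(NULL, cfg, start_limit = 0.2, runner = stub_b)
  expect_equal(fitb$amp_lower_limit_final, 0.12, tolerance = 1e-9)
  expect_true(all(diff(fitb$attempted_limits) < 0))
  # forward with no fit at the start signals the backward fallback
  stub_none <- function(...) list(good_enough = FALSE)
  expect_error(fit_forward(NULL, cfg, start_limit = 0.05,
                           runner = stub_none),
               class = "minisfit_no_initial_fit")
  # backward that never fits is a hard failure
  expect_error(fit_backward(NULL, ga_config(population = 10,
                                            threshold_step = 0.1),
                            start_limit = 0.2, runner = stub_none),
               "no acceptable fit")
})

test_that("a tiny GA run is deterministic and its best cost never increases", {
  exp6 <- recovery_experiment()
  cfg <- ga_config(population = 8, max_generations = 3,
                   stall_generations = 3,
                   param_ranges = default_param_ranges(20), seed = 99L)
  r1 <- run_ga(exp6$setup, cfg, amp_lower_limit = 0.05)
  r2 <- run_ga(exp6$setup, cfg, amp_lower_limit = 0.05)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$best_genome, r2$best_genome)
  expect_true(all(diff(r1$log$best_cost) <= 1e-12))
  # elitism on the full cached recovery run
  expect_true(all(diff(exp6$run$log$best_cost) <= 1e-12))
})
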