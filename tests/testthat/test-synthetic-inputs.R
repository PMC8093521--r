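test_that("periodic trains respect phase, count and the refractory ceiling", {
  expect_length(periodic_train(10, 0, 1), 10)
  expect_equal(periodic_train(10, 0.05, 0.35), c(0.05, 0.15, 0.25))
  expect_identical(periodic_train(0, 0, 1), numeric(0))
  # the ceiling is 1/L: accepted at exactly 1/L, rejected above it
  expect_length(periodic_train(1000, 0, 0.01, 1e-3), 10)
  expect_error(periodic_train(1100, 0, 1, 1e-3),
               class = "capsim_validation_error")
})

test_that("poisson trains are seeded, dead-time separated, and censored at the expected rate", {
  t1 <- poisson_train(20, 10, seed = 3)
  t2 <- poisson_train(20, 10, seed = 3)
  expect_identical(t1, t2)
  expect_false(identical(t1, poisson_train(20, 10, seed = 4)))
  expect_gte(min(diff(t1)), 1e-3)
  expect_identical(poisson_train(0, 10), numeric(0))
  # realised rate of the censored process: rate / (1 + rate * L)
  tt <- poisson_train(20, 100, refractory_s = 1e-3, seed = 1)
  expected_n <- 100 * 20 / (1 + 20 * 1e-3)
  expect_lt(abs(length(tt) - expected_n), 3 * sqrt(expected_n))
})

test_that("generators leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(poisson_train(20, 1, seed = 5))
  invisible(peak_times(c(0, 0.1), jitter_model(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("peak times trail thresholds by the configured plastic delay", {
  thr <- periodic_train(10, 0, 200)
  j <- jitter_model(peak_delay_mean_s = 2e-4, peak_delay_sd_s = 1e-4)
  pk <- peak_times(thr, j, seed = 8)
  d <- pk - thr
  expect_true(all(d > 0))
  expect_lt(abs(mean(d) - 2e-4), 3 * 1e-4 / sqrt(length(thr)))
  # zero dispersion collapses to a uniform shift
  j0 <- jitter_model(peak_delay_sd_s = 0)
  expect_equal(peak_times(thr, j0, seed = 8), thr + 2e-4)
  # a peak-timed marker is more dispersed than a threshold-timed one
  expect_gt(stats::sd(pk - thr), 0)
})

test_that("collision outcomes never diverge without jitter and degrade with it", {
  net <- hillock_network(3)
  j0 <- jitter_model(peak_delay_sd_s = 0)
  r0 <- timing_error_experiment(net, j0, n_reps = 6, rate_hz = 40,
                                t_end = 0.5, seed = 2)
  expect_identical(r0$divergence_rate, 0)
  jbig <- jitter_model(peak_delay_sd_s = 5e-4)
  rbig <- timing_error_experiment(net, jbig, n_reps = 6, rate_hz = 40,
                                  t_end = 0.5, seed = 2)
  expect_gt(rbig$divergence_rate, 0)
})
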