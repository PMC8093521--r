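test_that("build_retina wires n receptors onto one bipolar cell and one RGC", {
  net <- build_retina(retina_spec(12))
  expect_identical(sum(net$nodes$kind == "source"), 12L)
  expect_identical(nrow(net$neurites), 13L)
  expect_identical(validate_network(net), character(0))
  expect_identical(nrow(build_retina(retina_spec(1))$neurites), 2L)
  expect_identical(sum(build_retina(retina_spec(25))$nodes$kind == "source"), 25L)
  expect_error(retina_spec(0), class = "capsim_validation_error")
  expect_error(retina_spec(26), class = "capsim_validation_error")
  expect_error(retina_spec(2, c(150, 50)), class = "capsim_validation_error")
  expect_s3_class(retina_spec(2, c(150, 50), allow_any_frequency = TRUE),
                  "retina_spec")
})

test_that("intensity encodes affinely onto the discharge band", {
  expect_equal(encode_intensity(0), 2)
  expect_equal(encode_intensity(1), 100)
  expect_equal(encode_intensity(0.5), 51)
  expect_error(encode_intensity(1.2), class = "capsim_validation_error")
  expect_error(encode_intensity(0.5, 100, 2), class = "capsim_validation_error")
})

test_that("mean-sampling gaps measure refractory-end to next threshold", {
  expect_equal(mean_sampling_gap(c(0, 0.0014, 0.0029), 1e-3),
               c(0.4e-3, 0.5e-3))
  # saturated train at the ceiling: every gap is zero
  expect_equal(mean_sampling_gap(seq(0, 0.01, by = 1e-3), 1e-3),
               rep(0, 10))
  expect_error(mean_sampling_gap(c(0, 0.5e-3), 1e-3),
               class = "capsim_validation_error")
})

test_that("a single receptor passes straight through; silent receptors give no output", {
  sim <- simulate_retina(retina_spec(1), frequencies = 10, t_end = 1, seed = 2)
  tr_in <- sim$result$caps$origin_time_s
  expected <- sort(tr_in) + 2 * latency(0.003, 0.3)
  expect_equal(sim$rgc_train, expected[expected <= 1])

  silent <- simulate_retina(retina_spec(3), frequencies = c(0, 0, 0), t_end = 1)
  expect_identical(silent$rgc_train, numeric(0))
})

test_that("RGC output respects the refractory ceiling and permutation symmetry", {
  spec <- retina_spec(6)
  f <- c(20, 35, 50, 65, 80, 95)
  sim <- simulate_retina(spec, frequencies = f, t_end = 1.5, seed = 5)
  expect_lte(sim$mean_rate_hz, 1 / spec$refractory_s + 1e-9)
  expect_refractory_exclusion(sim$result, spec$refractory_s)

  # permuting which receptor carries which train leaves the output
  # unchanged: the bipolar gate sees the same pooled arrival stream
  net <- build_retina(spec)
  trains <- withr::with_seed(5, {
    u <- runif(6)
    lapply(seq_along(f), function(i) periodic_train(f[i], u[i] / f[i], 1.5))
  })
  ids <- paste0("r", 1:6)
  r1 <- simulate_caps(net, stats::setNames(trains, ids), 1.5)
  perm <- c(4, 1, 6, 2, 5, 3)
  r2 <- simulate_caps(net, stats::setNames(trains[perm], ids), 1.5)
  expect_equal(r1$output_trains$rgc, r2$output_trains$rgc)
})

test_that("RGC rate rises monotonically with common receptor frequency", {
  spec <- retina_spec(12)
  freqs <- c(5, 10, 20, 40, 80)
  rates <- vapply(freqs, function(f) {
    simulate_retina(spec, frequencies = rep(f, 12), t_end = 1.5,
                    seed = 7)$mean_rate_hz
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
  expect_lte(max(rates), 1 / spec$refractory_s + 1e-9)
})

test_that("gated mean sampling matches the dense-time oracle on a small group", {
  # downsized group so the lattice stays tractable: 5 receptors, 2 ms
  # neurites, 0.3 s horizon
  spec <- retina_spec(5, neurite_length_m = 0.0006)
  net <- build_retina(spec)
  f <- c(20, 30, 45, 60, 90)
  trains <- withr::with_seed(9, {
    u <- runif(5)
    stats::setNames(lapply(seq_along(f), function(i)
      quantise_train(periodic_train(f[i], u[i] / f[i], 0.3),
                     spec$refractory_s)), paste0("r", 1:5))
  })
  ev <- simulate_caps(net, trains, 0.3)
  or <- oracle_simulate(net, trains, 0.3)
  expect_trains_match(ev, or)
})

test_that("raising one receptor's frequency never lowers the RGC rate", {
  spec <- retina_spec(6)
  base <- c(10, 20, 30, 40, 50, 60)
  r0 <- simulate_retina(spec, frequencies = base, t_end = 1.5, seed = 11)
  up <- base; up[3] <- 80
  r1 <- simulate_retina(spec, frequencies = up, t_end = 1.5, seed = 11)
  expect_gte(r1$mean_rate_hz, r0$mean_rate_hz)
})
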