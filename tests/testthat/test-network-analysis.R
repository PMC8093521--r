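test_that("edge_lambda counts phase lengths and scales linearly with frequency", {
  net <- fig7d_network(1, 0.3)
  expect_equal(edge_lambda(net, 1)[["a_c"]], 3)
  expect_equal(edge_lambda(net, 2, "a_c")[["a_c"]], 6)
  # any edge at its own resonant frequency carries exactly one phase length
  e <- net$neurites[net$neurites$id == "h_e", ]
  f_res <- e$velocity_mps / e$length_m
  expect_equal(edge_lambda(net, f_res, "h_e")[["h_e"]], 1)
  withr::with_seed(4, {
    f <- runif(10, 0.2, 50)
    cc <- runif(10, 0.1, 4)
    for (i in seq_along(f))
      expect_equal(edge_lambda(net, f[i] * cc[i], "b_h")[["b_h"]],
                   cc[i] * edge_lambda(net, f[i], "b_h")[["b_h"]])
  })
  expect_error(edge_lambda(net, 0), class = "capsim_validation_error")
})

test_that("the two-input fixture pins its three printed relations", {
  net <- fig7d_network(1, 0.3)
  expect_identical(validate_network(net), character(0))
  expect_equal(edge_lambda(net, 1)[["a_c"]], 3)
  expect_equal(edge_lambda(net, 1)[["a_h"]] + edge_lambda(net, 1)[["h_e"]], 6)
  lat <- stats::setNames(latency(net$neurites$length_m,
                                 net$neurites$velocity_mps),
                         net$neurites$id)
  expect_equal(lat[["a_c"]] / (lat[["b_h"]] + lat[["h_e"]]), 0.5)
})

test_that("doubling input a doubles the in-transit counts on its routes", {
  net <- fig7d_network(1, 0.3)
  fr1 <- frequency_response(net, c(a = 1, b = 0))
  fr2 <- frequency_response(net, c(a = 2, b = 0))
  e1 <- stats::setNames(fr1$edges$in_transit, fr1$edges$neurite)
  e2 <- stats::setNames(fr2$edges$in_transit, fr2$edges$neurite)
  expect_equal(e1[["a_c"]], 3)
  expect_equal(e2[["a_c"]], 6)
  ae1 <- fr1$routes[fr1$routes$sink == "e", ]
  ae2 <- fr2$routes[fr2$routes$sink == "e", ]
  expect_equal(ae1$in_transit, 6)
  expect_equal(ae2$in_transit, 12)
  # silent drive gives silent outputs
  fr0 <- frequency_response(net, c(a = 0, b = 0))
  expect_true(all(fr0$sinks$frequency_hz == 0))
})

test_that("steady-state in-transit counts equal lambda, within one during transients", {
  net <- fig7d_network(1, 0.3)
  fr <- frequency_response(net, c(a = 1, b = 0))
  res <- fr$result
  lam <- edge_lambda(net, 1)
  for (tq in fr$steady_s + c(0.1, 0.9, 1.7, 2.3)) {
    expect_equal(in_transit_count(res, "a_c", tq), lam[["a_c"]])
    expect_equal(in_transit_count(res, "a_h", tq), lam[["a_h"]])
  }
  # once the edge has filled (t >= latency) the count stays within one
  # of lambda all the way through the nominal transient window
  lat_ac <- latency(net$neurites$length_m[1], 0.3)
  for (tq in seq(lat_ac + 0.05, fr$steady_s, by = 1.1))
    expect_lte(abs(in_transit_count(res, "a_c", tq) - lam[["a_c"]]), 1 + 1e-9)
})

test_that("frequency_response rejects a horizon shorter than the transient", {
  net <- fig7d_network(1, 0.3)
  expect_error(frequency_response(net, c(a = 1), t_end = 5),
               class = "capsim_config_error")
})

test_that("the input->output frequency map is replicable and probed for injectivity", {
  net <- fig7d_network(1, 0.3)
  grid <- expand.grid(a = c(1, 2), b = c(0, 1))
  probe <- uniqueness_probe(net, grid)
  expect_true(probe$replicable)
  # brute-force pairwise check against the probe's own verdict
  outs <- as.matrix(probe$mapping[, c("c", "d", "e")])
  ins <- as.matrix(grid)
  inj <- TRUE
  for (i in 1:(nrow(grid) - 1)) for (j in (i + 1):nrow(grid)) {
    if (any(ins[i, ] != ins[j, ]) && all(abs(outs[i, ] - outs[j, ]) <= 1e-9))
      inj <- FALSE
  }
  expect_identical(probe$injective, inj)
  # a collision-free network is injective: pure delays preserve frequency
  chain <- chain_network(c(1000, 1000))
  p2 <- uniqueness_probe(chain, data.frame(a = c(10, 20, 40)), t_end = 1)
  expect_true(p2$injective)
})
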