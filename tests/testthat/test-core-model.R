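test_that("latency and phase_length follow the refractory-distance arithmetic", {
  expect_equal(latency(0.003, 0.3), 0.01)
  expect_equal(latency(1, 1), 1)
  expect_equal(latency(0.006, 0.3), 0.02)
  expect_equal(phase_length(100, 0.3), 0.003)
  expect_equal(phase_length(1, 1), 1)
  expect_equal(phase_length(50, 0.3), 0.006)
  expect_error(latency(-1, 0.3), class = "capsim_validation_error")
  expect_error(latency(0.003, 0), class = "capsim_validation_error")
  expect_error(phase_length(0, 0.3), class = "capsim_validation_error")
})

test_that("phase_length is homogeneous of degree -1 in frequency", {
  withr::with_seed(7, {
    f <- runif(20, 0.1, 200)
    v <- runif(20, 0.01, 30)
    expect_equal(phase_length(2 * f, v), phase_length(f, v) / 2)
    expect_equal(latency(2 * v * 0.01, v), 2 * latency(v * 0.01, v))
  })
})

test_that("validate_network reports violations as data and is order-independent", {
  good <- chain_network()
  expect_identical(validate_network(good), character(0))

  missing <- cap_network(
    data.frame(id = c("a", "out"), kind = c("source", "sink")),
    data.frame(id = "a_x", from = "a", to = "ghost",
               length_m = 0.01, velocity_mps = 0.3))
  v <- validate_network(missing)
  expect_length(grep("a_x", v), 1)
  expect_match(v, "ghost")

  bad_sink <- cap_network(
    data.frame(id = c("a", "p", "out"),
               kind = c("source", "convergence", "sink")),
    data.frame(id = c("a_p", "p_out", "out_p"),
               from = c("a", "p", "out"), to = c("p", "out", "p"),
               length_m = 0.01, velocity_mps = 0.3))
  expect_true(any(grepl("sink has outgoing", validate_network(bad_sink))))

  # idempotent and stable under element permutation
  perm <- cap_network(missing$nodes[2:1, ], missing$neurites)
  expect_identical(sort(validate_network(missing)),
                   sort(validate_network(perm)))
  expect_identical(validate_network(missing), validate_network(missing))
})

test_that("cap_quantum and train validation enforce the refractory invariants", {
  q <- cap_quantum(0.01, 1e-3)
  expect_s3_class(q, "cap_quantum")
  expect_error(cap_quantum(-1), class = "capsim_validation_error")
  expect_error(cap_quantum(0, refractory_s = 0), class = "capsim_validation_error")

  expect_identical(validate_trains(list(a = c(0, 0.002, 0.004)), 1e-3),
                   character(0))
  expect_match(validate_trains(list(a = c(0, 0.0005)), 1e-3),
               "refractory")
  expect_match(validate_trains(list(a = c(0.01, 0.01)), 1e-3),
               "strictly increasing", all = FALSE)
})

test_that("hillock fixture has n converging axons and one output", {
  net <- hillock_network(3)
  expect_identical(validate_network(net), character(0))
  expect_identical(sum(net$nodes$kind == "source"), 3L)
  expect_identical(nrow(net$neurites), 4L)
})
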