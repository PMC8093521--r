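# The three canonical convergence scenarios: an in-phase pair fuses to
# one CAP; a third threshold arriving inside the refractory window is
# annulled; a third arriving after the window passes unhindered.

test_that("in-phase thresholds fuse to a single surviving CAP", {
  r <- resolve_convergence(data.frame(cap = c("i", "ii"),
                                      time_s = c(0.010, 0.010)),
                           refractory_s = 1e-3, fusion_tol_s = 1e-5)
  expect_identical(nrow(r$survivors), 1L)
  expect_equal(r$survivors$time_s, 0.010)
  expect_identical(r$records$outcome, "fused")
  expect_identical(r$records$participants, "i+ii")
  expect_identical(r$records$survivor, "i")
})

test_that("a slightly late third threshold is annulled by the fused pair", {
  r <- resolve_convergence(data.frame(cap = c("i", "ii", "iii"),
                                      time_s = c(0.010, 0.010, 0.0105)),
                           refractory_s = 1e-3, fusion_tol_s = 1e-5)
  expect_identical(nrow(r$survivors), 1L)
  expect_equal(r$survivors$time_s, 0.010)
  ann <- r$records[r$records$outcome == "annulled", ]
  expect_identical(ann$participants, "iii")
  expect_identical(ann$blocker, "i")
})

test_that("a third threshold after the refractory window passes", {
  r <- resolve_convergence(data.frame(cap = c("i", "ii", "iii"),
                                      time_s = c(0.010, 0.010, 0.0112)),
                           refractory_s = 1e-3, fusion_tol_s = 1e-5)
  expect_equal(r$survivors$time_s, c(0.010, 0.0112))
  expect_identical(r$records$outcome, c("fused", "passed"))
})

test_that("the refractory window is half-open: an arrival at exactly t+L passes", {
  r <- resolve_convergence(c(0.010, 0.011), refractory_s = 1e-3)
  expect_identical(nrow(r$survivors), 2L)
  r2 <- resolve_convergence(c(0.010, 0.011 - 1e-7), refractory_s = 1e-3)
  expect_identical(r2$records$outcome, c("passed", "annulled"))
})

test_that("resolve_convergence rejects unsorted input and bad tolerances", {
  expect_error(resolve_convergence(c(0.02, 0.01)),
               class = "capsim_validation_error")
  expect_error(resolve_convergence(c(0.01), refractory_s = 1e-3,
                                   fusion_tol_s = 1e-3),
               class = "capsim_config_error")
})

test_that("a collision-free chain is a pure delay", {
  net <- chain_network(c(1000, 1000))  # 1 ms + 1 ms
  res <- simulate_caps(net, list(a = 0), t_end = 0.1)
  expect_equal(res$output_trains$out, 0.002)
  expect_identical(collision_summary(res)[["annulled"]], 0L)
})

test_that("two equal-latency branches with identical trains fuse to one delayed train", {
  net <- hillock_network(2, length_m = 0.003)
  tr <- periodic_train(50, 0, 0.2)
  res <- simulate_caps(net, list(x1 = tr, x2 = tr), t_end = 0.5)
  expect_equal(res$output_trains$out, tr + 2 * latency(0.003, 0.3))
  cnt <- collision_summary(res)
  expect_identical(cnt[["fused"]], length(tr))
  expect_identical(cnt[["annulled"]], 0L)
})

test_that("identical inputs give bit-identical collision records", {
  net <- random_test_network(11)
  inp <- random_grid_inputs(net, 11)
  r1 <- simulate_caps(net, inp, 0.05)
  r2 <- simulate_caps(net, inp, 0.05)
  expect_identical(r1$collisions, r2$collisions)
  expect_identical(r1$output_trains, r2$output_trains)
})

test_that("refractory exclusion and conservation hold on random simulations", {
  for (seed in 1:8) {
    net <- random_test_network(seed)
    res <- simulate_caps(net, random_grid_inputs(net, seed), 0.05)
    expect_refractory_exclusion(res, net$refractory_s)
    expect_conservation(res, net)
    # causality: no output precedes the earliest input plus the
    # shortest edge latency
    first_in <- min(unlist(random_grid_inputs(net, seed)), Inf)
    lat_min <- min(latency(net$neurites$length_m, net$neurites$velocity_mps))
    for (tt in res$output_trains)
      if (length(tt)) expect_gte(min(tt), first_in + lat_min - 1e-12)
  }
})

test_that("adding an input train never perturbs outputs before its influence arrives", {
  for (seed in c(3, 5, 9)) {
    net <- random_test_network(seed)
    src <- net$nodes$id[net$nodes$kind == "source"]
    if (length(src) < 2) next
    inp <- random_grid_inputs(net, seed)
    base <- inp[-length(inp)]
    res0 <- simulate_caps(net, base, 0.05)
    res1 <- simulate_caps(net, inp, 0.05)
    extra_first <- min(inp[[length(inp)]], Inf)
    lat_min <- min(latency(net$neurites$length_m, net$neurites$velocity_mps))
    horizon <- extra_first + lat_min - 1e-12
    for (s in names(res0$output_trains)) {
      t0 <- res0$output_trains[[s]]
      t1 <- res1$output_trains[[s]]
      expect_identical(t0[t0 < horizon], t1[t1 < horizon])
    }
    expect_refractory_exclusion(res1, net$refractory_s)
  }
})

test_that("in_transit_count counts entered-but-not-exited thresholds", {
  net <- chain_network(c(3000, 1000))
  res <- simulate_caps(net, list(a = c(0, 0.001, 0.002)), t_end = 0.05)
  expect_equal(in_transit_count(res, "a_p", 0.0025), 3)
  expect_equal(in_transit_count(res, "a_p", 0.0035), 2)
  expect_equal(in_transit_count(res, "a_p", 0.05), 0)
  expect_error(in_transit_count(res, "nope", 0.001),
               class = "capsim_validation_error")
  expect_error(in_transit_count(res, "a_p", 1),
               class = "capsim_validation_error")
})
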