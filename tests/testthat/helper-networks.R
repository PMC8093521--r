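# Fixtures built in code: small networks, lattice-aligned drives, and
# invariant checkers shared across test files.

ORACLE_DT <- 1e-6

# Quantise a train to the lattice grid and re-enforce dead time on the
# grid, so the event-driven (continuous-time) and lattice (integer-
# step) engines see identical inputs and refractory boundaries are
# exact multiples of dt.
quantise_train <- function(times, refractory_s, dt = ORACLE_DT) {
  st <- unique(round(times / dt))
  Lst <- round(refractory_s / dt)
  keep <- integer(0)
  last <- -Inf
  for (s in st) {
    if (s - last >= Lst) { keep <- c(keep, s); last <- s }
  }
  keep * dt
}

# Simple source -> convergence -> sink chain with lattice-aligned
# latencies (given in whole microseconds).
chain_network <- function(lat_us = c(1000, 1000), velocity = 0.3,
                          refractory_s = 1e-3) {
  nodes <- data.frame(id = c("a", "p", "out"),
                      kind = c("source", "convergence", "sink"))
  neurites <- data.frame(id = c("a_p", "p_out"), from = c("a", "p"),
                         to = c("p", "out"),
                         length_m = lat_us * 1e-6 * velocity,
                         velocity_mps = velocity)
  cap_network(nodes, neurites, refractory_s)
}

# Random small network (<= 6 nodes): 1-3 sources feeding one or two
# cascaded convergences, terminating in 1-2 sinks.  Latencies are whole
# microseconds so the lattice oracle represents them exactly.
random_test_network <- function(seed, velocity = 0.3, refractory_s = 1e-3) {
  withr::with_seed(seed, {
    n_src <- sample(1:3, 1)
    n_conv <- if (n_src <= 2) sample(1:2, 1) else 1L
    n_sink <- sample(1:min(2L, 6L - n_src - n_conv), 1)
    src <- paste0("s", seq_len(n_src))
    conv <- paste0("c", seq_len(n_conv))
    snk <- paste0("k", seq_len(n_sink))
    from <- c(src, if (n_conv == 2) "c1", rep(conv[n_conv], n_sink))
    to <- c(rep("c1", n_src), if (n_conv == 2) "c2", snk)
    # with two convergences, optionally short-circuit a source into c2
    if (n_conv == 2 && runif(1) < 0.5) {
      from <- c(from, src[1])
      to <- c(to, "c2")
    }
    lat_us <- sample(500:2000, length(from), replace = TRUE)
    nodes <- data.frame(id = c(src, conv, snk),
                        kind = c(rep("source", n_src),
                                 rep("convergence", n_conv),
                                 rep("sink", n_sink)))
    neurites <- data.frame(id = paste0(from, "_", to, "_", seq_along(from)),
                           from = from, to = to,
                           length_m = lat_us * 1e-6 * velocity,
                           velocity_mps = velocity)
    cap_network(nodes, neurites, refractory_s)
  })
}

# Lattice-aligned Poisson drive for every source of a network.
random_grid_inputs <- function(network, seed, rate_hz = 250, t_end = 0.04) {
  src <- network$nodes$id[network$nodes$kind == "source"]
  stats::setNames(lapply(seq_along(src), function(i) {
    quantise_train(poisson_train(rate_hz, t_end, network$refractory_s,
                                 seed = seed * 37L + i),
                   network$refractory_s)
  }), src)
}

# Every output train must keep consecutive thresholds >= L - 1e-12 apart.
expect_refractory_exclusion <- function(result, refractory_s) {
  for (s in names(result$output_trains)) {
    tt <- result$output_trains[[s]]
    if (length(tt) >= 2)
      expect_gte(min(diff(tt)), refractory_s - 1e-12)
  }
}

# Threshold bookkeeping at every gated node: arrivals resolved by t_end
# must balance passed + annulled + fused participants.
expect_conservation <- function(result, network) {
  rec <- result$collisions
  gated <- network$nodes$id[network$nodes$kind != "source"]
  for (nd in gated) {
    arr <- 0L
    for (e in which(network$neurites$to == nd)) {
      tr <- result$transit[[network$neurites$id[e]]]
      arr <- arr + sum(tr$exit_s <= result$t_end)
    }
    r <- rec[rec$node == nd, , drop = FALSE]
    n_passed <- sum(r$outcome == "passed")
    n_ann <- sum(r$outcome == "annulled")
    n_fused <- sum(lengths(strsplit(r$participants[r$outcome == "fused"],
                                    "+", fixed = TRUE)))
    expect_identical(arr, n_passed + n_ann + n_fused)
  }
}

# Per-threshold agreement between two results, within slack seconds.
expect_trains_match <- function(res_a, res_b, slack = ORACLE_DT) {
  expect_identical(sort(names(res_a$output_trains)),
                   sort(names(res_b$output_trains)))
  for (s in names(res_a$output_trains)) {
    ta <- res_a$output_trains[[s]]
    tb <- res_b$output_trains[[s]]
    expect_identical(length(ta), length(tb))
    if (length(ta))
      expect_lte(max(abs(ta - tb)), slack + 1e-12)
  }
}
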