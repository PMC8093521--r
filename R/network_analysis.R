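# Phase-length (lambda) accounting on edges, the worked two-input /
# three-output network fixture, and input->output frequency
# transformation experiments.

#' Phase lengths fitting on a neurite
#'
#' `lambda = length / phase_length(f, v) = length * f / v`: the number
#' of inter-threshold distances that fit on the edge at drive frequency
#' `f`, which equals the steady-state count of CAPs simultaneously in
#' transit.  Doubling the frequency doubles lambda.  Counts within
#' 1e-9 of an integer are reported exactly.
#'
#' @param network A [cap_network()].
#' @param frequency_hz Drive frequency in hertz (> 0).
#' @param neurite Optional neurite id(s); default all.
#' @return Named numeric vector of lambda values.
#' @export
edge_lambda <- function(network, frequency_hz, neurite = NULL) {
  stopifnot(inherits(network, "cap_network"))
  if (!.is_number(frequency_hz) || frequency_hz <= 0)
    stop_validation("frequency_hz must be finite and > 0")
  ed <- network$neurites
  if (!is.null(neurite)) {
    unknown <- setdiff(neurite, ed$id)
    if (length(unknown))
      stop_validation("unknown neurite(s): ", paste(unknown, collapse = ", "))
    ed <- ed[match(neurite, ed$id), , drop = FALSE]
  }
  lam <- ed$length_m / phase_length(frequency_hz, ed$velocity_mps)
  near <- abs(lam - round(lam)) < 1e-9
  lam[near] <- round(lam[near])
  stats::setNames(lam, ed$id)
}

#' Two-input, three-output worked network fixture
#'
#' A straightened disordered feedforward network with sources `a`, `b`
#' and sinks `c`, `d`, `e` whose edge lengths are expressed in phase
#' lengths `lambda0 = velocity / base_frequency` of the baseline drive.
#' Three relations are pinned: the direct segment a->c is 3 phase
#' lengths (so 3 CAPs are in transit under steady baseline drive), the
#' route a->e totals 6 phase lengths, and the conduction time a->c is
#' half that of b->e.  The remaining geometry (one internal convergence
#' `h`; edges a->h and b->h of 2 lambda0; h->d of 2 lambda0; h->e of 4
#' lambda0) is a documented fixture choice.
#'
#' @param base_frequency_hz Baseline drive frequency (Hz), default 1.
#' @param velocity_mps Conduction velocity (m/s), default 0.3.
#' @param refractory_s Refractory duration L (s), default 1 ms.
#' @return A valid [cap_network()] with neurites `a_c`, `a_h`, `b_h`,
#'   `h_d`, `h_e`.
#' @examples
#' net <- fig7d_network()
#' edge_lambda(net, 1)          # a_c = 3
#' edge_lambda(net, 2, "a_c")   # doubles to 6
#' @export
fig7d_network <- function(base_frequency_hz = 1, velocity_mps = 0.3,
                          refractory_s = 1e-3) {
  lam0 <- phase_length(base_frequency_hz, velocity_mps)
  nodes <- data.frame(
    id = c("a", "b", "h", "c", "d", "e"),
    kind = c("source", "source", "convergence", "sink", "sink", "sink"),
    stringsAsFactors = FALSE)
  neurites <- data.frame(
    id = c("a_c", "a_h", "b_h", "h_d", "h_e"),
    from = c("a", "a", "b", "h", "h"),
    to = c("c", "h", "h", "d", "e"),
    length_m = lam0 * c(3, 2, 2, 2, 4),
    velocity_mps = velocity_mps,
    stringsAsFactors = FALSE)
  assert_network(cap_network(nodes, neurites, refractory_s))
}

# Topological order of node indices, or NULL when the graph has a cycle.
.topo_order <- function(ix) {
  n <- length(ix$node_id)
  indeg <- tabulate(ix$e_to, nbins = n)
  queue <- which(indeg == 0L)
  out <- integer()
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (e in which(ix$e_from == v)) {
      w <- ix$e_to[e]
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) queue <- c(queue, w)
    }
  }
  if (length(out) < n) NULL else out
}

# Longest source-to-sink latency (the transient horizon driver).
.longest_route_latency <- function(network) {
  ix <- .index_network(network)
  topo <- .topo_order(ix)
  if (is.null(topo))
    stop_config("network has a cycle; supply t_end and query_time explicitly")
  dist <- rep(-Inf, length(ix$node_id))
  dist[ix$kind == "source"] <- 0
  for (v in topo) {
    if (!is.finite(dist[v])) next
    for (e in which(ix$e_from == v))
      dist[ix$e_to[e]] <- max(dist[ix$e_to[e]], dist[v] + ix$e_lat[e])
  }
  m <- max(dist[ix$kind == "sink"], 0)
  if (!is.finite(m)) 0 else m
}

# All simple paths (as edge-index vectors) from one node to another.
.simple_paths <- function(ix, from_i, to_i) {
  paths <- list()
  walk <- function(v, edges_so_far, visited) {
    if (v == to_i) {
      paths[[length(paths) + 1L]] <<- edges_so_far
      return()
    }
    for (e in which(ix$e_from == v)) {
      w <- ix$e_to[e]
      if (w %in% visited) next
      walk(w, c(edges_so_far, e), c(visited, w))
    }
  }
  walk(from_i, integer(), from_i)
  paths
}

# Source nodes (by id) from which an edge is reachable.
.edge_upstream_sources <- function(ix) {
  n <- length(ix$node_id)
  reach <- matrix(FALSE, n, n)  # reach[s, v]: v reachable from s
  for (s in which(ix$kind == "source")) {
    seen <- s
    queue <- s
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      for (e in which(ix$e_from == v)) {
        w <- ix$e_to[e]
        if (!reach[s, w]) { reach[s, w] <- TRUE; queue <- c(queue, w) }
      }
    }
    reach[s, s] <- TRUE
  }
  lapply(seq_along(ix$edge_id), function(e)
    ix$node_id[which(ix$kind == "source" & reach[, ix$e_from[e]])])
}

#' Steady-state frequency response of a network
#'
#' Drives every source with a periodic train at its given frequency
#' (0 = silent), simulates, and reports per-edge and per-route
#' in-transit CAP counts at a post-transient query instant together
#' with per-sink output frequencies.  Steady state is taken as twice
#' the longest source-to-sink latency.
#'
#' @param network A valid acyclic [cap_network()].
#' @param input_frequencies Named numeric vector, one entry per source
#'   (missing sources are silent).
#' @param t_end Simulation horizon; defaults to the transient plus five
#'   periods of the slowest active drive.  Must exceed the transient.
#' @param query_time Instant at which in-transit counts are measured;
#'   defaults to the midpoint of the post-transient window.
#' @param random_phases Draw uniform random initial phases (seeded);
#'   default `FALSE` (deterministic phase 0, exact steady-state
#'   counts).
#' @param seed Integer seed for phase draws.
#' @param fusion_tol_s Fusion tolerance (s).
#' @return List with `edges` (data frame: neurite, lambda at the unique
#'   driving frequency when well defined, in-transit count), `routes`
#'   (per source->sink simple path: route, latency, lambda, in-transit
#'   count), `sinks` (output frequency per sink), `query_time_s`,
#'   `steady_s`, `t_end`, `collisions` (outcome counts) and `result`.
#' @export
frequency_response <- function(network, input_frequencies, t_end = NULL,
                               query_time = NULL, random_phases = FALSE,
                               seed = 1L, fusion_tol_s = 1e-5) {
  assert_network(network)
  ix <- .index_network(network)
  L <- network$refractory_s
  sources <- ix$node_id[ix$kind == "source"]
  if (is.null(names(input_frequencies)) ||
      !all(names(input_frequencies) %in% sources))
    stop_validation("input_frequencies must be named after source nodes")
  f <- stats::setNames(rep(0, length(sources)), sources)
  f[names(input_frequencies)] <- input_frequencies
  if (any(f < 0) || any(f > 1 / L + .refractory_eps))
    stop_validation("frequencies must lie in [0, 1/L]")
  steady <- 2 * .longest_route_latency(network)
  active <- f[f > 0]
  if (!length(active)) {
    t_end <- t_end %||% (steady + 1)
    query_time <- query_time %||% (steady + 0.5)
  } else {
    t_end <- t_end %||% (steady + 5 / min(active))
    if (t_end <= steady)
      stop_config("t_end must exceed the transient horizon (", format(steady), " s)")
    query_time <- query_time %||% (steady + 0.5 * (t_end - steady))
    if (query_time < steady || query_time > t_end)
      stop_config("query_time must lie in [steady, t_end]")
  }
  u <- if (random_phases) with_sim_seed(seed, runif(length(sources))) else
    rep(0, length(sources))
  trains <- stats::setNames(lapply(seq_along(sources), function(i) {
    if (f[i] == 0) return(numeric())
    periodic_train(f[i], u[i] / f[i], t_end, L)
  }), sources)
  res <- simulate_caps(network, trains, t_end, fusion_tol_s)

  up <- .edge_upstream_sources(ix)
  edges <- data.frame(
    neurite = ix$edge_id,
    lambda = vapply(seq_along(ix$edge_id), function(e) {
      drv <- up[[e]][f[up[[e]]] > 0]
      if (length(drv) == 1) edge_lambda(network, f[[drv]], ix$edge_id[e]) else NA_real_
    }, numeric(1)),
    in_transit = if (length(ix$edge_id))
      vapply(ix$edge_id, function(e) in_transit_count(res, e, query_time),
             numeric(1)) else numeric(),
    stringsAsFactors = FALSE)
  rownames(edges) <- NULL

  route_rows <- list()
  for (s in names(active)) {
    for (k in ix$node_id[ix$kind == "sink"]) {
      for (p in .simple_paths(ix, ix$idx[[s]], ix$idx[[k]])) {
        eids <- ix$edge_id[p]
        route_rows[[length(route_rows) + 1L]] <- data.frame(
          source = s, sink = k,
          route = paste(c(s, ix$node_id[ix$e_to[p]]), collapse = ">"),
          latency_s = sum(ix$e_lat[p]),
          lambda = sum(edge_lambda(network, f[[s]], eids)),
          in_transit = in_transit_count(res, eids, query_time),
          stringsAsFactors = FALSE)
      }
    }
  }
  routes <- if (length(route_rows)) do.call(rbind, route_rows) else
    data.frame(source = character(), sink = character(), route = character(),
               latency_s = numeric(), lambda = numeric(), in_transit = numeric())
  sinks <- data.frame(
    sink = names(res$output_trains),
    frequency_hz = vapply(names(res$output_trains), function(k)
      rgc_frequency(res, c(steady, t_end), k), numeric(1)),
    stringsAsFactors = FALSE)
  rownames(sinks) <- NULL
  list(edges = edges, routes = routes, sinks = sinks,
       query_time_s = query_time, steady_s = steady, t_end = t_end,
       collisions = collision_summary(res), result = res)
}

#' Injectivity and replicability of the input->output frequency map
#'
#' Evaluates [frequency_response()] over a finite grid of input
#' frequency tuples and reports whether distinct inputs give distinct
#' output tuples (a unique reference to the inputs) and whether a
#' same-seed re-run is identical.
#'
#' @param network A valid acyclic [cap_network()].
#' @param frequency_grid Data frame, one column per source, one row per
#'   input tuple (Hz).
#' @param t_end,seed,fusion_tol_s Passed to [frequency_response()].
#' @param tol_hz Output frequencies closer than this are considered
#'   equal.
#' @return List with `mapping` (inputs bound to sink-frequency
#'   outputs), `injective`, `replicable` and `collisions` (total
#'   outcome counts across the grid).
#' @export
uniqueness_probe <- function(network, frequency_grid, t_end = NULL,
                             seed = 1L, fusion_tol_s = 1e-5, tol_hz = 1e-9) {
  frequency_grid <- as.data.frame(frequency_grid)
  run_row <- function(i) {
    fr <- frequency_response(network,
                             stats::setNames(as.numeric(frequency_grid[i, ]),
                                             names(frequency_grid)),
                             t_end = t_end, seed = seed,
                             fusion_tol_s = fusion_tol_s)
    list(out = stats::setNames(fr$sinks$frequency_hz, fr$sinks$sink),
         coll = fr$collisions)
  }
  runs <- lapply(seq_len(nrow(frequency_grid)), run_row)
  outs <- do.call(rbind, lapply(runs, function(r) r$out))
  injective <- TRUE
  n <- nrow(frequency_grid)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      in_differ <- any(abs(as.numeric(frequency_grid[i, ]) -
                           as.numeric(frequency_grid[j, ])) > 0)
      out_same <- all(abs(outs[i, ] - outs[j, ]) <= tol_hz)
      if (in_differ && out_same) injective <- FALSE
    }
  }
  rerun <- run_row(1L)
  replicable <- identical(rerun$out, runs[[1L]]$out)
  list(mapping = cbind(frequency_grid,
                       as.data.frame(outs, optional = TRUE)),
       injective = injective, replicable = replicable,
       collisions = Reduce(`+`, lapply(runs, function(r) r$coll)))
}
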