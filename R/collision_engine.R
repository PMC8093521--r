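# Event-driven collision engine.
#
# CAPs are advanced edge-by-edge with delay length/velocity and resolved
# at every non-source node by a refractory gate.  The gate maintains the
# half-open blocking window [t_last, t_last + L) anchored at the last
# surviving threshold:
#   * an arrival within the fusion tolerance of the surviving threshold
#     FUSES into it (one survivor, earliest time kept);
#   * an arrival strictly inside the refractory window beyond the
#     tolerance is ANNULLED (removed entirely; its refractory does not
#     propagate);
#   * an arrival at or after the window end PASSES and opens a new
#     window.
# There is no global clock: events are ordered by a priority queue on
# arrival time with (time, node, insertion order) tie-breaking, so runs
# are bit-identical for identical inputs.

# ---- binary min-heap on (time, node, seq) -------------------------------

.heap_new <- function(n0 = 64L) {
  h <- new.env(parent = emptyenv())
  h$time <- numeric(n0); h$node <- integer(n0)
  h$cap <- integer(n0); h$seq <- integer(n0)
  h$n <- 0L; h$count <- 0L
  h
}

.heap_lt <- function(h, i, j) {
  if (h$time[i] != h$time[j]) return(h$time[i] < h$time[j])
  if (h$node[i] != h$node[j]) return(h$node[i] < h$node[j])
  h$seq[i] < h$seq[j]
}

.heap_swap <- function(h, i, j) {
  for (f in c("time", "node", "cap", "seq")) {
    tmp <- h[[f]][i]; h[[f]][i] <- h[[f]][j]; h[[f]][j] <- tmp
  }
}

.heap_push <- function(h, time, node, cap) {
  n <- h$n + 1L
  if (n > length(h$time)) {
    grow <- length(h$time)
    h$time <- c(h$time, numeric(grow))
    h$node <- c(h$node, integer(grow))
    h$cap <- c(h$cap, integer(grow))
    h$seq <- c(h$seq, integer(grow))
  }
  h$count <- h$count + 1L
  h$time[n] <- time; h$node[n] <- node; h$cap[n] <- cap; h$seq[n] <- h$count
  h$n <- n
  i <- n
  while (i > 1L) {
    p <- i %/% 2L
    if (.heap_lt(h, i, p)) { .heap_swap(h, i, p); i <- p } else break
  }
}

.heap_pop <- function(h) {
  out <- list(time = h$time[1L], node = h$node[1L], cap = h$cap[1L])
  .heap_swap(h, 1L, h$n)
  h$n <- h$n - 1L
  i <- 1L
  repeat {
    l <- 2L * i; r <- l + 1L; m <- i
    if (l <= h$n && .heap_lt(h, l, m)) m <- l
    if (r <= h$n && .heap_lt(h, r, m)) m <- r
    if (m == i) break
    .heap_swap(h, i, m); i <- m
  }
  out
}

# ---- refractory gate ----------------------------------------------------

# One gate per node.  Records are accumulated as lists of rows; a fusion
# group's record (fused if >= 2 participants, else passed) is emitted
# when the first arrival beyond the fusion tolerance closes the group.
.gate_new <- function(node, refractory_s, fusion_tol_s) {
  g <- new.env(parent = emptyenv())
  g$node <- node
  g$L <- refractory_s
  g$tol <- fusion_tol_s
  g$anchor <- -Inf
  g$survivor <- NA_character_
  g$group <- character()
  g$records <- list()
  g
}

.gate_close_group <- function(g) {
  if (!length(g$group)) return(invisible(g))
  outcome <- if (length(g$group) >= 2L) "fused" else "passed"
  g$records[[length(g$records) + 1L]] <- list(
    time_s = g$anchor, node = g$node, outcome = outcome,
    participants = paste(g$group, collapse = "+"),
    survivor = g$survivor, blocker = NA_character_)
  g$group <- character()
  invisible(g)
}

# Returns "fused", "annulled" or "passed" for one arrival; arrivals must
# be presented in non-decreasing time order.
.gate_arrival <- function(g, cap, time) {
  if (length(g$group) && time - g$anchor <= g$tol) {
    g$group <- c(g$group, cap)
    return("fused")
  }
  .gate_close_group(g)
  if (time < g$anchor + g$L - .refractory_eps) {
    g$records[[length(g$records) + 1L]] <- list(
      time_s = time, node = g$node, outcome = "annulled",
      participants = cap, survivor = NA_character_, blocker = g$survivor)
    return("annulled")
  }
  g$anchor <- time
  g$survivor <- cap
  g$group <- cap
  "passed"
}

.records_df <- function(rows) {
  if (!length(rows)) {
    return(data.frame(time_s = numeric(), node = character(),
                      outcome = character(), participants = character(),
                      survivor = character(), blocker = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    time_s = vapply(rows, function(r) r$time_s, numeric(1)),
    node = vapply(rows, function(r) r$node, character(1)),
    outcome = vapply(rows, function(r) r$outcome, character(1)),
    participants = vapply(rows, function(r) r$participants, character(1)),
    survivor = vapply(rows, function(r) r$survivor, character(1)),
    blocker = vapply(rows, function(r) r$blocker, character(1)),
    stringsAsFactors = FALSE)
}

#' Resolve one stream of CAP arrivals at a convergence
#'
#' Sweeps the arrivals in time order through the refractory gate and
#' reports, for every arrival, whether it fused with the current
#' surviving threshold, was annulled inside the refractory window, or
#' passed and opened a new window.  The window is half-open,
#' `[t_last, t_last + L)`: an arrival at exactly `t_last + L` passes,
#' because an ended refractory period has no further effect.
#'
#' @param arrivals Either a numeric vector of arrival times (seconds) or
#'   a data frame with columns `cap` (ids) and `time_s`, sorted by time.
#' @param refractory_s Refractory duration L in seconds.
#' @param fusion_tol_s Fusion tolerance: arrivals within this of the
#'   surviving threshold are treated as overlapping and fuse.  Must be
#'   `>= 0` and `< refractory_s`.  Default 10 microseconds, the upper
#'   end of the activation-threshold timing scale.
#' @return A list with `survivors` (data frame `cap`, `time_s`) and
#'   `records` (data frame `time_s`, `node`, `outcome`, `participants`,
#'   `survivor`, `blocker`).
#' @examples
#' # in-phase pair fuses; a third threshold 0.5 ms later is annulled
#' resolve_convergence(data.frame(cap = c("i", "ii", "iii"),
#'                                time_s = c(0.010, 0.010, 0.0105)),
#'                     refractory_s = 1e-3)
#' @export
resolve_convergence <- function(arrivals, refractory_s = 1e-3,
                                fusion_tol_s = 1e-5) {
  if (is.numeric(arrivals))
    arrivals <- data.frame(cap = paste0("cap", seq_along(arrivals)),
                           time_s = as.numeric(arrivals),
                           stringsAsFactors = FALSE)
  if (!is.data.frame(arrivals) || !all(c("cap", "time_s") %in% names(arrivals)))
    stop_validation("arrivals must be a numeric vector or a data frame with columns cap, time_s")
  if (!.is_number(refractory_s) || refractory_s <= 0)
    stop_validation("refractory_s must be finite and > 0")
  if (!.is_number(fusion_tol_s) || fusion_tol_s < 0 || fusion_tol_s >= refractory_s)
    stop_config("fusion_tol_s must satisfy 0 <= fusion_tol_s < refractory_s")
  if (is.unsorted(arrivals$time_s))
    stop_validation("arrivals must be sorted by time")
  g <- .gate_new("node", refractory_s, fusion_tol_s)
  for (i in seq_len(nrow(arrivals)))
    .gate_arrival(g, as.character(arrivals$cap[i]), arrivals$time_s[i])
  .gate_close_group(g)
  rec <- .records_df(g$records)
  surv <- rec[rec$outcome %in% c("fused", "passed"),
              c("survivor", "time_s")]
  names(surv) <- c("cap", "time_s")
  rownames(surv) <- NULL
  list(survivors = surv, records = rec)
}

# ---- event-driven simulation -------------------------------------------

#' Simulate CAP propagation through a network
#'
#' Every input threshold is advanced edge-by-edge with the neurite's
#' conduction latency; at every convergence (and sink) node the merged
#' arrival stream is resolved by the refractory gate (see
#' [resolve_convergence()]).  A surviving CAP is copied onto all
#' outgoing neurites of its node.  Thresholds still in transit at
#' `t_end` are dropped from the output trains but remain visible in the
#' transit log.
#'
#' @param network A valid [cap_network()].
#' @param inputs Named list of threshold-time vectors (seconds), one per
#'   source node.  Sources without an entry are silent.  Trains must be
#'   strictly increasing with gaps `>= L`.
#' @param t_end Simulation horizon in seconds (> 0).
#' @param fusion_tol_s Fusion tolerance in seconds (see
#'   [resolve_convergence()]).
#' @return An object of class `cap_sim_result`: list with
#'   `output_trains` (named list, one sorted time vector per sink),
#'   `collisions` (data frame of collision records, time-ordered),
#'   `transit` (per-neurite data frame `cap`, `entry_s`, `exit_s`),
#'   `caps` (registry of all CAP ids with origin), `t_end` and
#'   `parameters`.
#' @examples
#' net <- hillock_network(2)
#' simulate_caps(net, list(x1 = c(0, 0.01), x2 = c(0, 0.01)), t_end = 0.1)
#' @export
simulate_caps <- function(network, inputs, t_end, fusion_tol_s = 1e-5) {
  assert_network(network)
  L <- network$refractory_s
  if (!.is_number(t_end) || t_end <= 0)
    stop_validation("t_end must be finite and > 0")
  if (!.is_number(fusion_tol_s) || fusion_tol_s < 0 || fusion_tol_s >= L)
    stop_config("fusion_tol_s must satisfy 0 <= fusion_tol_s < refractory_s")
  ix <- .index_network(network)
  src_ids <- ix$node_id[ix$kind == "source"]
  if (length(inputs) && (is.null(names(inputs)) || !all(names(inputs) %in% src_ids)))
    stop_validation("inputs must be named after source nodes; unknown: ",
                    paste(setdiff(names(inputs), src_ids), collapse = ", "))
  assert_trains(inputs, L)

  n_nodes <- length(ix$node_id)
  gates <- lapply(seq_len(n_nodes), function(i)
    .gate_new(ix$node_id[i], L, fusion_tol_s))
  outputs <- stats::setNames(
    vector("list", sum(ix$kind == "sink")), ix$node_id[ix$kind == "sink"])
  for (s in names(outputs)) outputs[[s]] <- numeric()
  tr_entry <- lapply(seq_along(ix$edge_id), function(i) numeric())
  tr_exit <- lapply(seq_along(ix$edge_id), function(i) numeric())
  tr_cap <- lapply(seq_along(ix$edge_id), function(i) integer())

  cap_n <- 0L
  cap_origin <- character()
  cap_time <- numeric()

  h <- .heap_new()
  forward <- function(node_i, cap, time) {
    for (e in ix$outgoing[[node_i]]) {
      exit <- time + ix$e_lat[e]
      tr_entry[[e]][length(tr_entry[[e]]) + 1L] <<- time
      tr_exit[[e]][length(tr_exit[[e]]) + 1L] <<- exit
      tr_cap[[e]][length(tr_cap[[e]]) + 1L] <<- cap
      if (exit <= t_end) .heap_push(h, exit, ix$e_to[e], cap)
    }
  }

  # inject inputs: source nodes fire at their scheduled times and are
  # not gated (valid trains already satisfy the refractory separation)
  for (s in names(inputs)) {
    ni <- ix$idx[[s]]
    for (t0 in inputs[[s]]) {
      if (t0 > t_end) next
      cap_n <- cap_n + 1L
      cap_origin[cap_n] <- s
      cap_time[cap_n] <- t0
      forward(ni, cap_n, t0)
    }
  }

  while (h$n > 0L) {
    ev <- .heap_pop(h)
    g <- gates[[ev$node]]
    act <- .gate_arrival(g, as.character(ev$cap), ev$time)
    if (act == "passed") {
      kind <- ix$kind[ev$node]
      if (kind == "sink") {
        id <- ix$node_id[ev$node]
        outputs[[id]][length(outputs[[id]]) + 1L] <- ev$time
      }
      forward(ev$node, ev$cap, ev$time)
    }
  }
  for (g in gates) .gate_close_group(g)

  rows <- do.call(c, lapply(gates, function(g) g$records))
  rec <- .records_df(rows)
  if (nrow(rec)) {
    o <- order(rec$time_s, match(rec$node, ix$node_id))
    rec <- rec[o, , drop = FALSE]
    rownames(rec) <- NULL
  }
  transit <- stats::setNames(lapply(seq_along(ix$edge_id), function(e)
    data.frame(cap = tr_cap[[e]], entry_s = tr_entry[[e]],
               exit_s = tr_exit[[e]])), ix$edge_id)
  structure(list(
    output_trains = outputs,
    collisions = rec,
    transit = transit,
    caps = data.frame(cap = as.character(seq_len(cap_n)),
                      origin = cap_origin, origin_time_s = cap_time,
                      stringsAsFactors = FALSE),
    t_end = t_end,
    parameters = list(refractory_s = L, fusion_tol_s = fusion_tol_s,
                      engine = "event"),
    engine = "event"), class = "cap_sim_result")
}

#' @export
print.cap_sim_result <- function(x, ...) {
  cnt <- table(factor(x$collisions$outcome,
                      levels = c("fused", "annulled", "passed")))
  cat("<cap_sim_result> engine=", x$engine,
      " t_end=", format(x$t_end), " s\n", sep = "")
  cat("  sinks:", paste(sprintf("%s (%d)", names(x$output_trains),
                                vapply(x$output_trains, length, 1L)),
                        collapse = ", "), "\n")
  cat("  collisions: fused=", cnt[["fused"]], " annulled=", cnt[["annulled"]],
      " passed=", cnt[["passed"]], "\n", sep = "")
  invisible(x)
}

#' Count of fused / annulled / passed outcomes
#'
#' @param result A `cap_sim_result`.
#' @return Named integer vector with elements `fused`, `annulled`,
#'   `passed`.
#' @export
collision_summary <- function(result) {
  stopifnot(inherits(result, "cap_sim_result"))
  tab <- table(factor(result$collisions$outcome,
                      levels = c("fused", "annulled", "passed")))
  stats::setNames(as.integer(tab), names(tab))
}

#' CAPs in transit on a neurite at an instant
#'
#' A CAP is in transit on a neurite at time `t` when it has entered the
#' neurite (`entry <= t`) but not yet exited (`exit > t`).  Under steady
#' periodic drive at frequency f, the in-transit count on an edge equals
#' the number of phase lengths lambda that fit on it.
#'
#' @param result A `cap_sim_result`.
#' @param neurite Neurite id, or a vector of ids whose counts are
#'   summed (e.g. the edges of a route).
#' @param time_s Query instant(s), within `[0, t_end]`.
#' @return Integer count (vectorised over `time_s`).
#' @export
in_transit_count <- function(result, neurite, time_s) {
  stopifnot(inherits(result, "cap_sim_result"))
  unknown <- setdiff(neurite, names(result$transit))
  if (length(unknown))
    stop_validation("unknown neurite(s): ", paste(unknown, collapse = ", "))
  if (any(time_s < 0) || any(time_s > result$t_end))
    stop_validation("time_s must lie within the simulated horizon [0, t_end]")
  vapply(time_s, function(t) {
    sum(vapply(neurite, function(e) {
      tr <- result$transit[[e]]
      sum(tr$entry_s <= t & tr$exit_s > t)
    }, numeric(1)))
  }, numeric(1))
}
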