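#' Construct a CAP (computational action potential) quantum
#'
#' A CAP is the unit of phase ternary computation: an activation-threshold
#' instant followed by an absolute refractory window of duration `L`
#' during which the same membrane point cannot re-fire.  The three phases
#' of the ternary code are resting, threshold and refractory.
#'
#' @param threshold_time_s Time (seconds, >= 0) at which the activation
#'   threshold passes the reference point.
#' @param refractory_s Absolute refractory duration L in seconds (> 0).
#' @param id Opaque identifier; autogenerated when `NULL`.
#' @param lineage Character vector of ancestor CAP ids (fusion
#'   bookkeeping).
#' @return An object of class `cap_quantum`.
#' @examples
#' cap_quantum(0.01)
#' @export
cap_quantum <- function(threshold_time_s, refractory_s = 1e-3, id = NULL,
                        lineage = character()) {
  if (!.is_number(threshold_time_s) || threshold_time_s < 0)
    stop_validation("threshold_time_s must be a finite number >= 0")
  if (!.is_number(refractory_s) || refractory_s <= 0)
    stop_validation("refractory_s must be a finite number > 0")
  structure(
    list(id = id %||% paste0("cap-", format(threshold_time_s, digits = 12)),
         threshold_time_s = threshold_time_s,
         refractory_s = refractory_s,
         lineage = as.character(lineage)),
    class = "cap_quantum")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a neurite network model
#'
#' A network is a directed graph of nodes (`source`, `convergence`,
#' `sink`) joined by neurites, each with a physical length and a
#' conduction velocity.  All units are SI: metres, seconds, hertz.
#' The refractory duration L is a network-wide parameter; a neurite
#' column `refractory_s` may override it locally.
#'
#' The constructor checks structure (required columns, types) only;
#' [validate_network()] reports invariant violations as data so that
#' deliberately broken networks can still be represented and inspected.
#'
#' @param nodes Data frame with columns `id` (character, unique) and
#'   `kind` (one of `"source"`, `"convergence"`, `"sink"`).
#' @param neurites Data frame with columns `id`, `from`, `to`
#'   (node ids), `length_m` and `velocity_mps`.
#' @param refractory_s Network-wide refractory duration L in seconds.
#'   Default 1 ms, the absolute refractory period implied by a 100 Hz
#'   maximum discharge frequency.
#' @return An object of class `cap_network`.
#' @examples
#' net <- cap_network(
#'   nodes = data.frame(id = c("a", "p", "out"),
#'                      kind = c("source", "convergence", "sink")),
#'   neurites = data.frame(id = c("a_p", "p_out"),
#'                         from = c("a", "p"), to = c("p", "out"),
#'                         length_m = 0.003, velocity_mps = 0.3))
#' validate_network(net)
#' @export
cap_network <- function(nodes, neurites, refractory_s = 1e-3) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  neurites <- as.data.frame(neurites, stringsAsFactors = FALSE)
  need_n <- c("id", "kind")
  need_e <- c("id", "from", "to", "length_m", "velocity_mps")
  if (!all(need_n %in% names(nodes)))
    stop_validation("nodes must have columns: ", paste(need_n, collapse = ", "))
  if (nrow(neurites) > 0 && !all(need_e %in% names(neurites)))
    stop_validation("neurites must have columns: ", paste(need_e, collapse = ", "))
  for (cc in c("id", "kind")) nodes[[cc]] <- as.character(nodes[[cc]])
  if (nrow(neurites) > 0) {
    for (cc in c("id", "from", "to")) neurites[[cc]] <- as.character(neurites[[cc]])
    if (!"refractory_s" %in% names(neurites)) neurites$refractory_s <- NA_real_
  } else {
    neurites <- data.frame(id = character(), from = character(),
                           to = character(), length_m = numeric(),
                           velocity_mps = numeric(), refractory_s = numeric(),
                           stringsAsFactors = FALSE)
  }
  if (!.is_number(refractory_s) || refractory_s <= 0)
    stop_validation("refractory_s must be a finite number > 0")
  structure(list(nodes = nodes, neurites = neurites,
                 refractory_s = refractory_s),
            class = "cap_network")
}

#' @export
print.cap_network <- function(x, ...) {
  cat("<cap_network> ", nrow(x$nodes), " nodes (",
      sum(x$nodes$kind == "source"), " source, ",
      sum(x$nodes$kind == "convergence"), " convergence, ",
      sum(x$nodes$kind == "sink"), " sink), ",
      nrow(x$neurites), " neurites, L = ",
      format(x$refractory_s), " s\n", sep = "")
  invisible(x)
}

#' Conduction latency of a neurite
#'
#' Latency is the finite time information takes to travel a neurite:
#' `length / velocity`.
#'
#' @param length_m Neurite length in metres (> 0); vectorised.
#' @param velocity_mps Conduction velocity in metres/second (> 0).
#'   A typical unmyelinated CNS axon conducts at about 0.3 m/s.
#' @return Latency in seconds.
#' @examples
#' latency(0.003, 0.3)  # 0.01 s
#' @export
latency <- function(length_m, velocity_mps) {
  if (!is.numeric(length_m) || !is.numeric(velocity_mps) ||
      any(!is.finite(length_m)) || any(!is.finite(velocity_mps)) ||
      any(length_m <= 0) || any(velocity_mps <= 0))
    stop_validation("length_m and velocity_mps must be finite and > 0")
  length_m / velocity_mps
}

#' Phase length of a periodic CAP stream
#'
#' The phase length is the physical distance between two successive
#' activation thresholds travelling along a neurite:
#' `velocity / frequency`.  At 100 Hz and 0.3 m/s this is 0.003 m.
#'
#' @param frequency_hz Discharge frequency in hertz (> 0); vectorised.
#' @param velocity_mps Conduction velocity in metres/second (> 0).
#' @return Phase length in metres.
#' @examples
#' phase_length(100, 0.3)  # 0.003 m
#' @export
phase_length <- function(frequency_hz, velocity_mps) {
  if (!is.numeric(frequency_hz) || !is.numeric(velocity_mps) ||
      any(!is.finite(frequency_hz)) || any(!is.finite(velocity_mps)) ||
      any(frequency_hz <= 0) || any(velocity_mps <= 0))
    stop_validation("frequency_hz and velocity_mps must be finite and > 0")
  velocity_mps / frequency_hz
}

#' Validate a network model
#'
#' Checks every type invariant and returns the violations as a character
#' vector, one message per offending element; an empty vector means the
#' model is well formed.  Violations are data, not exceptions, so broken
#' models can be reported in full.
#'
#' @param network A [cap_network()].
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_network <- function(network) {
  if (!inherits(network, "cap_network"))
    stop_validation("network must be a cap_network")
  nodes <- network$nodes
  edges <- network$neurites
  v <- character()
  if (anyDuplicated(nodes$id))
    v <- c(v, paste0("duplicate node id(s): ",
                     paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")))
  if (nrow(edges) && anyDuplicated(edges$id))
    v <- c(v, paste0("duplicate neurite id(s): ",
                     paste(unique(edges$id[duplicated(edges$id)]), collapse = ", ")))
  bad_kind <- !nodes$kind %in% c("source", "convergence", "sink")
  for (id in nodes$id[bad_kind])
    v <- c(v, paste0("node '", id, "': unknown kind"))
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) {
      e <- edges[i, ]
      if (!e$from %in% nodes$id)
        v <- c(v, paste0("neurite '", e$id, "': from-node '", e$from, "' does not exist"))
      if (!e$to %in% nodes$id)
        v <- c(v, paste0("neurite '", e$id, "': to-node '", e$to, "' does not exist"))
      if (!is.finite(e$length_m) || e$length_m <= 0)
        v <- c(v, paste0("neurite '", e$id, "': length_m must be finite and > 0"))
      if (!is.finite(e$velocity_mps) || e$velocity_mps <= 0)
        v <- c(v, paste0("neurite '", e$id, "': velocity_mps must be finite and > 0"))
      if (!is.na(e$refractory_s) && e$refractory_s <= 0)
        v <- c(v, paste0("neurite '", e$id, "': refractory_s override must be > 0"))
    }
  }
  for (i in seq_len(nrow(nodes))) {
    nd <- nodes[i, ]
    n_in <- sum(edges$to == nd$id)
    n_out <- sum(edges$from == nd$id)
    if (nd$kind == "source" && n_in > 0)
      v <- c(v, paste0("node '", nd$id, "': source has incoming neurite(s)"))
    if (nd$kind == "sink" && n_out > 0)
      v <- c(v, paste0("node '", nd$id, "': sink has outgoing neurite(s)"))
    if (nd$kind == "convergence" && (n_in < 1 || n_out < 1))
      v <- c(v, paste0("node '", nd$id,
                       "': convergence must have >= 1 incoming and >= 1 outgoing neurite"))
  }
  v
}

# Stop (classed) if the network is invalid.
assert_network <- function(network) {
  v <- validate_network(network)
  if (length(v))
    stop_validation("invalid network:\n  ", paste(v, collapse = "\n  "))
  invisible(network)
}

#' Validate threshold trains
#'
#' A pulse train is the sequence of activation-threshold times observed
#' at one location.  Times must be strictly increasing and consecutive
#' times must be separated by at least the refractory duration L (a
#' membrane point cannot re-fire within L); separation is checked with a
#' 1e-12 s floating-point slack.
#'
#' @param trains Named list of numeric time vectors (seconds), one per
#'   location, or a single numeric vector.
#' @param refractory_s Refractory duration L in seconds, or `NULL` to
#'   skip the separation check.
#' @return Character vector of violation descriptions (possibly empty).
#' @export
validate_trains <- function(trains, refractory_s = NULL) {
  if (is.numeric(trains)) trains <- list(train = trains)
  v <- character()
  for (loc in names(trains)) {
    tt <- trains[[loc]]
    if (!is.numeric(tt))
      { v <- c(v, paste0("train '", loc, "': not numeric")); next }
    if (!length(tt)) next
    if (any(!is.finite(tt)) || any(tt < 0))
      v <- c(v, paste0("train '", loc, "': times must be finite and >= 0"))
    d <- diff(tt)
    if (any(d <= 0))
      v <- c(v, paste0("train '", loc, "': times must be strictly increasing"))
    if (!is.null(refractory_s) && any(d < refractory_s - .refractory_eps))
      v <- c(v, paste0("train '", loc, "': consecutive times closer than the refractory duration"))
  }
  v
}

assert_trains <- function(trains, refractory_s = NULL) {
  v <- validate_trains(trains, refractory_s)
  if (length(v))
    stop_validation("invalid train(s):\n  ", paste(v, collapse = "\n  "))
  invisible(trains)
}

#' Convergent axon-hillock fixture
#'
#' Builds the canonical collision fixture: `n_axons` source neurites of
#' equal length converging on a single hillock node, which continues
#' into one output axon.  Identical input trains therefore arrive in
#' phase at the hillock and fuse; offset trains are annulled or pass
#' depending on the offset relative to L.
#'
#' @param n_axons Number of converging input axons (>= 1).
#' @param length_m Length of each neurite in metres.
#' @param velocity_mps Conduction velocity (m/s).
#' @param refractory_s Refractory duration L (s).
#' @return A [cap_network()] with sources `x1..xn`, convergence `h` and
#'   sink `out`.
#' @export
hillock_network <- function(n_axons = 3, length_m = 0.003,
                            velocity_mps = 0.3, refractory_s = 1e-3) {
  if (!.is_count(n_axons) || n_axons < 1)
    stop_validation("n_axons must be a positive integer")
  src <- paste0("x", seq_len(n_axons))
  nodes <- data.frame(id = c(src, "h", "out"),
                      kind = c(rep("source", n_axons), "convergence", "sink"),
                      stringsAsFactors = FALSE)
  neurites <- data.frame(id = c(paste0(src, "_h"), "h_out"),
                         from = c(src, "h"), to = c(rep("h", n_axons), "out"),
                         length_m = length_m, velocity_mps = velocity_mps,
                         stringsAsFactors = FALSE)
  cap_network(nodes, neurites, refractory_s)
}

# Internal indexed view of a network used by the engines.
.index_network <- function(network) {
  nodes <- network$nodes
  edges <- network$neurites
  idx <- seq_len(nrow(nodes))
  names(idx) <- nodes$id
  e_from <- idx[edges$from]
  e_to <- idx[edges$to]
  e_lat <- if (nrow(edges)) latency(edges$length_m, edges$velocity_mps) else numeric()
  outgoing <- lapply(idx, function(i) which(e_from == i))
  list(node_id = nodes$id, kind = nodes$kind, idx = idx,
       edge_id = edges$id, e_from = unname(e_from), e_to = unname(e_to),
       e_lat = unname(e_lat), outgoing = outgoing)
}
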