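#' Brute-force dense-time lattice simulation (testing oracle)
#'
#' Ground-truth reference for [simulate_caps()]: each neurite is
#' discretised into a chain of membrane points with spacing
#' `velocity * dt`; a point fires when its upstream neighbour fired
#' `dt` earlier and the point is not within the refractory duration L
#' of its own last firing.  Network nodes are shared lattice points, so
#' collision outcomes (fusion within one step, annulment inside L,
#' passage after L) emerge from the local membrane rule alone rather
#' than from event bookkeeping.  Output trains agree with the
#' event-driven engine within one `dt` per threshold when neurite
#' latencies are (near-)multiples of `dt`.
#'
#' This is orders of magnitude slower than the event-driven engine and
#' exists to verify it; the time-stepping loop is compiled.
#'
#' @inheritParams simulate_caps
#' @param dt Lattice time step in seconds.  Must satisfy
#'   `dt <= fusion_tol_s / 10`.
#' @return A `cap_sim_result` with `engine = "oracle"`.  The collision
#'   log is empty (the lattice does not label outcomes); `node_fires`
#'   holds the firing times of every node.
#' @export
oracle_simulate <- function(network, inputs, t_end, dt = 1e-6,
                            fusion_tol_s = 1e-5) {
  assert_network(network)
  L <- network$refractory_s
  if (!.is_number(t_end) || t_end <= 0)
    stop_validation("t_end must be finite and > 0")
  if (!.is_number(dt) || dt <= 0)
    stop_config("dt must be finite and > 0")
  if (dt > fusion_tol_s / 10)
    stop_config("dt too coarse: need dt <= fusion_tol_s / 10")
  ix <- .index_network(network)
  src_ids <- ix$node_id[ix$kind == "source"]
  if (length(inputs) && (is.null(names(inputs)) || !all(names(inputs) %in% src_ids)))
    stop_validation("inputs must be named after source nodes")
  assert_trains(inputs, L)

  n_steps <- as.integer(ceiling(t_end / dt))
  L_steps <- as.integer(round(L / dt))
  edge_steps <- as.integer(round(ix$e_lat / dt))
  input_steps <- lapply(ix$node_id, function(id) {
    tt <- inputs[[id]]
    if (is.null(tt)) return(integer())
    st <- unique(as.integer(round(tt / dt)))
    st[st <= n_steps]
  })
  fires <- oracle_lattice_cpp(as.integer(ix$e_from - 1L),
                              as.integer(ix$e_to - 1L),
                              edge_steps, length(ix$node_id),
                              input_steps, n_steps, L_steps)
  node_fires <- stats::setNames(lapply(fires, function(s) s * dt), ix$node_id)
  outputs <- node_fires[ix$kind == "sink"]
  transit <- stats::setNames(lapply(seq_along(ix$edge_id), function(e) {
    entry <- node_fires[[ix$e_from[e]]]
    data.frame(cap = seq_along(entry), entry_s = entry,
               exit_s = entry + edge_steps[e] * dt)
  }), ix$edge_id)
  structure(list(
    output_trains = outputs,
    collisions = .records_df(list()),
    transit = transit,
    node_fires = node_fires,
    t_end = t_end,
    parameters = list(refractory_s = L, fusion_tol_s = fusion_tol_s,
                      dt = dt, engine = "oracle"),
    engine = "oracle"), class = "cap_sim_result")
}
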