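# Retinal convergence circuit: grouped light receptors -> bipolar cell
# -> retinal ganglion cell (RGC), computing refractory-gated mean
# sampling at the bipolar point of computation.

#' Specification of a retinal convergence group
#'
#' One bipolar cell receives an average of 12 (up to 25) light
#' receptors; its discharge is observed at the RGC.  Receptor discharge
#' frequencies span 2-100 Hz; frequencies outside that band are
#' rejected unless explicitly allowed (silent receptors, frequency 0,
#' are always allowed).
#'
#' @param n_receptors Receptors per bipolar group, in `[1, 25]`
#'   (default 12).
#' @param receptor_frequencies Optional numeric vector of per-receptor
#'   discharge frequencies (Hz), length `n_receptors`.
#' @param neurite_length_m Length of each receptor->bipolar neurite and
#'   of the bipolar->RGC relay (metres).  Default 3 mm: one refractory
#'   distance at 0.3 m/s and 100 Hz.
#' @param velocity_mps Conduction velocity (m/s), default 0.3 for small
#'   unmyelinated neurites.
#' @param refractory_s Refractory duration L (s), default 1 ms.
#' @param allow_any_frequency Permit positive frequencies outside
#'   2-100 Hz (the refractory ceiling `1/L` still applies at
#'   simulation time).
#' @return An object of class `retina_spec`.
#' @export
retina_spec <- function(n_receptors = 12, receptor_frequencies = NULL,
                        neurite_length_m = 0.003, velocity_mps = 0.3,
                        refractory_s = 1e-3, allow_any_frequency = FALSE) {
  if (!.is_count(n_receptors) || n_receptors < 1 || n_receptors > 25)
    stop_validation("n_receptors must be an integer in [1, 25]")
  if (!is.null(receptor_frequencies)) {
    f <- receptor_frequencies
    if (!is.numeric(f) || length(f) != n_receptors || any(!is.finite(f)) ||
        any(f < 0))
      stop_validation("receptor_frequencies must be ", n_receptors,
                      " finite values >= 0")
    if (!allow_any_frequency && any(f > 0 & (f < 2 | f > 100)))
      stop_validation("positive receptor frequencies must lie in [2, 100] Hz ",
                      "(set allow_any_frequency = TRUE to override)")
  }
  if (!.is_number(neurite_length_m) || neurite_length_m <= 0)
    stop_validation("neurite_length_m must be > 0")
  if (!.is_number(velocity_mps) || velocity_mps <= 0)
    stop_validation("velocity_mps must be > 0")
  if (!.is_number(refractory_s) || refractory_s <= 0)
    stop_validation("refractory_s must be > 0")
  structure(list(n_receptors = as.integer(n_receptors),
                 receptor_frequencies = receptor_frequencies,
                 neurite_length_m = neurite_length_m,
                 velocity_mps = velocity_mps,
                 refractory_s = refractory_s),
            class = "retina_spec")
}

#' Build the retinal convergence network
#'
#' `n` receptor sources (`r1..rn`) converge on one bipolar node (the
#' point of computation) which relays to a single RGC sink -- for 12
#' receptors, 13 neurites.  The bipolar->RGC synapse is modelled as a
#' pure relay with the same neurite geometry.
#'
#' @param spec A [retina_spec()].
#' @return A valid [cap_network()].
#' @export
build_retina <- function(spec) {
  stopifnot(inherits(spec, "retina_spec"))
  rec <- paste0("r", seq_len(spec$n_receptors))
  nodes <- data.frame(id = c(rec, "bipolar", "rgc"),
                      kind = c(rep("source", spec$n_receptors),
                               "convergence", "sink"),
                      stringsAsFactors = FALSE)
  neurites <- data.frame(id = c(paste0(rec, "_bipolar"), "bipolar_rgc"),
                         from = c(rec, "bipolar"),
                         to = c(rep("bipolar", spec$n_receptors), "rgc"),
                         length_m = spec$neurite_length_m,
                         velocity_mps = spec$velocity_mps,
                         stringsAsFactors = FALSE)
  net <- cap_network(nodes, neurites, spec$refractory_s)
  assert_network(net)
}

#' Map light intensity to receptor discharge frequency
#'
#' Light intensity and RGC output frequency are proportionally related;
#' the minimal transfer realising that is affine:
#' `f = f_min + intensity * (f_max - f_min)`.
#'
#' @param intensity Intensities in `[0, 1]` (vectorised).
#' @param f_min,f_max Frequency range in hertz (default 2-100, the
#'   measured bipolar discharge band).
#' @return Frequencies in hertz.
#' @examples
#' encode_intensity(c(0, 0.5, 1))
#' @export
encode_intensity <- function(intensity, f_min = 2, f_max = 100) {
  if (!is.numeric(intensity) || any(!is.finite(intensity)) ||
      any(intensity < 0) || any(intensity > 1))
    stop_validation("intensity must lie in [0, 1]")
  if (!.is_number(f_min) || !.is_number(f_max) || f_min >= f_max)
    stop_validation("need f_min < f_max")
  f_min + intensity * (f_max - f_min)
}

#' Mean-sampling gaps of an output train
#'
#' At the point of computation the first CAP's refractory period blocks
#' successors; the inter-threshold structure of the output therefore
#' depends only on the time from the end of each refractory period to
#' the next surviving activation threshold.  For consecutive output
#' times `(t_i, t_{i+1})` this gap is `t_{i+1} - (t_i + L)`, which is 0
#' for a train saturated at the ceiling frequency `1/L`.
#'
#' @param times Output threshold train (sorted, refractory-separated).
#' @param refractory_s Refractory duration L (s).
#' @return Numeric vector of gaps (seconds, all >= 0), length
#'   `length(times) - 1`.
#' @examples
#' mean_sampling_gap(c(0, 0.0014, 0.0029), 1e-3)
#' @export
mean_sampling_gap <- function(times, refractory_s = 1e-3) {
  assert_trains(list(train = times), refractory_s)
  if (length(times) < 2) return(numeric())
  pmax(diff(times) - refractory_s, 0)
}

#' Discharge frequency at a sink
#'
#' Threshold count inside the half-open window `(start, end]` divided
#' by the window length; an empty window gives 0.
#'
#' @param result A `cap_sim_result`.
#' @param window Numeric `c(start, end)` in seconds, within the
#'   simulated horizon.
#' @param sink Sink node id; may be omitted when the network has a
#'   single sink.
#' @return Frequency in hertz.
#' @export
rgc_frequency <- function(result, window, sink = NULL) {
  stopifnot(inherits(result, "cap_sim_result"))
  if (!is.numeric(window) || length(window) != 2 || diff(window) <= 0)
    stop_validation("window must be c(start, end) with end > start")
  if (window[2] > result$t_end + .refractory_eps)
    stop_validation("window exceeds the simulated horizon")
  if (is.null(sink)) {
    if (length(result$output_trains) != 1)
      stop_validation("several sinks present; name one")
    sink <- names(result$output_trains)
  }
  tt <- result$output_trains[[sink]]
  if (is.null(tt)) stop_validation("unknown sink '", sink, "'")
  sum(tt > window[1] & tt <= window[2]) / diff(window)
}

#' Simulate the retinal circuit
#'
#' Drives each receptor with a periodic train at its frequency and an
#' independently drawn uniform random initial phase in `[0, 1/f)`
#' (mean sampling requires desynchronised arrivals), runs the
#' event-driven engine, and summarises the RGC output.
#'
#' @param spec A [retina_spec()] with `receptor_frequencies` set, or
#'   frequencies supplied via `frequencies`.
#' @param frequencies Optional per-receptor frequencies overriding the
#'   spec.
#' @param t_end Simulation horizon (s).
#' @param seed Integer seed for the phase draws.
#' @param fusion_tol_s Fusion tolerance (s).
#' @param random_phases Draw random phases (default); otherwise all
#'   phases are 0 (fully synchronised receptors).
#' @return List with `result` (the `cap_sim_result`), `rgc_train`,
#'   `mean_rate_hz` (over the post-transient window), `gaps`
#'   (mean-sampling gaps of the RGC train) and `window`.
#' @export
simulate_retina <- function(spec, frequencies = NULL, t_end = 2, seed = 1L,
                            fusion_tol_s = 1e-5, random_phases = TRUE) {
  stopifnot(inherits(spec, "retina_spec"))
  f <- frequencies %||% spec$receptor_frequencies
  if (is.null(f))
    stop_validation("receptor frequencies must be given in the spec or via 'frequencies'")
  if (length(f) != spec$n_receptors)
    stop_validation("need one frequency per receptor")
  net <- build_retina(spec)
  L <- spec$refractory_s
  u <- if (random_phases) with_sim_seed(seed, runif(spec$n_receptors)) else
    rep(0, spec$n_receptors)
  trains <- stats::setNames(lapply(seq_len(spec$n_receptors), function(i) {
    if (f[i] == 0) return(numeric())
    periodic_train(f[i], u[i] / f[i], t_end, L)
  }), paste0("r", seq_len(spec$n_receptors)))
  res <- simulate_caps(net, trains, t_end, fusion_tol_s)
  transient <- 2 * 2 * latency(spec$neurite_length_m, spec$velocity_mps)
  window <- c(min(transient, t_end / 2), t_end)
  rgc <- res$output_trains$rgc
  list(result = res,
       rgc_train = rgc,
       mean_rate_hz = rgc_frequency(res, window, "rgc"),
       gaps = if (length(rgc) >= 2) mean_sampling_gap(rgc, L) else numeric(),
       window = window)
}
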