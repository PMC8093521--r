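# Precision and ternary information calculus.

#' Phase digitisation scheme
#'
#' The refractory window behind a CAP threshold is subdivided into `k`
#' equal phase positions (default 12); each CAP carries one symbol of
#' the given base (default 3, the ternary resting / threshold /
#' refractory code).
#'
#' @param subdivisions Number of phase positions k (>= 1).
#' @param base Information base per impulse (>= 2).
#' @return An object of class `cap_digitisation`.
#' @export
digitisation_scheme <- function(subdivisions = 12, base = 3) {
  if (!.is_count(subdivisions) || subdivisions < 1)
    stop_validation("subdivisions must be a positive integer")
  if (!.is_count(base) || base < 2)
    stop_validation("base must be an integer >= 2")
  structure(list(subdivisions = as.integer(subdivisions),
                 base = as.integer(base)),
            class = "cap_digitisation")
}

#' Refractory distance and time at a maximum discharge frequency
#'
#' The maximum CAP frequency is set by the refractory period: at
#' maximum frequency `f_max` the distance from threshold activation to
#' the end of the refractory period is `velocity / f_max` and the time
#' is `1 / f_max`.  At 0.3 m/s and 100 Hz this gives 0.003 m and 1 ms,
#' matching the observed absolute refractory period.
#'
#' @param velocity_mps Conduction velocity in metres/second (> 0).
#' @param max_frequency_hz Maximum discharge frequency in hertz (> 0).
#' @return List with `distance_m` and `time_s`.
#' @examples
#' refractory_metrics(0.3, 100)
#' @export
refractory_metrics <- function(velocity_mps, max_frequency_hz) {
  if (!.is_number(velocity_mps) || velocity_mps <= 0 ||
      !.is_number(max_frequency_hz) || max_frequency_hz <= 0)
    stop_validation("velocity_mps and max_frequency_hz must be finite and > 0")
  list(distance_m = velocity_mps / max_frequency_hz,
       time_s = 1 / max_frequency_hz)
}

#' Phase position of a threshold offset within the refractory window
#'
#' A threshold arriving at offset `o` behind a blocking CAP's threshold
#' (with `0 <= o < L`) falls into phase bin `floor(o * k / L)`.  Bins
#' are half-open and left-closed, consistent with the half-open
#' refractory window of the collision engine.
#'
#' @param offset_s Offset behind the blocking threshold, in `[0, L)`.
#' @param refractory_s Refractory duration L in seconds.
#' @param scheme A [digitisation_scheme()].
#' @return Integer bin index in `[0, k - 1]` (vectorised over
#'   `offset_s`).
#' @export
phase_index <- function(offset_s, refractory_s = 1e-3,
                        scheme = digitisation_scheme()) {
  stopifnot(inherits(scheme, "cap_digitisation"))
  if (!is.numeric(offset_s) || any(!is.finite(offset_s)) ||
      any(offset_s < 0) || any(offset_s >= refractory_s))
    stop_validation("offset_s must lie in [0, refractory_s)")
  k <- scheme$subdivisions
  pmin(as.integer(floor(offset_s * k / refractory_s)), k - 1L)
}

#' Distinguishable states carried by a window of impulses
#'
#' `n` impulses each carrying one base-`b` symbol span `b^n`
#' distinguishable states: one impulse of base 3 conveys 3 states
#' (1 trit), the spacing of two successive impulses conveys base-9
#' information.
#'
#' @param n_impulses Number of impulses in the window (>= 0).
#' @param base Information base per impulse (>= 2).
#' @return State count `base ^ n_impulses`.
#' @examples
#' states_per_window(2, 3)  # 9
#' @export
states_per_window <- function(n_impulses, base = 3) {
  if (!.is_count(n_impulses))
    stop_validation("n_impulses must be a non-negative integer")
  if (!.is_count(base) || base < 2)
    stop_validation("base must be an integer >= 2")
  base^n_impulses
}

#' Information per impulse in trits
#'
#' `log3(base)`: exactly 1 for the ternary CAP, 2 for base 9.
#'
#' @param base Information base (>= 2).
#' @return Information content in trits (base-3 digits).
#' @examples
#' trits_per_impulse(3)  # 1
#' @export
trits_per_impulse <- function(base) {
  if (!.is_number(base) || base < 2)
    stop_validation("base must be >= 2")
  log(base) / log(3)
}

#' Digitisation report for a refractory window
#'
#' Derived precision quantities for one CAP refractory window under a
#' digitisation scheme: the width of one phase bin (`L / k`), the
#' refractory distance/time at the ceiling frequency, and two
#' information figures that the ternary model states side by side --
#' one trit per impulse from the base-3 code, and `log3(k)` trits if
#' all `k` phase positions (about 2.26 trits at k = 12) are counted as
#' distinguishable.  Both are reported; see the package vignette for
#' why they differ.
#'
#' @param scheme A [digitisation_scheme()].
#' @param refractory_s Refractory duration L (s).
#' @param velocity_mps Conduction velocity (m/s).
#' @return List of named quantities.
#' @export
digitisation_report <- function(scheme = digitisation_scheme(),
                                refractory_s = 1e-3, velocity_mps = 0.3) {
  stopifnot(inherits(scheme, "cap_digitisation"))
  rm_ <- refractory_metrics(velocity_mps, 1 / refractory_s)
  list(refractory_s = refractory_s,
       refractory_distance_m = rm_$distance_m,
       max_frequency_hz = 1 / refractory_s,
       bin_width_s = refractory_s / scheme$subdivisions,
       bin_width_m = rm_$distance_m / scheme$subdivisions,
       subdivisions = scheme$subdivisions,
       base = scheme$base,
       trits_per_impulse = trits_per_impulse(scheme$base),
       trits_per_window_positions = trits_per_impulse(scheme$subdivisions),
       states_two_impulses = states_per_window(2, scheme$base))
}
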