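# Seeded generators for input threshold trains, and the jitter model
# contrasting threshold-timed with peak-timed codes.

#' Periodic threshold train
#'
#' Times are `phase + k / frequency` for `k = 0, 1, ...` up to `t_end`.
#' The frequency must respect the refractory ceiling `1 / L` (100 Hz at
#' L = 1 ms); frequency 0 gives an empty train (a silent source).
#'
#' @param frequency_hz Discharge frequency in hertz, `0 <= f <= 1/L`.
#' @param phase_s Initial phase offset in seconds (>= 0).
#' @param t_end Horizon in seconds.
#' @param refractory_s Refractory duration L used for the feasibility
#'   check.
#' @return Numeric vector of threshold times.
#' @examples
#' periodic_train(10, 0, 1)   # 10 thresholds in 1 s
#' @export
periodic_train <- function(frequency_hz, phase_s = 0, t_end,
                           refractory_s = 1e-3) {
  if (!.is_number(frequency_hz) || frequency_hz < 0)
    stop_validation("frequency_hz must be finite and >= 0")
  if (frequency_hz == 0) return(numeric())
  if (frequency_hz > 1 / refractory_s + .refractory_eps)
    stop_validation("frequency_hz exceeds the refractory ceiling 1/L = ",
                    format(1 / refractory_s), " Hz")
  if (!.is_number(phase_s) || phase_s < 0)
    stop_validation("phase_s must be finite and >= 0")
  if (phase_s >= t_end) return(numeric())
  k_max <- floor((t_end - phase_s) * frequency_hz + 1e-9)
  tt <- phase_s + (0:k_max) / frequency_hz
  tt[tt < t_end]   # half-open horizon [0, t_end)
}

#' Dead-time censored Poisson threshold train
#'
#' Homogeneous Poisson arrivals thinned so that consecutive kept times
#' differ by at least the refractory duration L (non-paralysable dead
#' time).  The realised rate of the censored process has expectation
#' `rate / (1 + rate * L)`.  Deterministic for a fixed seed; the
#' caller's RNG state is untouched.
#'
#' @param rate_hz Underlying Poisson rate in hertz (>= 0).
#' @param t_end Horizon in seconds.
#' @param refractory_s Dead time L in seconds.
#' @param seed Integer seed.
#' @return Numeric vector of threshold times.
#' @export
poisson_train <- function(rate_hz, t_end, refractory_s = 1e-3, seed = 1L) {
  if (!.is_number(rate_hz) || rate_hz < 0)
    stop_validation("rate_hz must be finite and >= 0")
  if (rate_hz == 0 || t_end <= 0) return(numeric())
  raw <- with_sim_seed(seed, {
    acc <- numeric()
    t_last <- 0
    repeat {
      gaps <- rexp(max(64L, ceiling(rate_hz * t_end / 2)), rate_hz)
      acc <- c(acc, t_last + cumsum(gaps))
      t_last <- acc[length(acc)]
      if (t_last > t_end) break
    }
    acc[acc <= t_end]
  })
  .dead_time_thin(raw, refractory_s)
}

# Keep an arrival only if it is >= L after the last kept arrival.
.dead_time_thin <- function(times, refractory_s) {
  keep <- numeric(length(times))
  n <- 0L
  last <- -Inf
  for (t in times) {
    if (t - last >= refractory_s) {
      n <- n + 1L
      keep[n] <- t
      last <- t
    }
  }
  keep[seq_len(n)]
}

#' Spike-peak jitter model
#'
#' Contrasts the two candidate temporal fiducials of a nerve impulse.
#' The activation threshold is temporally stable; the spike peak trails
#' it by a positive, plastic delay (the peak shifts with firing
#' frequency and synaptic modulation while the threshold does not).
#' The delay is modelled lognormal -- positive support, right-skewed --
#' with moment-matched mean `peak_delay_mean_s` and standard deviation
#' `peak_delay_sd_s`.
#'
#' Defaults: mean delay 0.2 ms (the spike peak sits about 0.2 ms after
#' inception) and sd 0.1 ms (single spikes are not temporally reliable
#' below about 0.1 ms).
#'
#' @param threshold_sd_s Gaussian temporal dispersion of the threshold
#'   marker itself (seconds, >= 0; default 0: the threshold is the
#'   stable fiducial).
#' @param peak_delay_mean_s Mean threshold-to-peak delay (s, > 0).
#' @param peak_delay_sd_s Standard deviation of the delay (s, >= 0).
#' @return An object of class `cap_jitter`.
#' @export
jitter_model <- function(threshold_sd_s = 0, peak_delay_mean_s = 2e-4,
                         peak_delay_sd_s = 1e-4) {
  if (!.is_number(threshold_sd_s) || threshold_sd_s < 0)
    stop_validation("threshold_sd_s must be >= 0")
  if (!.is_number(peak_delay_mean_s) || peak_delay_mean_s <= 0)
    stop_validation("peak_delay_mean_s must be > 0")
  if (!.is_number(peak_delay_sd_s) || peak_delay_sd_s < 0)
    stop_validation("peak_delay_sd_s must be >= 0")
  structure(list(threshold_sd_s = threshold_sd_s,
                 peak_delay_mean_s = peak_delay_mean_s,
                 peak_delay_sd_s = peak_delay_sd_s),
            class = "cap_jitter")
}

# Lognormal meanlog/sdlog for a target mean m and sd s.
.lnorm_pars <- function(m, s) {
  if (s == 0) return(list(meanlog = log(m), sdlog = 0))
  sdlog <- sqrt(log(1 + (s / m)^2))
  list(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Spike-peak times for a threshold train
#'
#' Each threshold time receives Gaussian threshold jitter (sd
#' `threshold_sd_s`) plus a positive lognormal peak delay.  The result
#' is re-sorted, since large delay draws can reorder neighbouring
#' spikes.  The same seed draws the same underlying standard normals
#' whatever the sd parameters, so sweeps over jitter magnitude use
#' common random numbers.
#'
#' @param times Numeric vector of threshold times (seconds).
#' @param jitter A [jitter_model()].
#' @param seed Integer seed.
#' @return Sorted numeric vector of peak times.
#' @export
peak_times <- function(times, jitter = jitter_model(), seed = 1L) {
  stopifnot(inherits(jitter, "cap_jitter"))
  n <- length(times)
  if (!n) return(numeric())
  draws <- with_sim_seed(seed, list(zt = rnorm(n), zp = rnorm(n)))
  p <- .lnorm_pars(jitter$peak_delay_mean_s, jitter$peak_delay_sd_s)
  delay <- exp(p$meanlog + p$sdlog * draws$zp)
  sort(times + jitter$threshold_sd_s * draws$zt + delay)
}

#' Collision-outcome divergence of peak-timed vs threshold-timed codes
#'
#' Runs each replicate twice through [simulate_caps()]: once with the
#' generated threshold trains as the temporal markers, once with
#' jittered spike-peak trains (centred by subtracting the mean peak
#' delay, so a constant offset -- which shifts every collision
#' uniformly and cannot change an outcome -- is excluded and only the
#' plastic dispersion is compared).  Divergence per replicate is the
#' normalised L1 distance between the two runs' counts of fused /
#' annulled / passed outcomes; it is exactly 0 when all jitter sds are
#' 0.
#'
#' @param network A valid [cap_network()] with at least one convergence.
#' @param jitter A [jitter_model()].
#' @param n_reps Number of replicates.
#' @param rate_hz Poisson drive rate per source.
#' @param t_end Drive horizon in seconds (the simulation horizon is
#'   extended so no collision is truncated).
#' @param seed Integer seed; replicate r uses derived seed `seed + r`.
#' @param fusion_tol_s Fusion tolerance passed to the engine.
#' @return List with `divergence_rate` (mean over replicates),
#'   `per_rep` (data frame of outcome counts and divergence per
#'   replicate), and the parameters.
#' @export
timing_error_experiment <- function(network, jitter = jitter_model(),
                                    n_reps = 20, rate_hz = 50, t_end = 1,
                                    seed = 1L, fusion_tol_s = 1e-5) {
  assert_network(network)
  stopifnot(inherits(jitter, "cap_jitter"))
  L <- network$refractory_s
  ix <- .index_network(network)
  sources <- ix$node_id[ix$kind == "source"]
  margin <- jitter$peak_delay_mean_s + 6 * max(jitter$peak_delay_sd_s,
                                               jitter$threshold_sd_s) + L
  t_sim <- t_end + margin + sum(ix$e_lat) + 10 * L
  rows <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    thr <- stats::setNames(lapply(seq_along(sources), function(i) {
      margin + poisson_train(rate_hz, t_end, L,
                             seed = (seed + r) * 131L + i)
    }), sources)
    pk <- stats::setNames(lapply(seq_along(sources), function(i) {
      p <- peak_times(thr[[i]], jitter, seed = (seed + r) * 977L + i)
      .dead_time_thin(sort(p - jitter$peak_delay_mean_s), L)
    }), sources)
    c1 <- collision_summary(simulate_caps(network, thr, t_sim, fusion_tol_s))
    c2 <- collision_summary(simulate_caps(network, pk, t_sim, fusion_tol_s))
    tot <- sum(c1) + sum(c2)
    rows[[r]] <- data.frame(
      rep = r,
      fused_thr = c1[["fused"]], annulled_thr = c1[["annulled"]],
      passed_thr = c1[["passed"]],
      fused_peak = c2[["fused"]], annulled_peak = c2[["annulled"]],
      passed_peak = c2[["passed"]],
      divergence = if (tot > 0) sum(abs(c1 - c2)) / tot else 0)
  }
  per_rep <- do.call(rbind, rows)
  list(divergence_rate = mean(per_rep$divergence),
       per_rep = per_rep,
       jitter = jitter,
       parameters = list(n_reps = n_reps, rate_hz = rate_hz, t_end = t_end,
                         seed = seed, fusion_tol_s = fusion_tol_s))
}

#' Divergence as a function of peak jitter magnitude
#'
#' Re-runs [timing_error_experiment()] for each value of
#' `peak_delay_sd_s` with identical seeds, so the sweep uses common
#' random numbers and isolates the effect of jitter magnitude.
#'
#' @param network A valid [cap_network()].
#' @param peak_delay_sds Numeric vector of peak-delay sds (seconds).
#' @param jitter Base [jitter_model()] supplying the other parameters.
#' @param ... Passed to [timing_error_experiment()].
#' @return Data frame with columns `peak_delay_sd_s` and `divergence`.
#' @export
divergence_sweep <- function(network, peak_delay_sds,
                             jitter = jitter_model(), ...) {
  rows <- lapply(peak_delay_sds, function(sd) {
    j <- jitter_model(threshold_sd_s = jitter$threshold_sd_s,
                      peak_delay_mean_s = jitter$peak_delay_mean_s,
                      peak_delay_sd_s = sd)
    data.frame(peak_delay_sd_s = sd,
               divergence = timing_error_experiment(network, j, ...)$divergence_rate)
  })
  do.call(rbind, rows)
}
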