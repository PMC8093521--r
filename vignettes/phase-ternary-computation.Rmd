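---
title: "Phase ternary computation with computational action potentials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase ternary computation with computational action potentials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capsim)
```

## The model

`capsim` simulates neural computation carried by *computational action
potentials* (CAPs).  A CAP is reduced to its two computationally
relevant events: the instant its activation threshold passes a membrane
point, and the absolute refractory window of duration $L$ that follows,
during which that point cannot re-fire.  Together with the resting
state these form a ternary phase code: resting, threshold, refractory.
The quantum is written $t\,(\text{base})$ — a temporal phase variable
carrying one symbol of a base (base 3 here).

CAPs travel along neurites at a fixed conduction velocity $v$, so a
neurite of length $\ell$ contributes a latency $\ell / v$.  There is no
global clock: timing in the network is set entirely by conduction
delays, which is why the engine is event-driven with a priority queue
on arrival time rather than stepped by a clock.

Computation happens where streams converge.  At a convergence node the
engine maintains a half-open blocking window $[t_{last}, t_{last}+L)$
anchored at the last surviving threshold:

* **fusion** — an arrival within the fusion tolerance $\varepsilon$ of
  the surviving threshold is treated as overlapping it; one CAP
  survives, keeping the earliest threshold time;
* **annulment** — an arrival beyond $\varepsilon$ but strictly inside
  the window is removed entirely (its refractory state does not
  propagate downstream);
* **passage** — an arrival at or after the window end survives and
  opens a new window.  The window is half-open because an ended
  refractory period has no residual effect.

A surviving CAP is copied onto every outgoing neurite of its node.
These three local rules are the whole computational mechanism; every
network-level behaviour in the package (mean sampling in the retina,
frequency transformation in the worked network) emerges from them.

## Parameters that matter

* `refractory_s` ($L$) — network-wide, per-neurite overridable; default
  1 ms, a textbook absolute refractory period for unmyelinated fibres.
  It is the dead time of every gate and the denominator of the
  digitisation calculus.
* `velocity_mps` ($v$) — default 0.3 m/s, the interferometrically
  measured conduction speed of small unmyelinated neurites.  The
  literature also contains much faster (25 m/s, squid) and slower
  (0.03 m/s) figures; the simulator takes $v$ as a parameter and does
  not arbitrate.
* `fusion_tol_s` ($\varepsilon$) — default 10 µs.  The sources describe
  fusion only as "thresholds overlapping"; 10 µs is the upper end of
  the activation-mechanism timing scale (1–10 µs), and the parameter is
  configurable.  It must satisfy $0 \le \varepsilon < L$.
* All units are SI throughout (seconds, metres, hertz); field names
  carry the unit suffix instead of unit-bearing types.

## Numerical choices

* **Boundary guard.**  Annulment requires
  $t < t_{last} + L - 10^{-12}\,\mathrm{s}$.  The $10^{-12}$ s slack is
  the same tolerance used by the refractory-exclusion invariant; it
  prevents floating-point rounding of summed latencies from flipping an
  exact-boundary passage into an annulment.  All times are well above
  this scale (µs and up).
* **Tie-breaking.**  Simultaneous events are processed in
  (time, node, insertion order) lexicographic order, so identical
  inputs give bit-identical collision logs.
* **Fused windows.**  The refractory window of a fused group is
  anchored at the earliest (surviving) threshold; the sources do not
  specify this, and anchoring at the survivor is the choice consistent
  with "one CAP continues".
* **Fan-out.**  A survivor is duplicated onto all outgoing neurites;
  nothing in the model restricts divergence.
* **Horizon.**  Thresholds still in transit at `t_end` are dropped
  from output trains but remain in the per-neurite transit log, so
  in-transit counts are exact at any queried instant within the
  horizon.
* **Cycles.**  The engine itself tolerates cyclic graphs (events are
  purely time-ordered); the transient analysis in
  `frequency_response()` needs a longest source-to-sink latency and
  therefore requires an acyclic network or an explicit horizon.

## The dense-time oracle

`oracle_simulate()` is a deliberately naive ground truth: every neurite
is discretised into membrane points spaced $v\,dt$ apart and a point
fires at step $s$ iff its upstream neighbour fired at $s-1$ and the
point is outside its own refractory window.  Nodes are shared lattice
points.  Collision outcomes are not bookkept — they emerge from the
local re-fire rule — which is exactly what makes the oracle an
independent check of the event-driven gate.  The time-stepping loop is
compiled (C++); at $dt = 1\,\mu s$ a pure-R loop would be unusable as a
test oracle.  Agreement is asserted per threshold within one $dt$.
Test fixtures quantise input times and latencies to the $dt$ grid so
that both engines see identical inputs and refractory boundaries are
exact; otherwise a collision gap within one $dt$ of $L$ could
legitimately resolve differently in the two time bases.

## The retinal model

`build_retina()` realises the canonical convergence circuit: $n$
grouped light receptors (average 12, up to 25 per bipolar cell) drive
one bipolar node — the point of computation — which relays to a retinal
ganglion cell (RGC).  Light intensity maps affinely onto the measured
2–100 Hz discharge band (`encode_intensity()`); the sources state only
a "corresponding" frequency change, so affine is the minimal
assumption and the map is pluggable.  Receptor trains are periodic with
independently drawn uniform random phases (seeded): the mean-sampling
argument requires desynchronised arrivals, and no phase distribution is
stated.  Hyperpolarising cone signalling is abstracted to threshold
trains — the computational claim concerns timing, not polarity — and
the bipolar→RGC synapse is a pure relay.

At the bipolar gate the first arriving CAP's refractory period blocks
all successors; the output inter-threshold interval is $L$ plus the gap
from refractory end to the next surviving threshold
(`mean_sampling_gap()`).  The output rate therefore reflects the pooled
receptor rate, censored by the dead time $L$ — this is the
"mean sampling" computation.  The sources give no closed formula for
the statistic, so the package reports the simulated rate and the gap
distribution and claims monotonicity (more light → higher pooled rate →
higher RGC rate), not equality with the arithmetic mean of receptor
frequencies.  Note that with $L = 1$ ms the hard ceiling on any train
is $1/L = 1000$ Hz; a pooled 12-receptor drive at 100 Hz each gates to
roughly 500 Hz, well above the 100 Hz physiological maximum of real
RGCs — the model reproduces the *direction* of the intensity–frequency
relation, not the measured band.

## Precision and information calculus

`refractory_metrics(v, f_max)` returns the refractory distance
$v/f_{max}$ and time $1/f_{max}$, which satisfy
$\text{distance} = v \times \text{time}$ by construction.  At
$v = 0.3$ m/s and $f_{max} = 100$ Hz this gives 3 mm and 10 ms.  The
source text prints the same distance with a companion time of 1 ms;
that pair is dimensionally inconsistent (3 mm at 0.3 m/s is 10 ms, and
a 1 ms window at 0.3 m/s spans 0.3 mm), and the package keeps the
consistent closed form rather than the printed figure.  The
discrepancy traces to using the observed ~1 ms absolute refractory
period alongside a 100 Hz ceiling: the two imply each other only at
$f_{max} = 1000$ Hz.

`phase_index()` digitises an offset inside the refractory window into
$k$ half-open bins (default $k = 12$); `states_per_window()` and
`trits_per_impulse()` give the ternary accounting ($3^n$ states for $n$
impulses; $\log_3 b$ trits per impulse).  The sources state both that
each of the 12 subdivisions codes one trit *and* that each neuron
conveys 1 trit per convergence interval; 12 distinguishable positions
would carry $\log_3 12 \approx 2.26$ trits.  `digitisation_report()`
exposes both readings side by side instead of resolving the tension.

## The worked two-input network

`fig7d_network()` pins the three printed relations of the worked
example: segment a→c is 3 phase lengths at the baseline frequency,
route a→e totals 6, and the conduction time a→c is half that of b→e.
The full topology is only partially specified in the source, so the
fixture documents its choices: one internal convergence `h`, edges
a→c (3 $\lambda_0$), a→h (2 $\lambda_0$), b→h (2 $\lambda_0$),
h→d (2 $\lambda_0$), h→e (4 $\lambda_0$), with
$\lambda_0 = v / f_{base}$.  "λ = 3 so there are 3 CAP" is interpreted
as the in-transit CAP count on the segment (a count, not a rate: at a
1 Hz drive, "3" cannot be hertz); sink discharge frequencies are
reported separately.  Under steady periodic drive the in-transit count
on an edge equals its λ exactly, and doubling the drive frequency
doubles it (3→6 on a→c, 6→12 along a→e).  The frequency-response
checks drive source `a` alone: with `b` active the shared segment h→e
carries both streams and the count is no longer a statement about
input `a`.

## The jitter experiment

The spike peak trails the activation threshold by a positive, plastic
delay: it shifts with firing frequency and synaptic modulation while
the threshold stays temporally fixed.  `jitter_model()` captures this
as a lognormal delay (positive support, right-skewed; no distribution
is stated in the sources) with moment-matched mean 0.2 ms — the
peak-from-inception figure — and default sd 0.1 ms, the scale below
which single spikes are not temporally reliable.
`timing_error_experiment()` simulates each replicate twice, once with
threshold markers and once with peak markers, and reports the
normalised L1 distance between the two collision-outcome count vectors.
Peak trains are centred by subtracting the mean delay first: a constant
offset shifts every collision uniformly and cannot change an outcome,
so the comparison isolates the plastic dispersion.  With zero jitter
the two runs are identical and the divergence is exactly 0; sweeps over
the peak-delay sd reuse the same underlying standard-normal draws
(common random numbers), so the sweep isolates magnitude.

## What the generators emulate — and what they do not

Periodic trains model steady receptor discharge; the dead-time censored
Poisson generator models irregular drive with the refractory constraint
(realised rate $r/(1 + rL)$).  Real photoreceptor output is neither
perfectly periodic nor Poisson, has adaptation, and retinal circuitry
contains centre–surround antagonism and amacrine inhibition that this
package deliberately omits.  Passing tests therefore show that the
collision calculus and its printed worked examples are internally
consistent and reproducible — not that the retina quantitatively
behaves this way.

## Problem sizes

The shipped tests run the event-driven engine on networks of up to 14
nodes with horizons of a few seconds, and the lattice oracle at
$dt = 1\,\mu s$ on 20 randomised networks of at most 6 nodes with
40 ms horizons plus a downsized 5-receptor retina at 0.3 s — sizes
chosen so the whole suite completes in about two minutes on one core
while still exercising thousands of collisions.

## Known limitations

* Antidromic (head-on) collision within a single fibre is out of scope;
  only convergence-node interference is modelled.
* Synaptic chemistry, graded potentials, myelination and membrane
  biophysics are absent by design: the package operates entirely at the
  level of threshold times and refractory windows.
* The uniqueness probe evaluates injectivity on a finite frequency
  grid; it is evidence, not proof, of a unique input→output reference.
* With heavy jitter the peak-marker trains must be re-thinned to
  respect the refractory separation, which itself contributes to
  divergence — deliberately so, since a physical membrane would impose
  the same constraint.
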