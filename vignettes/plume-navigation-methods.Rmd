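---
title: "Stochastic decision models for walking plume navigation: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic decision models for walking plume navigation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plumewalk)
```

This vignette is the package's own account of its models, the
numerical choices behind them, and what its synthetic-data experiments
do and do not demonstrate.

## The scientific problem

A walking fly tracking an odor source in a turbulent plume does not
experience a smooth gradient. Odor arrives as brief filaments — most
encounters last tens of milliseconds, separated by blanks whose
durations span orders of magnitude — and the location of the next
encounter is essentially unpredictable. The package models navigation
in this regime as a small set of stochastic decisions whose *rates*
are modulated by the recent timing of encounters, rather than as a
deterministic response to instantaneous concentration.

## Encounters and filtered signals

The perceived signal is the mean intensity in a small elliptical
"virtual antenna" ahead of the head (center 2.16 mm in front, semi-axes
0.77 mm x 0.23 mm, major axis perpendicular to the heading). Camera
shot noise makes the background Gaussian; an encounter is an excursion
above `mean + 2.5 sd` of that background. Both the onset and the
offset must persist for 50 ms — shorter excursions are dropped and
shorter dips are bridged — which suppresses false events while
counting well-separated pulses identically for any threshold between
2.0 and 3.5 sd.

Three running sensory variables are causal exponential filters with
timescale `tau = 2 s` and zero initial state:

* `W_freq` — the filtered onset train, reported in Hz (normalized by
  `1/tau`, so a steady onset rate maps to itself);
* `W_dur` — the filtered binary exposure, in seconds;
* `W_conc` — the filtered raw intensity.

One unit impulse is placed at the first step of each encounter. All
filters are linear and causal, and `mean(d)` equals total encounter
time over total time exactly — properties the test suite checks
directly.

## The saccade model

Reorientation happens in discrete saccades. Turn times follow a
Poisson process with base timescale `tau_T = 0.75 s` (optionally with
linear rate modulation by `W_freq` and `W_dur`, carried by inverse
timescales so "disabled" is exactly zero); magnitudes are folded
normal `|N(30, 10^2)|` degrees; between turns the heading performs
0.22 deg/step white jitter. The direction of each turn is upwind with
probability

`p_T(x) = 1 / (1 + exp(-alpha x))`.

**The sigmoid argument.** The filter feeding the sigmoid is the *raw*
exponential convolution of the onset train (unit jump per onset,
steady value `tau` times the onset rate), not the Hz-normalized
variant. The choice rescales the gain; we resolved it against the
model's published quantitative behavior: with `alpha = 0.242` on the
raw filter, the stationary mean reflected orientation at 3 Hz is about
24-25 degrees off upwind and the orientation-frequency slope over
0-3.5 Hz is 18-19 deg/Hz, both consistent with the reported values;
the normalized variant misses them by a factor of ~1.5. The analytic
cross-check is a 7-state birth-death chain on `theta+ in {0, 30, ...,
180}` (`turn_chain_stationary_mean()`), which the degenerate simulator
(zero magnitude spread and jitter) matches exactly.

**Turn semantics.** "Upwind" means the signed orientation change that
reduces the reflected orientation `theta+`; at exactly `theta+ = 0` or
`180` the direction is drawn uniformly (reflecting boundary). In the
likelihood each detected turn contributes one turn term at its
midpoint step; all other walking steps are straight terms. The
magnitude distribution (30 +- 10 deg) and jitter SD are measured
constants, not fitted parameters, so they drop out of the likelihood
maximization — the fitted parameters are the gain and the (inverse)
timescales, estimated by L-BFGS on 500 random 20% subsets of the
trajectories, with the per-subset distribution and its medians
reported.

## The stop and walk models

Walk-to-stop and stop-to-walk transitions are independent
inhomogeneous Poisson processes; three rate families compete for each
direction (last-encounter, accumulated-evidence, encounter-duration;
see `rate_model_spec()`). Conventions that the formulas leave open:

* time-since-encounter is `+Inf` before the first onset, so the rate
  starts at baseline;
* the accumulated-evidence filter is the raw convolution (unit jump
  per onset); the slope parameters absorb its scale;
* the likelihood is the per-step product form: every exposure step
  contributes `exp(-dt lambda)`, every transition contributes
  `dt lambda exp(-dt lambda)` at the first step of the new bout, and
  bouts censored by the end of a sequence contribute survival only.
  `dt lambda << 1` is asserted at fit time (warning above 0.5);
* the generative samplers decide the transition into step `i` with the
  rate at step `i`, exactly matching those event terms (the
  state-sequence sampler inverts the cumulative discrete hazard
  `-log(1 - dt lambda)` per bout, which is the exact inverse-CDF of
  per-step Bernoulli thinning);
* positivity is enforced structurally: the last-encounter model is
  parameterized by `(log lambda0, log lambda_peak, log 1/tau)`, so any
  admissible point has a positive rate everywhere.

Fits flag estimates within 5% (of the log-range) of a box bound; a
family that can only chase the data into a corner of its parameter
space is not a credible model, and the mismatched-family test
reproduces that diagnostic.

## Model comparison

`compare_models()` scores fitted families on held-out sequences by
held-out log-likelihood (the selection score), by the summed squared
deviation between model-generated and observed conditioned
time-to-transition survival curves, and by AIC/BIC. Two design points
matter:

* Conditioning starts (all onsets / isolated onsets / clump leaders /
  matched random times) are restricted to steps actually spent in the
  exposure state, for observed and simulated curves alike; clumps are
  3+ onsets within 1 s, isolation is a 1 s exclusion window, both
  configurable.
* Model curves are generated by thinning with *common random numbers*
  (seeded per train, not per model) and several repetitions, so
  identical models tie exactly and curve differences reflect the rate
  functions.

We initially selected by the curve discrepancy. On synthetic data the
wrong families' best fits mimic the conditioned curves almost exactly
(selection near chance between mimicking pairs), while held-out
log-likelihood identifies the generating family reliably — in our
replicate experiments, essentially always for the walk direction and
in well over 90% of replicates for the stop direction at moderate data
sizes. The discrepancy remains reported as the quantitative analog of
judging the panel curves by eye.

## The synthetic plume

The generator emulates the wind-tunnel arena (300 x 180 mm, source at
the origin, 150 mm/s mean flow, lateral jets switching at 10 1/s,
90 Hz frames on an 8-bit intensity scale): discrete odor packets are
emitted at a Poisson rate, advected downwind, displaced laterally by a
shared telegraph drift plus a per-packet straight transverse ray, and
rendered as Gaussian blobs with linearly growing radius and
power-law-diluting peak intensity, over Gaussian background noise.

The per-packet rays are the one mechanism beyond the simplest
coherent-ribbon picture: with only the shared meander the instantaneous
plume is a single filament and a navigating agent meets encounters at
well under 1 Hz; independent rays fill the cone with filaments, which
is what the imaged plume shows and what pushes the perceived statistics
toward the published regime.

Emission rate (40 1/s), growth rate (1.5 mm/s), initial radius (1 mm),
peak intensity (70), dilution exponent (0.7), emission jitter (7 mm),
ray speed SD (8 mm/s) and telegraph coupling (0.01) are calibration
constants fixed once against four criteria: centerline intermittency
20 mm downwind inside the imaged band (0.12-0.39; we land near 0.34),
monotone off-axis decay, encounter/blank durations spanning about two
decades at far-field points, and agent-perceived encounter statistics
near 200 ms / 4 Hz. The movie renderer rasterizes any window of the
analytic field; the agent simulator samples the field directly, so no
full-resolution movie is ever materialized.

**What the calibration cannot deliver.** The three published perceived
statistics — mean encounter duration ~200 ms, mean encounter frequency
~4 Hz, mean perceived intermittency ~0.11 — cannot hold jointly as
time averages: onset rate times mean duration *is* the experienced
intermittency, so 4 Hz x 200 ms would imply 80% odor exposure inside
the plume, irreconcilable with any intermittency below ~0.5. Our
agents perceive ~180 ms mean durations and an in-plume onset rate of
~1.8-2.2 Hz ("in plume" meaning positions whose intermittency-map
value is at least 0.05). We calibrated the duration to the published
center and report the frequency honestly; the published 4 Hz
presumably reflects a different, unstated functional of the encounter
train.

## The agent

Agents (walk 10.1 mm/s, instantaneous saccades, the antenna geometry
above) sample the field each step, add background noise, and register
an encounter onset after 50 ms of continuous above-threshold signal,
subject to a 100 ms refractory period; `d(t)` is the raw
above-threshold state. Stops, walks, and saccades are drawn from the
fitted models per step. Walls reflect the heading; arrival is first
entry into a 20 x 20 mm box at the source. Ablations replace one
encounter-modulated component with its ensemble average from a
reference run: constant stop/walk rates from exponential fits to the
reference bout durations, or a fixed upwind probability equal to the
reference's upwind-turn fraction. Occupancy maps use 1 mm bins,
exclude trajectories shorter than 5 s, slower than 2 mm/s on average,
or displacing less than 50 mm, and drop the front 20 mm from the
marginals.

## Problem sizes and other numerical choices

The packaged experiments use sizes chosen to make their estimators
comfortably accurate while staying desk-scale: 500 trajectories x 60 s
for turn-gain recovery (subset medians accurate to a few percent); 500
bout sequences x 60 s for the stop/walk recoveries; 16 x 120 s runs
per rate for the orientation-frequency slope; 500 agents x 60 s for
the perceived-encounter calibration; 50 replicates at 120 training /
150 held-out sequences for the model-selection experiment. The
Savitzky-Golay smoother uses order 4, window 9; angular velocity is
computed from the smoothed unit-circle components with the
better-conditioned quotient, never by differentiating the wrapped
angle; samples within half a window of a trace end are flagged
invalid. Power-law tails are fit by least squares on the empirical
survival function over the top 1.5 decades (binned-density fits are
visibly biased for heavy tails), reported in the density convention,
with a curvature diagnostic flagging non-power-law samples.

## Limitations

The plume generator reproduces the statistical regime of the imaged
plume, not its hydrodynamics: its centerline intermittency grows
(rather than decays) with distance as packets expand, its filaments
are straight rays rather than strained sheets, and its intensity scale
is only monotonically related to concentration. Passing recovery tests
show that the estimators are correct for data generated by the models
themselves; they cannot show that the models are the right description
of real flies. The per-timestep regression t-tests treat autocorrelated
samples as independent — the trajectory-level block bootstrap is
provided alongside for honest uncertainty.
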