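---
title: "Trajectory learning by mean shift plus homeostasis, and the companion population analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trajectory learning by mean shift plus homeostasis, and the companion population analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foragerl)
```

## The scientific problem

A central-place forager runs from a home port to a hidden target region and
back; when the target moves, the animal re-scales its trajectory over tens
of trials.  The same computational problem appears in a head-fixed joystick
task where a forelimb movement must place the joystick inside a hidden
radial band.  `foragerl` implements a minimal reinforcement-learning account
of this behavior — a generative trajectory model whose two scale parameters
are updated trial by trial by a *mean-shift-plus-homeostasis* (MeSH) rule —
together with models of how hippocampal synchronous population events (SPEs,
the calcium-imaging proxy for ripple-associated reactivation) could gate
that learning, and the population-imaging analyses used to characterize such
data (SPE detection and clustering, event-component loadings, place maps,
response reliability, peri-movement sorting, consensus linear decoding,
cross-day ROI matching).  Everything is exercised on synthetic data with
known ground truth.

## The trajectory model

A trial's movement is generated by two control signals sampled on a grid of
step `dt`:

* heading: a linear sweep across (-pi, pi] over the trial, offset by a
  per-trial heading `omega[i]`, plus smoothed Gaussian noise;
* speed: one (joystick) or two (arena) Gaussian bumps of width `sigma` at
  times `tau`, scaled by a per-trial gain `a[i]`, plus smoothed noise.

Path-integrating these signals yields, for the arena configuration (two
bumps at 1 s and 3 s of a 4-s trial, heading offset `pi`), an out-and-back
loop whose maximal radial excursion is exactly proportional to the gain.
The proportionality constant is computed numerically
(`amplitude_gain()`, about 0.94 position units per unit gain for the
default shape), so gains can be stated in amplitude units.  The equations
do not force the loop to close; at the default shape the endpoint misses
the origin by about 6% of the excursion, which the package reports as a
diagnostic and does not correct.

Per-trial parameters are sampled as `a[i] ~ N(A[i], sigma_a)` and
`omega[i] ~ N(Omega[i], sigma_omega)` and the policy means are updated by

```
A[i+1]     = A[i]     + alpha (a[i]     - A[i])     upsilon[i] - beta (a[i]     - A[0])
Omega[i+1] = Omega[i] + alpha (omega[i] - Omega[i]) upsilon[i] - beta (omega[i] - Omega[0])
```

where `upsilon[i]` is an exponentially smoothed local reward rate
(`lambda = 0.3`).  Two modeling readings deserve a note:

* **The reward rate includes the current trial.**  If `upsilon[i]` were
  computed before trial *i*'s outcome, the mean-shift term would have zero
  expectation (the executed value is sampled symmetrically around the
  policy) and the agent could not learn from reward at all.  Including the
  current outcome couples the shift to reward — rewarded executions drag
  the policy toward themselves with an extra weight `alpha * lambda` — and
  produces the observed gradual, bidirectional adaptation.
* **Heading arithmetic is circular.**  The heading update uses the signed
  circular difference and wraps `Omega` back into (-pi, pi], so policies
  near the seam (the arena default is `Omega0 = pi`, pointing the outward
  leg into the arena) behave continuously.

## Task environments

The arena is 75 x 75 cm with the port at the origin and the y axis pointing
inward.  The collection area is 20 x 14 cm around the port; the two hidden
18 x 14 cm target rectangles are centered 34 cm and 52 cm from the port.  A
trial is rewarded when any trajectory sample enters the active rectangle
(closed boundaries, single-sample entry suffices); the next trial arms 2 s
after the return to the collection area.  The joystick task rewards
contiguous occupancy (>= 100 ms) of a radial band, with reward delivered
1 s after the qualifying crossing and a 3.3-s inter-trial interval.  The
default bands, 4-6 mm and 8-10 mm, are configurable.

## Default parameters and what they were calibrated against

The defaults are the package's study conditions, chosen once:

| parameter | default | units | rationale |
|---|---|---|---|
| `dt` | 0.01 | s | resolves `sigma` (0.5 s arena, 0.15 s joystick) |
| trial duration | 4 (arena), 1.5 (joystick) | s | observed movement time scales |
| default amplitude | 34 | cm | the familiar near-target distance; the "default policy" is the overtrained behavior |
| `sigma_a` | 0.25 A0 | gain | trial-to-trial amplitude CV ~0.25 |
| `sigma_omega` | 0.15 | rad | keeps interception probability above 0.6 |
| `alpha` | 0.4 | /trial | adaptation over tens of trials, not single-trial jumps |
| `beta` | 0.01 | /trial | anchors the policy near its default without preventing adaptation |
| `lambda` | 0.3 | /trial | reward-rate memory of a few trials |
| noise | 0.15 rad, 2 units/s, 0.15-s smoothing | | small within-trajectory wiggle |

They were calibrated jointly against three qualitative targets of the task
regime — interception probability above 0.6 at the trained target, smooth
amplitude adaptation over tens of trials after a near-to-far switch, and
stable (non-drifting) performance within a block — and then frozen.  With
weak homeostasis (`beta` well below 0.01) the reward-gated tracking term
turns the policy into an unanchored random walk: block-one amplitude
drifts far above the target because interception anywhere along the path
imposes no overshoot penalty.  `beta = 0.01` is the smallest value that
keeps stable blocks stationary.

## Perturbation variants

SPE-timed inactivation is modeled as one of four modifications of the
update on ~30% catch trials: reversion to the default policy; failure to
register the reward (the update recomputed with the outcome forced
negative, which also corrupts the smoothed reward rate); a ten-fold
exaggerated increment; or an increment scaled into [0, 0.1] (default
0.05, the interval midpoint).

The perturbation study conditions the magnitude of the trial-to-trial
change in the policy *scaling parameter* on the previous trial's type
(unrewarded / rewarded / rewarded + laser).  Using the policy parameter —
"the change in trajectory parameters" — rather than the noisy executed
amplitude isolates the update itself; `conditional_deltas()` computes
both, and for measured data (where the policy is latent) the executed
amplitude is the only option.  Unrewarded-and-lasered trials are classified
as unrewarded.  Under the default-policy variant the expected pattern is:
large changes after unrewarded trials (reward normally stabilizes the
policy), small changes after rewarded trials, and unrewarded-sized changes
after rewarded + laser trials, with interception performance on
laser-following trials unchanged.  The laser and unrewarded conditions
differ truly by a few percent in this model, so with 15 sessions their
statistical indistinguishability is borderline by construction —
some simulated batches resolve the difference.

## Movement initiation

Self-initiated movement times are modeled by the hazard
`H(t) = g(t) / (1 - G(t))` built from a Gaussian latency density
`g(mean 3 s, s.d. 0.48 s)`: stepping through time and initiating when a
uniform draw falls below `H dt` reproduces `g` exactly (the package samples
the equivalent inverse-transform form, with a uniform jitter inside the
winning step; `dt = 0.002 s`).  The SPE gate is *latched*: initiation
additionally requires at least one SPE since the window start.  SPE times
come from an exponential (0.5 Hz) or empirical interval sampler; laser
windows thin SPEs to a fraction (default 0.25) and can add a rebound event
at laser offset (default probability 0.9).

The blockade-delay study (mean latency versus laser duration 0/1/2/4 s)
runs with the rebound channel disabled.  With a near-certain rebound, a
*short* laser ending before the hazard mass effectively schedules an early
SPE and opens the gate sooner than the baseline Poisson process — the
delay-versus-duration relation becomes non-monotone for reasons unrelated
to the blockade itself.  Disabling rebound isolates the quantity the sweep
is about; the rebound pathway is exercised separately.

## Fitting

`grid_search_fit()` simulates sessions at each point of a 5 x 5 grid
(`alpha` in {0.05, 0.1, 0.2, 0.4, 0.8}; `sigma_a` in {0.05, 0.1, 0.15,
0.2, 0.3} A0) and scores switch-aligned curves over offsets -10..+40
against an observed curve.  The default loss fits the mean-amplitude and
interception-probability curves jointly (each normalized by the observed
curve's variance); amplitude-only and s.e.m.-weighted variants are
available.  All grid cells share session seeds (common random numbers) so
neighboring losses are not washed out by independent simulation noise.

A parameter-recovery caveat, established with the package's own oracle:
the switch-aligned mean curves constrain approximately the *product*
`alpha * sigma_a` (adaptation speed), not each factor separately.  Cells
along that ridge — e.g. (0.4, 0.20 A0), (0.8, 0.15 A0), (0.2, 0.30 A0) —
produce amplitude curves within 1-2 cm and hit-rate curves within ~0.1 of
each other, below realization noise at 20 simulations per cell.  Exact
recovery of a generating interior pair as the argmin therefore happens in
only ~30% of repeat fits, although the recovered `alpha` is within one
grid step of the truth on average (the property the tests assert).  Users
should read the loss surface, not just the argmin.

## Synthetic data generator

Behavioral sessions lay the simulated trials on a continuous clock with
rest at the port (2-s re-arm plus up to 2 s extra, arena; 3.3-s ITI plus
sampled initiation latency, joystick) and place reward and laser flags on
the trace.  Neural sessions draw ROI spike trains as inhomogeneous Poisson
from Gaussian place fields (width 6 cm) with log-normal peak rates
(median 3 Hz, log-s.d. 1 — the heavy-tailed activation propensity) over a
0.1-Hz untuned background; SPEs are injected at ~0.5 Hz inside eligible
windows (within 2 s after trajectory stop, *retrospective*, arena; within
2 s before movement onset, *prospective*, joystick; or uniformly), each
recruiting one of three recurring ensembles of 20% of ROIs, with a 0.4-s
refractory separation so injected events remain individually resolvable.
dF/F is the spike train convolved with a 0.5-s single-exponential calcium
kernel plus Gaussian noise (s.d. 0.1).

What the generator does *not* emulate: photobleaching, motion artifacts,
source-extraction crosstalk, theta-timescale structure inside events, or
behaviorally heterogeneous field remapping.  Passing tests on this
generator show the analysis code recovers planted structure under its own
assumptions; they are not evidence about real imaging noise.

Positive-control regimes used by the validation studies (chosen to be
clearly decodable, not typical): place-map recovery uses a 1200-s
open-field coverage trace (an Ornstein-Uhlenbeck walk at ~12 cm/s, since
the task's stereotyped loops do not tile the arena) with 50 ROIs; decoding
uses 200 ROIs at median peak 10 Hz, log-s.d. 0.5, 900 s, 1-s bins, and
decodes *arena-centered* coordinates — the decoder is a pure linear map
with no intercept, so an uncentered target would force the population to
synthesize a constant offset.  Negative controls (background-only
activity, permuted decoder weights) are exercised alongside.

## Population analyses: conventions and numerical choices

* **SPE detection**: an ROI is *active* in a window if it has at least one
  inferred spike; the window is 200 ms with a 1-frame stride; events are
  local maxima of the active fraction at threshold 0.15 *of all imaged
  ROIs*, with non-maximum suppression at one window.  The detector sees
  every ROI the session recorded.
* **Clustering**: k-means (20 restarts) on binary participation vectors,
  k chosen by mean silhouette width on Euclidean distance.
* **Event-component loadings**: windows of +/-250 ms of dF/F around each
  event are concatenated and the leading principal component extracted;
  the ROI with the largest-magnitude weight is forced positive so loadings
  are reproducible; each event's loading is the mean projection of its
  window.
* **Place maps**: movement periods at >= 1 cm/s; 4-cm bins; bins entered
  fewer than 5 times masked; transient counts divided by occupancy
  seconds; NA-aware Gaussian smoothing (sigma = 4 cm, normalized
  convolution so masked bins neither leak nor shrink fields);
  max-normalized.
* **Reliability**: mean pairwise trial-to-trial Pearson correlation of the
  population vector in a sliding +/-250-ms window (an alternative per-ROI
  definition can be assembled from the same primitives); windows with
  constant activity yield NA with a warning.
* **Peri-movement sorting**: the cross-validated mode sorts by peak time
  on a random half of trials and applies the order to the held-out half;
  the hierarchical mode splits ROIs at the median session activity, then
  sorts by latency, falling back to a pure latency sort when activities
  tie numerically.
* **Consensus decoder**: each fold solves `W = pinv(F) K` (minimum-norm
  least squares) on a random subset of `P = 75` trials; the consensus is
  the element-wise mean over `N = 50` folds.  Rank-deficient folds are
  legitimate (the pseudoinverse is still defined) and are counted in a
  message.  The permuted-weights control shuffles unit assignment.
* **Cross-day matching**: Pearson correlation of registered footprints,
  greedy one-to-one assignment in descending order above `r = 0.8`.
* **Conditional deltas**: Kruskal-Wallis across the three prior-trial
  conditions on session means, Holm-corrected pairwise rank-sum tests; a
  fully tied table returns p = 1 by convention; heading deltas are
  circular.
* **Bootstrap PETHs**: `k` = number of catch trials; 1000 resamples of
  `k` catch and `k` control trials; 100-ms bins over 12 s; percentile 95%
  bands; significant spans are disjoint-band runs of >= 200 ms.

## Degenerate inputs and failure behavior

Empty trajectories, unknown target ids, occupancy shorter than a sample,
sub-11-sample traces, more than 20% flagged tracking samples, zero
attempts, fewer than 5 catch trials, fewer events than clusters, identical
participation vectors, zero-variance covariates and mismatched matrix
shapes all raise classed errors (`invalid_input`, `configuration_error`,
`schema_error`, `data_error`, `quality_error`) rather than propagating
NaNs.  Every stochastic operation takes a seed and is bitwise reproducible.

## Problem sizes

The validation studies use 15-20 sessions of 85-160 trials for the
behavioral claims, 10-20 synthetic imaging sessions for detection metrics,
10,000 draws for latency distribution checks, 5,000 draws per blockade
condition, 50 repeat fits for parameter recovery, and 50-200 null sessions
for the PETH calibration; these sizes put the Monte-Carlo error well below
each criterion's margin while keeping the full suite inside a coffee
break.

## Known limitations

* The reward rule ("interception anywhere along the path") imposes no
  overshoot cost, so very weak homeostasis lets the policy drift upward;
  conclusions about the `beta -> 0` limit should not be drawn from this
  implementation.
* Parameter recovery from switch-aligned means alone is ridge-limited (see
  *Fitting*); fitting richer statistics (trial-to-trial variance,
  hit-rate curves, both blocks) is the practical remedy.
* The joystick-task bands place the second target ~4 exploration s.d.
  away from the first, so unassisted band-two discovery is slow; the
  joystick simulations here characterize stable-block behavior, not
  band-switch learning.
* The laser-vs-unrewarded equivalence in the perturbation signature is a
  near-coincidence of this model's magnitudes, not a structural identity;
  at 15 sessions it resolves in some seed batches.
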