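---
title: "A time-varying state-space model of larval zebrafish schooling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A time-varying state-space model of larval zebrafish schooling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(loomschool)
```

## The model

Seven-day-old zebrafish larvae swim in discrete bouts and keep away from
their group mates: at each bout they tend to turn away from the eye that
carries more retinal occupancy. `loomschool` implements this visuomotor
policy together with a slow internal state that modulates its gain based on
recent visual experience, so that simulated groups reproduce
experience-dependent changes in group structure (animals pre-exposed to
high density subsequently swim closer together; removing all visual input
slowly restores the baseline).

The model has three tiers.

**Retinal occupancy.** A neighbor (or projected dot) of vertical
half-extent $H$ at distance $d$ subtends a vertical angle
$v = 2\,\arctan(H/d)$ (degrees). The visual field spans $\pm 165°$ around
the heading with a $30°$ blind zone behind the animal; height along the
body axis is taken constant, so each object contributes one occupancy
value at its center bearing (`per_object` mode, used by the simulator). A
`rasterized` mode discretizes the field on a $1°$ grid and gives each cell
to the nearest covering object, which corrects for mutual occlusion when
analyzing dense scenes; the raster resolution comfortably exceeds the
$5°$/$10°$ binning used in the turning analyses.

**Turning policy.** Per-object biases are combined across the two eyes
with weights $w_i = v_i / \sum v_i$ (the sum running over both eyes).
With a linear per-object response the probability of turning right
collapses to

$$p(\text{right}) \;=\; 0.5 + a\!\left[\sum_{\text{left}} v_i^2/\Sigma v
\;-\; \sum_{\text{right}} v_i^2/\Sigma v\right],$$

clamped to $[0,1]$ after summation. The slope is $a = 0.0104$ per degree
for a single agent responding to projected dots and $a = 0.00372$ for
interacting groups (both estimated from data in the source experiments).
`p_turn_right()` also evaluates an arbitrary tabulated bias curve;
`estimate_slope()` inverts the map from binned turning fractions, weighting
bins by their event counts because occupancy differences are very unevenly
populated in real data.

**Internal state.** Looming events — per-step increases in any single
object's occupancy — drive a leaky integrator

$$\tau \frac{ds}{dt} = s_{\text{rest}} - s(t) + r \cdot \mathrm{Input}(t),$$

with $\tau = 6$ h, $r = 13$, $s_{\text{rest}} = 0$. The effective policy
slope is $a' = a\,[1 - (s - s_{\text{start}})/D]$ with
$s_{\text{start}} = 0.6$ and $D = 0.19$ ($D = 0.1$ for the group
split/merge simulations, matching the stronger responses of that design).
Because $\tau$ vastly exceeds session durations the integrator operates in
its near-linear regime: minutes of high density raise $s$ roughly linearly,
and recovery without visual input follows the slow exponential decay.

### Conventions and numerical choices

* Positions in cm, headings in degrees counter-clockwise from the arena
  $+x$ axis, wrapped to $(-180°, 180°]$; positive bearings lie to the
  *left* of heading, and turning right means a negative heading change.
* An object at exactly $0°$ bearing is assigned to the right eye — a
  deterministic tie-break for a measure-zero event.
* Distances are measured center to center, matching the dot-stimulus
  definitions ("distance to dot center").
* $\mathrm{Input}(t)$ is in degrees per simulation step at
  $\Delta t = 1/50$ s, the unit against which $r = 13$ is calibrated; a
  `per_second_input` switch normalizes to degrees per second instead.
* The integrator is stepped by forward Euler (input changes every step);
  the closed-form constant-input solution is kept as a test oracle, and
  the two agree to well below $10^{-4}$ relative error over hours of
  simulated time at the default step.
* $s$ is clamped to $[s_{\text{rest}}, s_{\text{start}} + D]$, so the
  effective slope never reverses sign and is bounded above; the source
  experiments never exhibit response reversal.
* Looming inputs below $10^{-9}$ degrees per step are zeroed (a numerical
  dead-band), so geometrically loom-free stimuli produce exactly zero
  input rather than floating-point dust.

### Looming semantics

The default looming signal is *neighbor-induced*: the previous scene is
re-viewed from the agent's current pose, so occupancy changes caused by
the agent's own motion contribute nothing. This choice reproduces the
stationary-scene null result (a frozen dot field elicits no modulation,
however the agent moves) without any parameter adjustment; the raw,
as-experienced signal is retained as a configuration switch. Two further
boundary rules matter:

* an object newly added to the scene (e.g. a density switch) counts with
  its full occupancy as one loom event — a real onset on the retina;
* an object that was already in the scene but hidden in the blind zone
  emerges without looming. Without this rule, dots circling the agent on
  fixed rings would register large spurious looms each time they crossed
  the field edge, contradicting the design of the rotational control
  stimulus ("moving, not looming"). The blind zone is applied to looming
  detection as well as occupancy.

## The agent simulator

Agents are points with a heading. Each simulation step
($\Delta t = 1/50$ s):

1. **Perception** — occupancy profiles and the looming input are computed
   from the previous step's poses (a synchronous update, so agent order is
   irrelevant); group agents see each other with half-extent equal to the
   configured fish height, VR agents see the stimulus dots with their
   radii.
2. **Integration** — one Euler step of $s$, then the effective slope.
3. **Bouts** — a Bernoulli decision clock fires at
   `bout_rate * dt` per step (a discretized Poisson process at 1.64 Hz).
   Decisions arriving while a bout executes queue the next bout to start
   immediately afterwards. This keeps the *emergent* onset rate equal to
   the configured rate while every bout lasts its full 320 ms — with
   idle-only decisions the measured rate would fall short by the busy
   fraction of the bout cycle. At bout onset the heading rotates in full;
   the 0.1 cm displacement is spread linearly over the 320 ms; a step that
   would exit the 6.5 cm arena disc is truncated at the boundary and the
   bout's remaining displacement cancelled.

Turn direction comes from the wall rule or the policy: the probability of
a wall-avoidance turn is logistic in the distance to the wall (half-max at
1.25 body lengths, steepness 4 per body length) — a stand-in for the
empirical wall-response curves, anchored at the same 1.25 BL radius used
to exclude wall events from the turning analyses. Within 1.25 BL neighbors
are ignored. Turn magnitudes are drawn from an explicit mixture of forward
bouts ($|N(0°, 10°)|$) and turn bouts ($|N(35°, 15°)|$, weight 0.5); the
empirical magnitude distribution is not printed in the source material, so
all four numbers are configuration-exposed and the direction sign always
comes from the policy.

The per-step loop runs compiled (Rcpp); all randomness flows through R's
RNG, so a session is bitwise reproducible from its seed, and
`run_session()` emits trajectories, state traces (with looming input,
effective slope and nearest-neighbor distance per frame) and a bout log.
Density switches remove uniformly chosen agents or add agents at fresh
uniform positions (within 0.9 × arena diameter, the initial-placement
rule) whose states are drawn from a normal distribution fitted to the
current group's states.

## Stimulus generators and what they emulate

`surrogate_trajectories()` produces non-interacting bout-walkers with the
same bout kinematics and wall behavior as the agents (social slope and
integrator zeroed). They stand in for the pre-recorded fish trajectories
used in the original rig; they reproduce bout-level statistics but not the
repulsive spatial structure of real groups — which is irrelevant for
replay stimuli, where only the dot-to-focal geometry matters. Streams loop
when presented beyond their duration, restarting with a momentary
discontinuity exactly as the rig did.

The remaining generators reproduce each projection protocol: `replay`
(one 0.75 cm-radius dot per fish; a speed-up option downsamples frames),
`stationary` (one frozen frame), `rotational_rings` (19 dots at the modal
k-th nearest-neighbor distances of a source recording, advancing in
bout-like arcs with per-bout random direction — translation without loom),
`looming_hexagon` (19 fixed dots on a hexagonal lattice whose radii walk
between 0.075 and 0.9 cm — loom without translation; the size dynamics are
an explicit grow/shrink/hold Markov schedule with configurable rates,
standing in for resampled recorded angular-size traces), and the three
`single_dot` protocols (5 s tangential sweeps from ±75° to ±30° with the
printed radius/distance schedules). Focal-frame streams (rings, single
dot) are re-anchored to the agent's pose every step, mirroring closed-loop
VR; world-frame streams are not.

## Analysis procedures

`kinematics()` uses central differences; `detect_bouts()` thresholds a
5-frame boxcar-smoothed speed at 0.15 cm/s with a 100 ms refractory merge
(tracker settings are unpublished; these defaults are calibrated against
the simulator's ground-truth bout log, with the caveat that back-to-back
queued bouts merge into single detected episodes). `nn_series()` reports
per-frame and 60 s block nearest-neighbor distances in cm.
`shuffled_control()` mixes animals across recordings and circularly shifts
reused animals' time signatures. `turn_probability_map()` applies the
1.25 BL wall exclusion and the 5°/10° binning before slope estimation.
`apply_filters()` implements the immobility (>50% of frames, with
"immobile" operationalized as smoothed speed < 0.05 cm/s) and bout-rate
(<0.25 Hz) exclusions. `fit_recovery()` fits
$N(t) = N_\infty + (N_0 - N_\infty)e^{-t/\lambda}$ by Levenberg–Marquardt
least squares and reports both the first observation inside a ±5% band
around the pre-exposure baseline and the continuous band entry of the
fitted curve ("time to baseline" is otherwise undefined in the source
text).

## Protocol reproductions and problem sizes

`run_recovery_experiment()`, `run_exposure_experiment()`,
`run_stationary_experiment()` and `run_split_merge_experiment()` wrap the
study designs: 24 seeded repetitions per condition, 4 versus 19 virtual
neighbors, 20 min high-density exposure, and 20 min baseline/probe
measurement windows (matching the recording blocks of the original
experiments, with the first minute of each measured phase discarded as a
settling period). The recovery battery samples zero-neighbor durations of
0–80 min in 10 min steps; the exposure battery uses 5–40 min exposures of
a looped 5 min high-density segment, so all durations present the same
material. The split/merge battery acclimates groups for 30 min before
resizing — long enough for the state distribution to separate between
densities while keeping the full battery tractable; group controls run at
their target size throughout.

These scales are the package's defaults and are what the acceptance
script and the test suite execute end to end; the expected qualitative
outcomes (suppression after high density, monotone effect of exposure
time, the stationary null, the split/merge sign pattern, exponential
recovery) are asserted by `tests/testthat/test-acceptance.R` at the
tolerances stated there.

## Known limitations

* Agents are points: no body deformation, hydrodynamics, collisions, or
  3-D swimming, and no occlusion by the focal animal's own body.
* The wall-response function and the turn-magnitude distribution are
  explicit stand-ins (logistic; Gaussian mixture) for unpublished
  empirical curves — both parameterized in the configuration.
* The simulated nearest-neighbor modulation after high-density exposure is
  deeper than the corresponding real-fish effect, which stretches the
  simulated time-to-baseline relative to the reported recovery while
  preserving its exponential shape; see the acceptance outputs for the
  computed values.
* Bout timing across agents is fully independent; whether real fish
  suppress bouts while a neighbor moves is not modeled.
* `surrogate_trajectories()` matches individual kinematics, not group
  spatial statistics, of recorded fish.
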