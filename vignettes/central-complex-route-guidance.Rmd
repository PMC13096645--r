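---
title: "A lateralised familiarity model of insect route guidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A lateralised familiarity model of insect route guidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(routecx)
```

## The problem

Ants following a learned visual route can tell, from terrestrial scene
recognition alone, whether their goal lies to their left or to their right.
`routecx` implements a circuit-level account of how such *lateralised*
recognition signals — presumed to originate in the mushroom bodies (MB) — can
drive stable route following when they are fed into the insect central
complex (CX), the midline brain region that holds a compass estimate of the
current heading and compares it with a stored goal heading to steer.

The package simulates the closed loop

> steering exposes the agent to views → view familiarity (left/right) updates
> the goal heading → the goal/compass comparison steers,

and provides the in-silico experiments built on it (a directional-bias by
directional-noise robustness sweep, and a celestial-cue rotation
perturbation), together with the behavioural metrics used to quantify both
simulated and recorded paths and trackball traces.

## The circuit model

All three layers are discretised into `n_columns` angular columns (default
8, i.e. 45° per column), mirroring the columnar anatomy of the protocerebral
bridge (PB) and fan-shaped body (FB). All angles are degrees; positive turn
= clockwise/right.

**Compass (PB / Δ7).** The current heading $\theta$ is encoded as an
activity bump over columns with preferred directions $\phi_j = (j-1)\,
360/n$:
$$a_j = \max\!\big(0, \cos(\theta_{\mathrm{app}} - \phi_j)\big),$$
peak-normalised to 1, where $\theta_{\mathrm{app}} = \theta + k \cdot 360/n$
and $k$ is the integer column shift implementing a rotated celestial
reference (`celestial_rotation_cells()`; a 135° rotation is exactly $k = 3$
on the default grid). The heading is imposed, not self-sustained: the
EB↔PB ring-attractor recurrence is outside scope. A von-Mises-shaped kernel
is available as an alternative bump shape; any single-peaked symmetric
kernel supports the same behaviour. Decoding is by population vector, which
for the rectified cosine on an even grid is exact (the frequency-2 alias of
the kernel cancels over a half circle of columns); for the von-Mises kernel
it is exact only up to the aliased ±(n−1) harmonic.

**Goal field (FB / FBN).** Two per-hemisphere banks of sustained activity
whose sum encodes the allocentric goal heading. Each step both banks decay
by $1-\lambda$ (default $\lambda = 0.2$) and are charged by that side's
familiarity signal with the compass bump displaced by one column toward
that side's anatomical offset:
$$L \leftarrow (1-\lambda) L + f_L\, \mathrm{shift}(a, -1), \qquad
  R \leftarrow (1-\lambda) R + f_R\, \mathrm{shift}(a, +1).$$
The offsets mirror the ±45° lateral tuning of the self-motion inputs the
same circuitry integrates for path integration. A left signal that fires
when the body points *right* of the goal therefore writes goal activity
displaced back toward the goal, and symmetrically.

**Steering (PFL → LAL).** The combined goal field is compared against
laterally shifted copies of the compass bump,
$d_R = \langle L{+}R,\ \mathrm{shift}(a,+1)\rangle$,
$d_L = \langle L{+}R,\ \mathrm{shift}(a,-1)\rangle$, and the turn command is
$$\Delta\theta = g \cdot s \cdot \frac{d_R - d_L}{d_R + d_L + \varepsilon}
  + \eta, \qquad \eta \sim \mathcal{N}(0, \sigma_m^2),$$
capped at ±`turn_cap` (90°). The mass normalisation makes the dynamics
invariant to the goal field's absolute amplitude; $\varepsilon = 10^{-9}$
makes the empty-goal case pure motor noise.

**Familiarity input (MB stand-in).** Visual recognition is abstracted as an
orientation-tuned signal: the left signal peaks, on average, at
`directional_bias` $b$ degrees clockwise of the route direction (default
+45°), the right symmetrically at $-b$:
$$f_{\mathrm{side}} = A \exp\big(\kappa(\cos(\theta - c_{\mathrm{side}}) - 1)\big),
  \qquad c_L = r + b + \epsilon_L,\ c_R = r - b - \epsilon_R,$$
with fresh independent per-step shifts $\epsilon \sim \mathcal{N}(0,
\sigma_d^2)$ ("directional noise", default 10°), and values below
`threshold` (default 0.05) zeroed. $\kappa = 5$ gives a half-maximum width
of about ±30°, the "rapid decay away from the memorised gaze direction"
regime. With these defaults a uniformly oriented agent receives no signal
on either side over a fraction
$1 - \big(2b + 2\arccos(1 + \log(\mathrm{thr})/\kappa)\big)/360 \approx 0.38$
of orientations — the input is sporadic, though not absent more often than
present; we verify the empirical silent fraction against this closed form
rather than asserting any particular cut-off.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `n_columns` | 8 | — | 45°/column; makes 135° an exact 3-column shift |
| `decay` ($\lambda$) | 0.2 | /step | goal persistence; sets how fast old goals fade |
| `gain` | 1 | — | steering gain |
| `motor_noise_sd` | 10 | °/step | per-step turn noise |
| `turn_scale` | 60 | ° | turn at full lateralisation of the drive |
| `directional_bias` | +45 | ° | offset of the left familiarity peak |
| `directional_noise_sd` | 10 | ° | per-step tuning-curve jitter |
| `tuning_kappa` | 5 | — | tuning sharpness (half-width ≈ 30°) |
| `threshold` | 0.05 | — | familiarity floor (sporadic signalling) |

`turn_scale` deserves a note. The steering quotient is dimensionless, so a
degrees-per-unit-drive scale must be chosen. We calibrated it once against
the celestial-rotation dynamics: at onset the stored goal conflicts with
the shifted compass, but the incoming familiarity keeps writing fresh goal
activity that inflates the normalising denominator, so the mismatch drive
is diluted. At `turn_scale = 30` the onset veer does not separate from the
pre-onset baseline of segment turn angles; at 60 it does (roughly 30° vs a
14° baseline at the defaults), while the bias-regime and robustness
behaviour are unchanged. It is exposed in `circuit_config()`.

## The two experiments

**Bias × noise sweep** (`sweep_bias_noise()`). Each grid cell runs seeded
closed-loop trials (default 200 steps, started 90° off-route
with an empty goal field, so the goal must be acquired from familiarity
alone) and records the directional error: the absolute angle between the
start-to-end chord and the route. The test suite asserts the three regimes
along the bias axis at noise 10°: stable route following (< 30° mean error)
for $b = +45$°, stable *reversed* following (> 150°) for $b = -45$°, and a
labile zone at $b = 0$ whose mean error exceeds the positive-bias cell and
whose inter-seed SD exceeds both stable cells. It also asserts that the
$b=+45$ cell stays below 45° under doubled motor noise, $\lambda \in \{0.1,
0.5\}$, zero threshold, and $\kappa \in \{3, 8\}$.

**Celestial rotation** (`sun_rotation_experiment()`). A cohort (default 20
agents, 300 steps) retraces the route (agents start route-aligned); between
step 120 and 121 the compass bump is shifted 3 columns (135°). Paths are
discretised every 3 steps; bearings (relative to the route) and absolute
turn angles between successive segments are summarised as cohort mean ± SE,
aligned so the onset junction is index 0 — `rotation_step` must therefore
be a multiple of `segment_stride`, and the rotation is applied *between*
two segments so the index-0 turn angle compares a clean pre-rotation
segment with the first rotated one. `phase_report()` emits markers for the
five phases: pre-onset baseline, signed onset deflection (a left turn for a
+3-cell shift: the stored goal appears 135° counter-clockwise of the
apparent heading), first corrective-turn latency, meander window, and
restabilisation.

**Meander detection.** Per-step absolute turns are dominated by motor
noise, which hides the conflict phase entirely at step resolution; the
conflict is, however, clearly visible in the segment-level turn-angle
series, where its duration scales with $1/\lambda$ as the old goal trace
fades. `phase_report()` therefore detects the meander window on the
segment series: post-onset segment indices whose cohort-mean turn angle
exceeds the pre-onset segment baseline + 2 SD, chained from the onset with
a tolerance of two below-threshold segments, so isolated noise exceedances
far from the onset never qualify. The window is reported in steps.

## The synthetic-behaviour generators

`gen_trackball_cohort()` emulates open-loop trackball recordings of
individuals fixed in the 8 compass orientations on a familiar route: each
trace is a constant expected angular velocity whose sign points toward the
route (positive when the route is right of the body axis), with the
individual's fixed side bias taking over at the aligned and anti-aligned
orientations, plus AR(1) noise (coefficient 0.8 at 10 Hz) so traces are
behaviourally smooth rather than white. Defaults: 17 individuals, 12 s at
10 Hz, mean turn speed 20°/s, noise SD 10°/s (SNR 2). Ground-truth labels
travel with every dataset so sign recovery by the metrics pipeline can be
scored. `gen_unfamiliar_cohort()` breaks the orientation dependence
(random sign per trace) while keeping the side bias, emulating recordings
in unfamiliar surroundings. `gen_perturbed_path()` exports simulator runs
in the path-table format the metrics read.

What these generators do *not* emulate: visual scenes, view memories,
gait, trackball counter-rotation mechanics, or the noise spectrum of real
recordings. Passing the recovery tests therefore shows that the metrics
pipeline is correct and adequately powered under the stated SNR, not that
the model fits any particular recorded dataset.

## Behavioural metrics

* `turn_ratio()` — $(\mathrm{right}-\mathrm{left})/(\mathrm{right}+
  \mathrm{left})$ of the time-integrated absolute angular velocity. The
  integral is the exact integral of the piecewise-linear interpolant of the
  samples, split at interpolated zero crossings (equivalent to trapezoidal
  integration away from sign changes); verified against dense-grid
  quadrature.
* `preferred_side_proportion()` — fraction of turning time on the
  larger-time side, ties 0.5.
* `discretise_path()` — arc-length resampling at a fixed length (12 cm for
  digitised ant paths, 3 steps for simulated ones), trailing remainder
  discarded; per-segment bearings and per-junction absolute turn angles.
* `directional_error()` — |start→end chord bearing − goal|, in [0°, 180°].
* `circular_mean_se()` — population-vector circular mean, SE = circular SD
  /√n, with optional within-individual averaging first.
* `signed_rank_exact()` — exact one-sample Wilcoxon signed-rank p over all
  $2^n$ sign assignments (subset-sum dynamic programming; midranks for
  ties; zeros dropped; $n \le 25$). Six same-signed values give the exact
  one-sided p $1/64 = 0.015625$.

## Numerical and design choices

* Angles wrap to (−180°, 180°]; positive = clockwise/right.
* Turn-then-step kinematics: the turn is applied to the heading before the
  unit step is taken (the ordering is not observable in any reported
  metric, but must be fixed for reproducibility).
* Constant speed; steering only.
* Celestial rotations are quantised to whole columns
  (`round(deg / spacing)`), matching the discrete bump-shift
  implementation rather than a continuous remapping.
* Default trial start: heading = route + 90°, empty goal field — the agent
  must bootstrap the goal from familiarity; the rotation experiment starts
  route-aligned instead, since those agents are retracing an established
  route.
* Trial noise (two familiarity shifts and one motor draw per step) is
  drawn up front from the trial seed, making records bit-reproducible.
* Left and right directional-noise draws are independent (the weaker
  assumption; sharing a draw would correlate the two sides).
* Text IO writes 17 significant digits and parses with correctly-rounded
  `strtod`, so traces and paths round-trip bitwise.

## Problem sizes

The shipped tests and the acceptance script use: 50 seeds per sweep cell
for the regime comparisons (20 for the robustness variants), 200-step
trials, 20-agent 300-step cohorts for the rotation experiment, and 100
generator seeds (13,600 traces) for sign recovery — sizes at which every
comparison above is stable across base seeds on a desktop machine in well
under a minute.

## Known limitations

* The compass is imposed, not attractor-maintained; compass noise and
  drift are not modelled.
* Familiarity is a tuning-curve abstraction; there is no image memory, so
  nothing here speaks to how left/right view memories are acquired.
* One canonical circuit is implemented; hemisphere-specific goal banks
  with alternative wiring (bee path-integration-style vs fly
  travel-tracking-style layouts) are a possible extension, not included.
* The labile zero-bias regime is genuinely bimodal (agents commit to one
  of the two stable directions); its mean error and SD summarise a mixture
  and should be read as such.
* Statistical power computations for the signed-rank tests are out of
  scope.
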