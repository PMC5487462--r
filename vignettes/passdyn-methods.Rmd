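---
title: "Behavioral dynamics of pick-and-place pass decisions: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral dynamics of pick-and-place pass decisions: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(passdyn)
```

`passdyn` simulates a tabletop social pick-and-place task: on each trial an
object appears at one of five pickup locations on the agent's left, a target
appears at one of twenty locations on the right, and the agent reaches for
the object and then either transports it to the target or releases it on the
table for a partner to finish the trial. The package couples two
low-dimensional dynamical systems — goal-directed steering/velocity dynamics
for the hand, and a bistable action-selection system for the pass/no-pass
choice — and reproduces the characteristic empirical signatures of the task:
hysteresis of the pass transition across ascending and descending target
sweeps, curved movement paths produced by stereotyped initial movement
angles, and single-peaked velocity profiles with early peaks.

## The task space

The table is 1.50 m by 0.89 m. Grid coordinates live in a participant frame
whose origin is the agent's ready/start hand position, x increasing toward
the target side, y increasing away from the agent across the table. The five
pickup locations sit at x = -0.323 m with mean y positions of -1.4, 7.2,
15.8, 24.4 and 33 cm, and each carries a body-scaled label E/A in
{0.2, 0.4, 0.6, 0.8, 1.0}: the fraction of the agent's preferred comfortable
reach (`reach`, default 0.522 m, the empirical mean) at which it was placed.
The twenty targets sit at x = +1.037 m with y from -7 cm to +59.5 cm in
3.5 cm steps.

Two details are worth flagging.

* **Label versus coordinate.** The printed mean pickup spacing (8.6 cm) is
  not 20% of the mean reach, because reach was measured from the standing
  position, which the task description never localises. The package
  therefore keeps the E/A *label* (0.2..1.0) attached to each pickup for
  anything "action-scaled" while using the printed mean *coordinates* for
  geometry. `task_space(pickup_mode = "reach_scaled")` instead spaces
  pickups by `0.2 * reach` with a fixed standing offset.
* **Ready location.** The only documented constraint on the participant
  frame's position within the table is that all grid points fit on the
  table; the default `ready_table = c(0.35, 0.15)` m satisfies it with
  margin and is configurable.

A session is 600 trials in three blocks of 200. In the ordered blocks (1 and
3) each pickup location is presented 40 trials in a row, targets sweeping
once up and once down; block 3 reverses block 1's pickup order. In block 2
every (pickup, target) pair appears twice in seeded random order, so every
pair appears exactly six times per session.

## Hand-movement dynamics

The hand is a point end-effector with heading $\varphi$ (measured from the
+y axis toward +x, so $\dot x = v\sin\varphi$, $\dot y = v\cos\varphi$),
steered by a damped angular spring toward the goal direction $\theta_g$:

$$\ddot\varphi = -b_g\dot\varphi - k_g(\varphi - \theta_g)
  \left(e^{-c_1 d_g} + c_2\right),$$

with goal distance $d_g$ (nondimensionalised by 1 m in both exponentials)
hardening the spring on approach and $c_2$ keeping it from vanishing at
distance. The angular error is wrapped to $(-\pi, \pi]$ before the spring
term, and $\theta_g$ is the *signed* two-argument angle of the goal: the
textbook arccos form is unsigned and cannot steer both ways. Speed obeys a
second-order law relaxing toward a distance-scaled ceiling,

$$\ddot v = -b_v\dot v - k_v\!\left(v - C_v(1 - e^{-d_g})\right),$$

so the agent accelerates while far from the goal and brakes on approach,
yielding the single-peaked bell-like profile of natural reaches. Speed is
clamped at zero from below (the law can transiently drive it negative near
the goal). Movements start from rest and are integrated with explicit Euler
at dt = 0.01 s, uniform heading noise of half-width 1.14 degrees added each
step, and terminate within 4 cm of the goal (budget 5,000 steps, i.e. 50
model-seconds; table-scale movements need 30–200).

**Parameter scales.** The damping/stiffness values published for the
antecedent locomotion steering model (b = 3.25, k = 7.5, and a velocity
loop of order 10/25) describe whole-body walking with time constants near a
second. Applied to sub-second tabletop reaches they put the speed peak at
the very end of the movement and leave the heading loop underdamped, in
contradiction with the empirical profile (peak in the first half, typically
near the first third) and with smooth monotone heading convergence. The
defaults are therefore rescaled to hand-movement time constants:
`b_g = 20`, `k_g = 60` (overdamped for every goal distance, since
$b_g^2 > 4k_g(1+c_2)$), and `b_v = 60`, `k_v = 900` (critically damped,
poles at -30 1/s, 90% rise in roughly 0.13 s). These were chosen against
the qualitative kinematic signatures only.

**Maximum-speed constants.** A single $C_v$ cannot reproduce the three
printed class-mean peak speeds (pickup 1.46, pass 1.75, target transport
1.80 m/s) because the three movement classes span very different distances
(0.33–0.46 m, ~0.5–0.9 m, ~1.4 m) under the same saturating drive
$C_v(1-e^{-d})$. $C_v$ is therefore per movement class, fixed by
`calibrate_speed()`: a proportional fixed-point iteration that simulates an
ordered 200-trial block with noise, measures class-mean peaks through the
same analysis path used for reporting (finite-difference speeds,
512-point spline), and rescales each $C_v$ until all classes match within
0.01 m/s (3–4 iterations). The shipped defaults
(`r paste(sprintf("%s %.2f", names(velocity_params()$C_v), velocity_params()$C_v), collapse = ", ")` m/s)
are the output of that calibration.

## Initial movement angles

Empirically, movement curvature is produced by stereotyped initial movement
angles that depend on the pickup location but not on the movement's end
point; the model adopts this directly. Printed initial-angle endpoints
(pickup movements 185.88°–201.59°; pass 31.21° to -35.15°; target 31.35° to
-33.89°) are interpolated across the five pickup labels: linearly for
pickup movements and with a saturating exponential (unit rate parameter 3)
for pass/target movements, whose printed increments shrink as pickup
distance grows. Pass and target movements get identical treatment because
their printed ranges are nearly identical. Uniform noise of half-width 20°
is added per movement.

**Angle conventions.** The analysis convention in which those endpoint
values are printed measures angles counter-clockwise from +x *with the y
axis pointing toward the participant*: that is the only reading under which
the printed straight-line angles to the pickups increase with pickup
distance (171.83°–236.15°) and the printed initial-angle endpoints produce
the reported positive-to-negative curvature flip across pickup locations.
Conversion to the model heading is $\varphi = \mathrm{angle} + 90^\circ$
(`printed_angle_to_heading()`). The package's own measurement operators
(`curvature_area()`) are frame-agnostic: they report angles
counter-clockwise from +x in the coordinates they are given, so measured
initial angles on simulated trajectories are the mirror (sign-flipped
modulo 360°) of the printed convention. Curvature area is signed positive
to the left of the chord.

## Action selection

The pass/no-pass choice is the scalar bistable normal form

$$\dot x = -\alpha + x - x^3, \qquad \alpha = (\sigma - E/A)\,\delta,$$

with potential $V(x) = \alpha x - x^2/2 + x^4/4$ (the quartic sign is fixed
so that $\dot x = -V'(x)$ holds exactly). For $|\alpha| <
\alpha_c = 2/(3\sqrt3) \approx 0.3849$ two stable branches coexist; beyond
$\pm\alpha_c$ a saddle-node bifurcation leaves one. The positive branch
codes *pass* and the negative branch *no pass* — the assignment forced by
the cubic's algebra, under which far targets ($E/A$ large, $\alpha$
negative) produce passes. The trial E/A is the target's y distance over
reach (the empirical definition; Euclidean hand-to-target distance is a
configuration alternative). Each trial integrates the flow for 1,500
fixed-size RK4 steps (dt = 0.005) from the previous trial's end state
(x = 0 at session start), giving trial-to-trial memory; any fixed-step
schedule that reaches the attractor gives identical modes, which is why a
deterministic RK4 stands in for an adaptive solver whose step sequence is
not reproducible.

The defaults $\sigma = 0.825$ and $\delta = \alpha_c/0.028 \approx 13.75$
are calibrated so the bistable band edges sit exactly at the empirical
ascending/descending transition ratios 0.853 and 0.797 (σ is their
midpoint). The hysteresis loop width in E/A units is $2\alpha_c/\delta =
0.056$ analytically.

**Critical slowing.** Just beyond the fold the flow passes through a narrow
channel; within the finite 7.5-unit decision window the mode flips reliably
once $|\alpha|$ exceeds $\alpha_c$ by about 0.1 (about 0.007 in E/A units).
Fine hysteresis sweeps therefore overshoot the band edges by roughly 0.002
E/A per side; the session-level protocol is unaffected because adjacent
targets are 0.067 E/A apart, far clear of the channel.

## Simulation protocol

Each trial runs: ready-to-pickup movement; E/A computation and decision;
transport movement to the target (no pass) or to a jittered pass location
(pass). Pass locations are a session-level anchor — the near-confederate
(0.464, 0.5607) m or near-target (0.7695, 0.5893) m table-frame location —
plus a lognormal radial offset (`meanlog = log(0.05)`, `sdlog = 0.5`;
median 5 cm, chosen to give a few-cm spread in the absence of printed
parameters) in a uniform direction, clipped to the table. The full
experiment is eight 600-trial sessions, four per anchor strategy. One RNG
stream per session with a fixed draw order (pickup initial angle, a block
of per-step heading deviates, transport initial angle, pass jitter) makes
sessions bit-reproducible from their seed; decisions-only sessions
(`movements = FALSE`) skip movement integration yet produce identical
decision series, since the default E/A mode does not consult hand position.

The two pass anchors cannot be reconciled exactly with the
participant-frame cluster centres reported for the empirical data (the two
frames differ by an undocumented offset); anchors are taken at their printed
table-frame values.

## Analysis operators

* `time_normalize()`: cubic-spline resample of x(t), y(t) at 512 uniform
  times. Movements simulated from rest open with a short run of coincident
  samples; the run is collapsed to its last sample (path and endpoints
  unchanged) so the spline is fit to the moving portion, as when empirical
  segments are cut at a boundary crossing — otherwise spline wiggle across
  the stationary samples corrupts the initial-angle estimate.
* `curvature_area()`: signed chord-deviation area by trapezoidal
  integration of perpendicular offset against chord position; initial angle
  from points 1 and 9 of the resample; deviation = initial angle minus
  chord angle. Coincident endpoints, or coincident points 1 and 9, raise
  errors.
* `velocity_profile()`: finite-difference speeds on the raw samples,
  spline-resampled to 512; returns peak and normalised peak time.
* `pass_rate_by_target()` / `transition_point()`: per-target pass fractions
  per order condition, and linear interpolation of the 50% crossing in
  target y, converted to E/A. Within one ordered block the denominators are
  5 (ascending), 5 (descending), and 10 in the random block.
* `optimal_clusters()`: K-means (multi-restart `stats::kmeans`) SSE for
  k = 1..3 against the mean SSE of 100 uniform Monte-Carlo reference draws
  over the observed bounding box; the k with the largest reference-minus-
  observed gap wins, ties to the smaller k.
* `fit_radial_distribution()`: squared distances from the centroid
  ("squared Euclidean distance" taken literally; plain distances are a
  flag), closed-form ML fits of Gaussian/exponential/lognormal, one-sample
  KS test each, best family by largest p. The KS test is applied directly
  to the distances rather than to a kernel density estimate of them — the
  KDE adds smoothing bias without changing the comparative question — and
  asymptotic p-values are used; since fitted parameters bias KS p-values
  upward uniformly across families, only the comparative "percent of
  sessions with p > 0.1" logic should be interpreted.

## What the generator does and does not emulate

Simulated sessions reproduce the task's structure (grids, block schedules,
trial counts), the decision dynamics with hysteresis and carryover, and
movement kinematics with stereotyped initial angles, heading noise and
pass-location jitter. They do not emulate inter-participant variability
(every session uses the mean reach, so transition estimates quantise to
midpoints between adjacent target E/A values — see Limitations), fatigue or
learning across blocks, anticipatory co-actor behaviour, arm kinematics
beyond the end-effector point, or mid-movement decision revision (the
decision is made once, at pickup completion). Passing tests on simulated
data therefore validate the model's internal consistency and its
qualitative agreement with the published aggregate signatures, not
participant-level prediction.

## Numerical choices

Euler at dt = 0.01 s tracks a dt = 1e-4 RK4 reference within 1 cm of final
position over full movements (tested). Heading-noise deviates are drawn as
one block per movement so the RNG stream advances by a fixed amount per
movement regardless of arrival step. `fixed_points()` uses `polyroot` with
a Newton polish and agrees with a dense sign-scan bracket to 1e-8. The
decision RK4 uses fixed steps (see above). Degenerate inputs error
explicitly: zero-distance goals, coincident chord endpoints, constant
series in correlations, all-identical point clouds.

Default problem sizes in the tests and the acceptance script — 20 sessions
for transition statistics, one full movement session for kinematics, 8
sessions for pass-location structure, 200-trial blocks for calibration —
are the smallest sets at which the reported aggregates are stable to well
within their comparison tolerances.

## Limitations

* **Transition quantisation.** With a single (mean) reach, per-condition
  pass-rate curves are deterministic 0/1 steps, so interpolated transition
  points can only take values midway between adjacent target E/A ratios
  (spacing 0.067). The simulated ascending/descending transitions are
  therefore 0.838 and 0.771 in every session, versus the empirical 0.853
  and 0.797: the ascending value and the all-condition overall mean land
  within 0.015 of the empirical reports, the descending value 0.026 away.
  The empirical estimates average over participants whose reaches vary
  (SD about 7 cm), which smooths the same quantisation; reproducing that
  would require departing from the stated single-reach simulation protocol.
  Correspondingly, the hysteresis-centre estimate (mean of ascending and
  descending) recovers σ only up to half a grid step (0.034), while the
  all-condition overall mean — the hysteresis-free estimator that the
  random block provides — recovers it within 0.015.
* **Finite decision window.** Decisions within about 0.007 E/A of a band
  edge inherit the previous mode rather than resolving within the trial
  (critical slowing), an intended consequence of the fixed decision window.
* **Single-strategy sessions.** Each simulated session uses one pass
  anchor; participants who switched strategies mid-experiment are not
  modelled.
* The KS p-values are asymptotic and computed with fitted parameters; they
  support family comparison, not absolute goodness-of-fit claims.
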