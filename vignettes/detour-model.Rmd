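---
title: "The detoursim model: spiking strategy selection in a detour task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The detoursim model: spiking strategy selection in a detour task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detoursim)
```

## The task and the question

In the inward semitransparent-V detour task a subject starts in front of a
V-shaped barrier, facing its apex, with a reward visible behind the barrier
through vertical see-through stripes. A direct approach is futile: the
barrier is physically solid everywhere, so the subject must suppress the
urge to walk at the visible reward and instead take a detour around an arm
of the V. The time spent in the *barrier zone* — a band directly in front
of the barrier — operationalizes inhibitory control: the longer a subject
perseveres at the barrier, the weaker its inhibition of the prepotent
direct approach.

`detoursim` simulates an agent in this task and asks how two neural
factors shape the behavior: the strength `w` of an inhibitory connection
that lets obstacle evidence suppress the direct-approach channel, and the
size `N` of the neural populations carrying each signal. The package runs
the full factorial sweep over `w` and `N` and reports per-cell summary
statistics of barrier-zone time.

## Model components

### Spiking units

Every population consists of Izhikevich two-variable units,

$$\dot v = 0.04v^2 + 5v + 140 - u + I, \qquad \dot u = a(bv - u),$$

with the reset $v \leftarrow c$, $u \leftarrow u + d$ when $v$ reaches
30 mV. Units are of the regular-spiking class: $a = 0.02$, $b = 0.2$,
$c = -65 + 15\gamma^2$, $d = 8 - 6\gamma^2$, where $\gamma \sim U[0,1]$ is
drawn independently per unit at every trial reset. The jitter
desynchronizes units and is the model's only source of randomness: given
the drawn parameters, everything downstream is deterministic.

Integration is forward Euler with 1 ms substeps; the voltage advances in
two half-steps of 0.5 ms per substep (the standard stabilisation for the
quadratic voltage term), and the recovery variable updates once from the
new voltage. Resets are applied exactly — after any spike, `v` equals `c`
bit-for-bit and `u` has been incremented by exactly `d` — and the
canonical rest state $(v, u) = (-70, -14)$ is a machine-precision fixed
point at zero input. The hot loop is compiled (Rcpp); the exported
`izhikevich_substep()` is the plain-R reference implementation, and the
test suite asserts bit-identical agreement between the two paths.

One hundred substeps bridge each 10 Hz world step, so a population's
output per world step is its spike count over 100 ms. The normalized
drive is `min(1, spikes / (N * s_max))` with `s_max = 5`, a tight upper
bound on regular-spiking rates over 100 ms (sustained input at the full
sensory gain yields about four spikes per unit). Dividing by `N` keeps
the mean drive size-invariant while the step-to-step standard deviation
shrinks roughly as $1/\sqrt{N}$ — the precision gain that larger
populations buy, and the effect the population-size sweep probes.
`drive_precision()` measures exactly this curve.

### Leaky integrators and selection

Each strategy channel feeds a leaky integrator with input threshold
$\tau = 1$: above threshold the rate is $\epsilon = 0.1$ with leakage
$\lambda = 0.9$; below it the rate drops to $\omega = 0.024$ with no
leakage. `leaky_integrator()` implements two update modes:

* `"replace"` — direct assignment,
  $y_{t+1} = e\,(x - (1-l)\,y_t)$. For constant supra-threshold input it
  converges geometrically to $\epsilon x / (1 + \epsilon(1-\lambda))$,
  which the tests verify to $10^{-9}$ within 500 iterations. Its decay
  branch, however, is non-accumulating and flips sign around zero input:
  once the input falls silent, $y_{t+1} = -\omega y_t$ alternates sign
  every step.
* `"incremental"` — $y_{t+1} = y_t + e\,(x - (1-l)\,y_t)$, a conventional
  leaky accumulator with smooth exponential decay.

The closed-loop network uses the incremental mode by default. This was a
forced design decision, not a preference: with the replace-mode readout,
the sign alternation makes the argmax flip strategy on every world step
as soon as both strategy populations fall quiet (the flips ride on values
around $10^{-150}$), which destroys choice memory and renders the
inhibition weight behaviorally inert. The replace mode remains available
via `network_config(integrator_mode = "replace")` and stays the default
of the bare `leaky_integrator()` operation.

### The selection network

Four populations of equal size `N`: a *barrier* population driven by the
obstacle signal, a *reward-proximity* population driven by the width of
red in the visual field, and one population per strategy. The allocentric
population receives the barrier population's normalized drive; the
egocentric population receives the reward population's drive *minus*
`w` times the barrier drive — the single one-way inhibitory connection
under study, allowed to go negative (hyperpolarizing) without
rectification. Strategy drives are scaled by 10 and fed to the
integrators, and the behavioral choice is the argmax of the two
integrator values. Exact ties retain the previous choice; the initial
choice is egocentric, the prepotent response that inhibition must
overcome. All population-to-population currents carry a one-world-step
synaptic delay. Symmetric mutual inhibition between the strategy
populations is available (`mutual_inhibition`) but off by default: the
network diagram under study has only the barrier-to-egocentric link, and
competition is realized by the argmax.

### Arena and sensors

The world is a 60x60-unit square, origin at the center. Two 20-unit
barrier arms meet at a 90 degree apex pointing at the agent; the agent
starts 20 units from the apex, facing it; the goal disc sits 8 units
behind the apex inside the V. Arms carry alternating opaque/transparent
1-unit stripes anchored opaque at the apex. The barrier zone is a 4-unit
band along the outer faces of both arms plus a cap around the apex (the
two per-arm quadrilaterals alone would leave a dead wedge directly in
front of the vertex). The agent is a disc of radius 0.5 moving 0.5 units
per step (5 units/s at 10 Hz); collisions cancel the motion component
into the surface, so the agent slides and never penetrates.

The camera casts 64 rays over a 120 degree field of view. Two channels:

* **Red** — a ray is red when its first *visual* obstruction is the goal
  disc; opaque stripes and border walls occlude, transparent stripes do
  not. The count of red rays, divided by `red_saturation = n_rays / 4`,
  is the reward drive; the mean red ray index is the homing centroid.
* **Depth** — distance to the nearest *physically solid* surface,
  transparent stripes included. Depths are binned into four bands (edges
  2, 4, 6, 8 units; weights 0.4/0.3/0.2/0.1) and the weighted sum,
  normalized by `n_rays * 0.4`, is the barrier drive — a receptive field
  for obstacles immediately in front of the agent.

The goal placement deserves a note: the goal *reach* radius is 5 world
units (a trial succeeds when the agent center comes within 5 of the goal
center), so the goal must sit at least $5\sqrt{2}$ behind a 90 degree
apex or the reach disc protrudes outside the V and the task degenerates
to a straight run. The default of 8 is the smallest integer placement
that keeps the whole reach disc strictly inside the V.

### Sensor calibration

The rendering-side scalings (how large the goal appears, how pixel
counts map to drives) are not dictated by the behavioral protocol, yet the network only
expresses its mechanism in a particular sensory regime. The shipped
calibration (`goal_visual_radius = 3`, `red_saturation = 16` rays) was
chosen to satisfy three operating points, in this order of precedence:

1. **Approach**: the red channel engages from the start pose (weak but
   above zero), so the egocentric channel has a head start and the direct
   approach is the prepotent response.
2. **Apex contact**: pressed at the apex with the goal half-occluded by
   stripes, reward and barrier channels drive their populations at
   comparable supra-rheobase currents, so the contest is decided by the
   inhibition weight and by spiking noise — the two experimental factors.
3. **Flat arm faces**: the barrier channel wins on average, so a detour
   always completes within the 120 s ceiling, matching the premise of the
   behavioral protocol.

A larger rendered disc violates (3) — the disc fills the view at the
wall position nearest the goal and that spot becomes absorbing for the
direct approach; a larger `red_saturation` violates (1) and (2) by
silencing the reward channel entirely. Rheobase for these units is
$I \approx 4$, reached at a sensory drive of about $0.27$ at the
drive-to-current gain of 15.

### Navigation policies

The allocentric policy rasterizes the arena to a 1-unit occupancy grid
(obstacles inflated by the agent radius, goal cell kept free), runs a
breadth-first wavefront expansion from the goal cell (8-connected, unit
cost), and heads for the neighboring cell with the smallest distance,
ties broken in the fixed order N, NE, E, SE, S, SW, W, NW. Every
reachable non-goal cell has a neighbor exactly one closer (the Bellman
property), so gradient descent cannot get trapped; the tests verify the
distance field against an independent graph-library shortest-path oracle
on random grids. Because the continuous agent can stand closer to a wall
than the inflated raster admits, its own cell may be blocked and its
8-neighborhood can straddle a thin diagonal wall; a neighbor is therefore
only eligible if the straight segment from the agent to that neighbor's
center crosses no solid barrier segment. The arena is static, so the map
is computed once per trial and reused — per-step replanning on a static
arena provably yields the identical map (tested).

The egocentric policy is a proportional controller: the new heading is
the old heading plus `k_turn` (default 1) times the angular offset of the
red centroid from the camera center; with no red in view the agent
rotates in place by 15 degrees per step.

## Trial protocol and the sweep

A trial runs at most 1,200 steps at 10 Hz (120 s ceiling), succeeds when
the agent comes within 5 units of the goal center, redraws every unit's
$\gamma$ at reset, and counts a step toward barrier time when the
post-move pose lies in the zone (at most one count per step). The sweep
runs 15 trials (configurable) for each pair of inhibition level
(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0) and population size (1, 2, 5, 10), with
per-trial seeds drawn deterministically from a master seed and recorded
for exact replay.

Summaries per cell: mean, sample SD (n-1 denominator, 0 for a single
trial), median and IQR with interpolated quartiles (R's default type-7
rule; the choice matters for small cells and is fixed here so the output
schema is well defined), min, max. Trials that hit the step ceiling are
flagged unsuccessful and excluded from summaries with a warning; their
barrier times remain in the per-trial table. Under the shipped
calibration timeouts are rare (a few percent, concentrated at zero
inhibition and small populations), but they do occur, whereas animals in
this protocol essentially always complete the detour within the limit.

The figure analogues use log10 of the median with a seeded percentile
bootstrap (1,000 resamples) for the median's confidence interval — the
CI method is a package choice — and a
mean-vs-SD scatter onto which user-supplied animal summary statistics can
be merged (`compare_animals()`). The package ships only a clearly
labelled synthetic example CSV; no animal numbers are bundled because
none are published in machine-readable form with the model.

## What the simulation does and does not emulate

The generator reproduces the *structure* of the behavioral experiment:
the geometry, the sensory conflict (reward visible, path blocked), the
10 Hz closed loop, the trial count and the sweep grid. It does not
emulate physics-engine contact dynamics, asynchronous sensor transport,
learning across trials (none, by design), or any species' actual sensory
acuity. Passing trend tests therefore says that *this mechanism* —
spiking populations, one inhibitory link, integrator argmax — produces
the qualitative pattern (barrier time falls with inhibition; its spread
falls with population size); it does not validate quantitative
correspondence to any animal's barrier times.

Expected orderings at small trial counts are stochastic. With 10-15
trials per cell the median ordering across inhibition levels at
population size 10 held at every master seed we examined; at population
size 1 roughly one seed in five inverts an ordering — small-population
cells are intrinsically noisy at these trial counts.
The shipped trend checks run at the package's default master seed (42)
with the scaled-down grid (sizes 1 and 10, weights 0 and 1, 10 trials).

## Numerical choices and degenerate inputs

* Euler substeps: `dt = 1` ms, 100 per world step; both configurable.
* All containment tests use closed boundaries (a pose exactly 5 units
  from the goal counts as success; a ray hitting a segment endpoint
  counts as a hit).
* Collision resolution accepts a slid position only if it is no deeper
  into any wall than the starting pose (tolerance $10^{-9}$ per step),
  so numerical drift cannot ratchet the agent through a wall.
* The wavefront treats the goal cell of a rasterized arena as free even
  if the goal hugs an obstacle; a goal cell explicitly passed as blocked
  is an error.
* Ray indices are 1-based throughout the R API (ray 1 is the leftmost);
  the angular mapping is what the controller consumes, and it is tested
  exactly (rightmost centroid at 120 degrees field of view turns the
  heading by -60 degrees at unit gain).
* An empty cell in the sweep (all trials errored) is reported as a
  missing summary row rather than NaNs.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run, by choice, at sizes that
exercise every code path while staying lightweight: 100 random 20x20
grids for the wavefront oracle, 10 replicate populations x 200 world
steps for the drive-precision curve, a 2x2x10-trial scaled sweep for the
trend checks, and the full 7x4 grid at 5 trials per cell for the
mean-vs-SD association. The full 7x4x15 sweep (420 trials) is a single
`run_sweep(sweep_config())` call and completes in a few minutes on one
core.

## Known limitations

* The direct-assignment integrator form is kept faithfully but is
  unusable as the closed-loop readout (see above); readers comparing the
  two update rules should note the mode flag.
* Barrier-zone geometry is a polygonal approximation (two quads plus an
  apex cap); a rounded band would differ by at most the cap corners.
* At zero inhibition a small fraction of trials perseveres to the
  ceiling; the summary pipeline excludes them, which biases those cells'
  statistics toward the escaping trials.
* The model is deterministic within a trial given the drawn unit
  parameters; all between-trial variability is parameter jitter, whereas
  a physical simulation would add sensor and actuation noise.
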