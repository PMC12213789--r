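---
title: "The goalgrow model: a foraging neural agent with coherence-gated neuron growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The goalgrow model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(goalgrow)
```

## The model

`goalgrow` simulates an "organism" — a small three-layer neural network —
moving in discrete time across a square field scattered with point objects
of four colors. Each color carries a signed *color-number* (red 8, green 2,
yellow 1, blue −1): the sign decides whether an untrained organism
approaches or retreats from the object, the magnitude scales how hard it is
pulled. An object whose center comes within the organism's radius, inside
its frontal vision cone, is *touched*: it disappears, and touching red or
green triggers weight learning. When the organism's center reaches the field
border it leaps to a uniform random point on the segment between the
crossing point and its start position.

The controller has:

* **Receptors.** The vision cone (π radians by default) is split into
  `n_receptors` equal sectors; each receptor reports the Euclidean-nearest
  live object in its sector as `(color_number, 1/(1+D), 1/(1+A))`, where
  `D` is distance and `A` the absolute angular deviation from the heading.
  The receptor index already encodes side, so a single non-negative angle
  is normalized.
* **Perceptive layer.** Each neuron reads `nc` receptors topographically;
  its input is the weighted sum of the three signals, squashed by the odd
  logistic `squash(x) = 2/(1+exp(-x)) - 1`. These weights are drawn once in
  [0, 0.5) and never learn.
* **Goal layer.** A recurrent net: each neuron reads `nc` perceptive
  neurons (topographic, weights in [0, 0.5)) and `nc` random other goal
  neurons (weights in [−0.5, 0.5)). The recurrent term always uses the
  previous tick's outputs (synchronous update).
* **Motor layer.** Each motor neuron initially reads `nc` random goal
  neurons (weights in [0, 0.5)). Odd-indexed motors drive the x
  displacement, even-indexed the y displacement:
  `DX = 2 k_dx Σ(odd outputs)/TM`, likewise `DY`. If nothing is perceived
  the organism rotates by `rotation_step` instead of translating.

## Plasticity and the four modes

Let λ(t) be the mean squared one-step change of the goal outputs — a crude
global "EEG" of the layer — and ρ(i) the same quantity per neuron. Three
gates control learning; substituting ∞ for a gate removes it, which defines
the modes:

| Mode | Tact | T1 | T2 | behavior |
|------|------|----|----|----------|
| 1 | ∞ | ∞ | ∞ | no learning at all |
| 2 | 0.5 | ∞ | ∞ | touch-triggered weight updates only |
| 3 | 0.5 | 0.01 | ∞ | plus gradient reinforcement when T1 < λ < T2 |
| 4 | 0.5 | 0.01 | 0.1 | plus structural growth when λ > T2 |

*Touch updates.* A red or green touch multiplies, for every goal neuron
with `|output| > Tact`, its perceptive-input weights by `(1 + k1·colr)` and
its motor-output weights by `(1 + k2·colr)` (green) or `(−1 − k2·colr)`
(red) — red touches flip the motor drive of the currently active neurons,
which is how red avoidance is meant to be learned. `colr` is set at a
neuron's first gated update to the touched object's |color-number| and is
multiplied by `colr_decay` after every update, bounding cumulative weight
growth. The update rules themselves leave `colr` uninitialized; the
first-gated-touch rule is our documented choice, switchable to a constant
via `colr_init`.

*Reinforcement.* When `T1 < λ < T2`, each goal-input weight moves by
`kb · O_src · 0.5 · Δout · (1 + out)(1 − out)` — the one-step output delta
times the derivative of `squash` at the current output: the trailing factor
is the standard squash derivative `0.5(1+y)(1−y)`, which makes the update a
gradient step on the squared one-step output change.

*Growth (Mode 4).* When `λ > T2` the layer grows: repeatedly take the two
neurons with smallest ρ (ties by lowest id; re-selected every iteration
with new neurons included), create a new neuron whose every input slot is
copied from donor 1 with probability `p`, else donor 2; the chosen donor's
memory `t_memory` rises by `df`, and the running coherence ζ accumulates
the donor's updated memory. Output slots copy donor 1's or rewire to a
random motor neuron. The event ends when ζ reaches `t_coherence`. Since
every slot raises some memory by `df > 0`, ζ diverges and the loop always
terminates; heavily-used donors end events after a single creation. We
accumulate ζ in closed form per created neuron (the per-slot sum is
order-independent), which is algebraically identical to the slot-by-slot
pseudo-code. A hard cap (`max_goal_neurons`, default 2500) truncates events
with a warning; the default sits above the ~2000 neurons long runs reach.

## Geometry and numerical choices

* The field is an axis-aligned square (`side_length` 500); objects are
  points, the organism a disc of radius 10.
* Movement is applied in world coordinates exactly as the displacement
  formulas state; the heading (used only by perception and touch cones) is
  set to `atan2(DY, DX)` after any nonzero move. An `egocentric` option
  rotates (DX, DY) into the heading frame instead; the world-frame reading
  is the default.
* Border crossing is resolved after the movement step and before touch
  detection; the leap lands strictly inside the field (clamped by
  `1e-9 · side_length`). "Start position" means the simulation's initial
  position.
* Perception range is unlimited (distance already attenuates as `1/(1+D)`);
  a `max_range` cut-off is available but off by default.
* `squash` clamps its output to ±(1 − 1e−12): touch learning can inflate
  weights enough that the logistic rounds to exactly ±1 in doubles, which
  would break the open-interval invariant downstream.
* Exactly one λ-gated action fires per tick (reinforce *or* grow); touch
  updates fire on touches regardless of the λ band. After growth the
  forward pass is re-run on the enlarged layer with the same t−1 outputs;
  a new neuron's previous output is donor 1's t−1 output and its current
  output is 0 until that pass.
* In Mode 1 the *learnable* state — weights, wiring, memories, `colr` — is
  bit-frozen over any run. The layer outputs themselves keep evolving
  (frozen weights do not freeze dynamics), so output vectors are excluded
  from the frozen-state comparison.
* Every source of randomness draws from named substreams (world, weights,
  growth, leaps, relocation) derived from one master seed, so runs are
  reproducible byte-for-byte and changing one subsystem's draw count never
  shifts another's.

## Defaults and what they mean

Sizes not pinned down by the model equations default to: 16 perceptive
neurons, 8 motor neurons, `nc = 4` connections per unit, `k_dx = k_dy = 6`
field units (so a tick moves at most ~6 units, small against the 500-unit
field), rotation step π/8 (one receptor sector). Plasticity defaults:
`k1 = k2 = 0.05`, `kb = 0.1`, `colr_decay = 0.99`, `p = 0.7`, `df = 0.1`,
`t_coherence = 1`, gates `(0.5, 0.01, 0.1)`. The goal layer starts at 28
neurons in Mode 4 and 1000 in Modes 1–3, which keeps the structural modes
comparable while letting Mode 4 grow. All of these sit in one nested
configuration (`default_config()`), are validated against a closed schema,
and can be overridden from JSON.

## The experiment at desk scale

Wall-clock run budgets are hardware-bound, so the package defines
experiments by step count: the bundled experiment and acceptance script run
**20 replicates per mode at 5,000 ticks** with the default field (200
objects), and every output file records its configuration. At this scale
(seed 1): Mode 1 touches ~2% of objects — the organism is promptly trapped
by conflicting pulls, drifts to a border pocket and oscillates, matching
the under-10% inactivity bound. Mode 4's mean total exceeds the other
modes: structural growth visibly raises movement amplitude (median step
length grows from under 1 to ~8 field units as the layer grows past 1,500
neurons), producing more border leaps and more touches.

Two caveats the tests make explicit. First, the red-avoidance contrast is
*weak* at this scale: a 5,000-tick run yields only a handful of red
touches, and because each red touch multiplies motor weights by a negative
factor, an even number of touches restores approach — the learned sign is
close to random parity, and the matched-pairs Wilcoxon comparisons do not
reach uniform significance at 20 replicates. Second, the Mode-4 versus
Mode-2 margin is small relative to between-run variance. Both contrasts
strengthen with longer runs and more replicates; neither threshold nor
parameter was adjusted to force them.

## The relocation probe

`relocation_probe()` teleports the organism mid-run to a distant point
(network untouched) and asks whether the trajectory re-enters its
pre-relocation confinement region. Confinement is quantified by
`confinement_episodes()`: maximal stretches of at least `window` ticks
(default 200) whose position bounding box has diagonal at most
`trap_diameter` (default 15% of the side length). These two knobs are our
own operationalization of "trapped in an area"; the underlying description
is informal. Returning after relocation is the model's strongest
goal-directedness signature and is rare; the probe reports occurrence and
latency rather than asserting a rate.

## What the generator does and does not emulate

Worlds are generated internally: uniform object placement, exact per-color
counts, uniform organism start. The worlds are entirely synthetic — there
is no object motion, no respawning, no sensor noise, and a point-object
geometry. Passing tests therefore demonstrate
internal consistency of the model and the statistics pipeline, not
predictions about any physical foraging system.

## Known limitations

* Statistical power at the bundled scale is limited (above); the learning
  contrasts need substantially longer runs and more replicates to
  stabilize.
* ρ is a metric in output space only; topology-aware variants with several
  concurrent minima are out of scope.
* Neuron death, connection pruning and multi-level goal hierarchies are
  not modeled.
* The heading-update rule and rotation geometry are free modeling choices,
  exposed in the configuration rather than hard-coded.
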