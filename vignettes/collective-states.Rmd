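---
title: "Quantifying collective states of schooling fish: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collective states of schooling fish: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolstates)
```

## The model of the data

The empirical object is a trajectory table: per video frame, the
position (cm) and velocity (cm/s) of each individually tracked fish in
a rectangular, shallow tank, at a known frame rate (30 fps in the
reference setup). Tracking drops individuals intermittently, so the
pipeline never requires persistent identities: every per-frame statistic
normalizes by the number of valid individuals present in that frame.

Headings are derived from velocities. A velocity defines a heading when
its magnitude is at least `speed_floor` (default 1e-6 cm/s — a machine
noise guard, not a behavioral threshold). Below the floor the fish is
effectively stationary and its most recent valid heading is carried
forward; a fish that has never moved is excluded from heading averages.
Carrying forward keeps the per-frame count stable through brief pauses;
excluding stationary fish outright is a defensible alternative, and the
choice only matters in dense, slow swarms where some fish idle.

## Order parameters and smoothing

Polarization is the magnitude of the mean unit heading; rotation is the
magnitude of the mean normalized angular momentum about the group center
of mass, with counter-clockwise positive and fish exactly at the center
contributing zero. Both are dimensionless in [0, 1] and invariant under
global translations and rotations (a property the test suite checks
directly, alongside a per-fish loop oracle).

Both series are smoothed with a centered moving average spanning 30
frames (1 s). Even spans are reduced by one frame to keep the window
centered; near the series edges the half-width shrinks symmetrically.
One subtlety is deliberately fixed here: the smoothed rotation magnitude
is the smoothed *magnitude* series, not the magnitude of the smoothed
signed series. A mill that flips handedness mid-visit passes through
zero signed rotation; smoothing the signed series first would manufacture
a spurious drop out of the milling state.

## States, visits and transitions

The `(O_r, O_p)` plane is partitioned with one threshold `k = 0.35`:
P when `O_p > 1−k` and `O_r < k`, M when `O_p < k` and `O_r > 1−k`,
S when both are below `k`, and the transitional region T elsewhere.
Inequalities are strict, so points exactly on a threshold are
transitional. The partition is a heuristic over the observed density
hotspots; the package keeps `k` configurable and the test suite checks
that the qualitative occupancy ordering survives moving `k` to 0.25.

Visits are maximal runs of one label. Tracking gaps shorter than 1 s
flanked by the same label are bridged; longer gaps split the series into
segments, and visits are never merged — nor transitions counted —
across a segment boundary, because the intervening behavior was not
observed. A completed transition is a change of state between
consecutive non-T visits within a segment, whether or not T frames
intervene; an excursion into T that returns to the same state is a
perturbation, not a transition. The completion fraction statistic
counts, among T visits longer than 1 s with defined states on both
sides, the share whose flanking states differ.

Milling handedness is the sign of the mean signed rotation over each
milling visit; an exactly zero mean (probability zero) is tie-broken to
counter-clockwise and logged.

## Group geometry

The area spanned by the group is measured with a 2D alpha shape: the
union of Delaunay triangles whose circumradius is at most the probe
radius. The triangulation is a Bowyer–Watson insertion written for this
package (no Delaunay implementation is available among its
dependencies), using the incircle determinant predicate with
counter-clockwise triangles and three distant auxiliary vertices; the
test suite validates it against the convex-hull area and Euler triangle
counts on random clouds, and the alpha-shape area against a Monte-Carlo
point-sampling oracle.

The probe radius defaults to one body length (5.2 cm) and is an explicit
calibration parameter: the reference analysis does not record its value.
The packing fraction multiplies fish count per unit area by a nominal
body area of 3.38 cm² (a 5.2 × 0.65 cm body, the 8:1 aspect of the
reference species); any other constant rescales packing fractions
uniformly without changing their dependence on state or group size.

Two estimator caveats matter when comparing packing fractions across
group sizes. First, the alpha-shape area of a finite point cloud is
biased low by boundary raggedness, with a relative bias shrinking like
n^(-1/2); a fixed-spacing group therefore shows a residual downward
drift of measured area per fish — about 25% between 30 and 300
individuals in the bundled generator — even though its density is
constant by construction. This is far from the tenfold growth a
catastrophic (non-H-stable) system would show, which is the contrast the
tests assert. Second, the probe radius trades concavity tracking against
fragmentation; per-frame component counts are reported so fragmented
frames can be filtered.

## Phase-space maps

Occupancy and conditional-mean maps bin `(O_r, O_p)` on a 30 × 30 grid
(O_r on the first axis), half-open bins with the last bin closed so a
value of exactly 1 is kept. Bins supported by fewer than `min_count`
samples (100 for occupancy and mean maps, 20 for transition-conditioned
maps) are masked and never interpolated from. Refinement to a 300 × 300
mesh is bilinear between unmasked bin centers; fine points whose
containing coarse bin is masked stay empty, and where a neighboring bin
needed for interpolation is masked the bin's own value is used — the
refined surface never extrapolates beyond the supported region nor
exceeds the range of the contributing bins.

Transition paths (the `(O_r, O_p)` track from the last frame of the
source visit to the first frame of the destination visit) are resampled
to a common length of 100 points by linear interpolation in normalized
time, then averaged pointwise. Phase-velocity fields use forward finite
differences of the resampled paths, assigned to the bin of the starting
point of each difference; the scheme is unstated in the reference
analysis and forward differencing is the simplest consistent choice.

## The zonal model

Agents move at exactly constant speed in the plane. Each carries three
concentric zones — repulsion (radius 1), orientation (3), attraction
(15, model length units) — and a 270° field of perception whose 90°
blind sector applies to every zone: an agent cannot react to what it
cannot see, repulsion included. Any visible neighbor inside the
repulsion zone makes the desired direction the normalized sum of unit
vectors away from those neighbors, overriding all else. Otherwise the
mean heading of visible orientation-zone neighbors (excluding the
focal's own heading) and the normalized attraction vector are each
normalized and averaged when both zones are populated. The desired
direction is perturbed by Gaussian angular noise (sd 0.2 rad), the
heading turns toward it by at most 60° per unit time (6° per step at
dt = 0.1), and the agent advances. Updates are synchronous. Runs last
2500 steps from a uniform random initialization in a disc of radius 15
(the attraction range, guaranteeing initial connectivity) and record the
final-step order parameters; speed sweeps cover 0.1–4.1 in steps of 0.1
with independently seeded replicates.

Two conventions deserve justification. Normalizing the orientation and
attraction responses before averaging (rather than averaging the raw
zone sums) is load-bearing in 2D: with raw sums, the attraction term
grows with the number of far neighbors and collapses any group of ~70+
agents into a dense swarm at every speed, erasing the three-state
structure; with normalized terms the model exhibits swarming at low
speed and milling/polarized order at high speed, as intended. The
turn-rate limit is read as per unit time (6°/step), consistent with the
explicit time step.

### What the 2D model does and does not reproduce

The planar model reproduces the central speed-driven structure: at
s = 0.1 groups settle into a disordered, dense swarm; at high speed
(s ≈ 3–4) the final states split between a coherent mill and a
polarized group with few mid-range outcomes — the bistability signature
— for groups up to 150 agents.

It does *not* reproduce the reference group-size trend at the top of the
speed range. There, larger groups are reported to mill ever more
stably, with no polarized outcomes at 300 agents. In the planar model
the opposite happens at high speed: a 300-agent group's mill must grow
its radius linearly in N (perimeter packing with unit repulsion)
rather than as N^(1/2), quickly exceeding the 15-unit attraction range,
and the stable large-N configuration becomes a polarized band (measured:
roughly half of 300-agent runs at s = 3 end polarized, most at s = 4).
The zone-model family this parameterization comes from is
three-dimensional, where volume scaling keeps large groups within
interaction range; the planar implementation was chosen to match the
planar order parameters and the shallow-water system. The corresponding
acceptance expectations are left in place and fail honestly; treat
large-N high-speed comparisons between this 2D model and 3D results
with care.

## Synthetic data: what it emulates and what it does not

Three generators make every stage testable without recordings.
`make_archetype()` builds analytic single frames (exact tangential
mills, perfectly aligned schools, uniform swarms) with known order
parameters. `make_state_series()` emits an order-parameter time series
that dwells at per-state anchor points — (O_p, O_r) = (0.85, 0.10) for
P, (0.10, 0.85) for M, (0.15, 0.15) for S, the centers of the empirical
high-density regions — with Gaussian fluctuations and linear ramps
(ground truth T) between states. `make_bounded_school()` realizes a
state script as full trajectories in a tank: translating-and-reflecting
blobs for P, rotation about a drifting center for M, slow jitter with
shrunken spacing for S (speeds 10 / 8 / 2 cm/s, spacing 4 cm ≈ 0.8 body
lengths — representative of shallow-water shoaling), so the swarm is
slower and denser than the ordered states, as in real schools.

These generators emulate the *geometry* of the states and the scripted
switching, not the dynamics of real fish: there is no social feedback,
no boundary-induced perturbation mechanism, no tracking-error structure,
and transitions happen on schedule rather than stochastically. Passing
the recovery tests therefore shows the pipeline measures what it claims
to measure on data with known ground truth — not that real shoals
behave like the generator.

## Numerical choices and problem sizes

Order-parameter identities are asserted to 1e-12; the alpha-shape /
Monte-Carlo comparison to 2%; bilinear refinement exactness on linear
fields to 1e-6. Classification clamps machine-epsilon overshoots of the
[0, 1] range that arise from averaging unit vectors. Simulation
reproducibility comes from R's RNG (seeded per replicate by a base seed
plus counter), so identical seeds give identical runs, and equivariance
under global rotation holds to floating-point accuracy over short
horizons.

The bundled analyses and tests run at desk scale by design: scripted
fixtures of 1–3 minutes at 30 fps with 30–60 fish, simulation checks
with 24 replicates per condition at the reference step count (2500) for
group sizes 30–300, and full-length (500-replicate) sweeps left to the
user via `speed_sweep()`. The 47% transition-completion worked example
is evaluated from its printed visit counts (1943 of 4119) by
constructing an explicit visit sequence with those counts and running
the statistic over it.

## Known limitations

* The state partition is a fixed-threshold heuristic; occupancy
  fractions shift with `k`, though orderings are robust in the tested
  range.
* The alpha-shape probe radius and body area are calibration parameters
  with no recorded reference values; packing fractions are comparable
  within an analysis, not across differently calibrated ones.
* The zonal model is planar; its large-N high-speed behavior differs
  from the 3D family as described above.
* Persistence curves and completion fractions are sensitive to the
  smoothing span near state boundaries; sub-second dwells below the
  span are not resolvable by construction.
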