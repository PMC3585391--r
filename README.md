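# schoolstates

Quantitative analysis of collective states in schooling fish.

Groups of schooling fish do not move in one fixed formation: the same
school drifts between a dense, disordered **swarm (S)**, a fast,
aligned **polarized school (P)**, and a rotating **mill (M)**. This
package implements the complete pipeline for identifying these
dynamically-stable states and the transitions between them from
trajectory data (per-frame positions and velocities of individually
tracked fish), together with a constant-speed zonal agent-based model
that shows the same state structure arises from local interaction rules
alone, without tank boundaries. It is aimed at researchers in collective
animal behavior working with tracked shoals, flocks or swarms in 2D
arenas.

## The order parameters

Each frame of `N` fish with unit heading vectors `u_i` is projected onto
two numbers:

* **polarization** — the magnitude of the mean heading,

  `O_p = (1/N) | Σ_i u_i |`,

  1 when every fish points the same way, ~0 for incoherent headings;

* **rotation** — the magnitude of the mean normalized angular momentum
  about the group center of mass,

  `O_r = (1/N) | Σ_i (r̂_ic × u_i) · ẑ |`,

  where `r̂_ic` is the unit vector from the center of mass to fish `i`;
  1 for a coherent mill.

After smoothing (centered moving average, 30 frames = 1 s at 30 fps) the
`(O_r, O_p)` plane is partitioned with a single threshold `k = 0.35`:
polarized when `O_p > 1−k` and `O_r < k`; milling when `O_p < k` and
`O_r > 1−k`; swarm when both are below `k`; everything else is the
transitional region (T). A *completed transition* is a move from one of
S/P/M to a different one — an excursion into T that returns to the same
state does not count.

On top of this the package computes: visit run-length statistics,
transition rates and destination fractions, persistence (survival)
curves, milling handedness, alpha-shape group area and packing fraction,
distance to the tank boundary, phase-space occupancy/conditional-mean
maps with bilinear refinement, averaged transition paths and
phase-velocity fields, local polarization versus individual speed, and
the radial shell structure of the mill.

The zonal model (`sim_config()`, `run_sim()`, `speed_sweep()`) moves
agents at constant speed with repulsion/orientation/attraction zones
(radii 1/3/15), a 270° field of perception, a 60°-per-unit-time turn
limit and 0.2 rad Gaussian heading noise; the C++ core makes
500-replicate speed sweeps practical.

## Worked example

Generate a scripted synthetic school (polarized → mill → swarm →
polarized, 20 s each) in a 210 × 120 cm tank and run the full pipeline:

```r
library(schoolstates)
set.seed(7)
script <- data.frame(label = c("P", "M", "S", "P"), dwell_s = c(20, 20, 20, 20))
school <- make_bounded_school(script, n = 60)
an <- analyze(school$dataset, analysis_config())
an
#> <school_analysis> 2580 frames (1.4 min), 9 visits, 3 completed transitions
#>   time fractions: S 0.25  P 0.46  M 0.26  T 0.02
#>   transition rate: 2.09 / min   manifest 63e0492d

round(an$summary$state_fractions, 3)
#>     S     P     M     T
#> 0.253 0.462 0.264 0.022

an$summary$handedness
#>        n_clockwise n_counterclockwise
#>                  1                  1

mean(an$series$packing_fraction, na.rm = TRUE)
#> [1] 0.384
```

The recovered time fractions mirror the script (two polarized dwells out
of four segments → P ≈ 0.46), the three scripted state changes are
recovered as exactly 3 completed transitions, and the transition rate
(3 transitions in 1.4 min ≈ 2.1/min) is in the range reported for real
shoals of this size. `write_analysis(an, "out/")` exports every table as
delimited text stamped with the configuration hash.

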