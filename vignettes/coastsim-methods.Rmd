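---
title: "coastsim: model, design choices and numerical details"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{coastsim: model, design choices and numerical details}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coastsim)
```

## The model in brief

`coastsim` couples a population of tourism operators to a spatial coastal
environment. The world is a rectangular grid of cells read from a plain-text
map of six-digit codes: digits 1–2 give the geospatial type (deep sea,
nearshore waters, water's edge, coastline, beachfront, beach, faraway beach,
inland — each with an elevation interval and a geospatial attractiveness
value), digit 3 flags mangroves or fauna, digit 4 the coral cover, and
digits 5–6 are reserved. Cells carry pollution (unbounded above, floored at
0), environmental degradation in [0, 1], and an attractiveness in [0, 1]
computed as `0.5 + Wgeo·Geo + Wbio·Bio − Wpol·min(Pol, 1) − Wenv·Env`.

Two agent families live on the grid. *Operators* (five types with fixed
counts 30/10/20/5/10 and typed initial resources and input requirements)
allocate integer resource units each tick over maintenance, tourism,
environment and savings, collect revenue net of pollution, degradation,
location and maintenance-delay penalties, and go bankrupt at zero resources.
Land-based operators are immobile; water-based ones hold a land base and
move among admissible water cells towards attractiveness. *Environmental
resources* (fish, turtles, coral, mangroves) carry a health in [0, 1] that
responds to local pollution and degradation, die with probability 0.5 below
health 0.25, and reproduce with probability 0.01 above 0.95 subject to
per-cell caps (2 fish, 2 turtles, 3 coral, 1 mangrove).

Three environmental pressures act on different time scales: pollution
(generated by operators whose tourism over-investment outruns their
environmental investment, diffusing each tick), sudden events (at a fixed
interval, each cell independently hit with a small probability, depositing
degradation that later spreads, persists, or clears with probability 1/3
each), and sea-level rise (a per-tick increment of `SLR-increase`/1000/35
meters, optionally accelerating ×1.25/×1.5/×1.75/×2.0 from ticks
200/400/800/1200, eroding low land that borders the sea; mangroves buy a
0.2 m buffer).

Operators respond through a collective-action mechanism processed per tick
in the order sudden events → SLR → pollution, each with a collaborative pass
over vulnerable cells followed by an individual pass. Willingness to act is
a probability assembled from how the operator is affected (on the cell, next
to it, or via its base), its mobility, and — for collaborative action — the
balance of positive versus negative out-links. Contributions are capped
individually (an eight-row table over excess resources, needs coverage,
saving tendency, and affectedness) and rise in round-robin unit steps until
the event cost is covered exactly; a funded action remediates the cell
stochastically (e.g. each 0.1 pollution chunk removed with probability 0.75
on land, 0.50 in water), and every ordered pair of willing operators updates
its directed link strength by an eight-row learning table scaled by the
`positive-association`/`negative-association` parameters.

## Scheduling and reproducibility

Each tick executes: (1) diffusion, degradation ageing/evolution,
marine-life movement, attractiveness recompute; (2) allocations and action
budgets; (3) sudden-event check, then SLR and erosion; (4–6) the two action
passes per event kind; (7) revenue settlement; (8) operator pollution
updates; (9) operator movement; (10) bankruptcy; (11) resource demography.
Wherever a set of agents or cells acts "simultaneously", they are processed
sequentially in a fresh random order. A single global RNG stream seeded by
`seed-for-random` drives every draw, so a run is a pure function of
(parameters, map, seed); the determinism tests assert bit-identical series.

Attractiveness is recomputed once per tick, in step (1). Actions taken later
in the same tick therefore affect the attractiveness that operators see only
from the next tick on; the alternative (recomputing after step 6) would let
remediation pay off within the tick, which would blur the one-tick delay
between investment and perception that the rest of the model assumes.

## Parameters

`parameter_space()` lists all 34 parameters (33 behavioural plus the seed)
with their types and ranges; `coast_params()` validates a full set. Defaults
are the midpoints of the documented parameter ranges — a neutral baseline for
exploration, not a calibrated scenario — with the three booleans set to
unlimited revenues, links to shared bases on, and linear SLR. The
consequential ones:

* `tourism-returns` [2, 5]: revenue per tourism unit; the main income dial.
* `pollution-change` [0.01, 0.5] / `pollution-clean-up` [0.01, 0.1]:
  pollution units added (removed) per unit of raw pollution effect.
* `pollution-diffusion-rate` [0.01, 0.25]: fraction of a cell's pollution
  exported per tick; the diffusion step conserves total mass exactly.
* `SLR-increase` [0, 50] mm/year, converted internally to meters per tick.
* `sudden-event-interval` {35, …, 350} ticks and
  `patches-affected-sudden-event` [0, 10] %.
* `cost-pollution` {1..20} (per 0.1 chunk, `Ce = ceil(Pol/0.1 · cost)`),
  `cost-SLR` and `cost-extreme-event` {5..50} (flat).
* `positive-association` [0.01, 0.2] / `negative-association` [0.01, 0.25]:
  link-learning step sizes; with both forced to zero, link strengths are
  provably constant (a property test runs this).

## The synthetic map generator

The generator emulates the structure of the original island input: parallel
bands from deep sea through nearshore waters, water's edge, coastline,
beachfront, beach and faraway beach to inland, with fauna and coral codes
sprinkled over the nearshore band (45% of nearshore cells hold fauna, 50%
hold some coral) and mangroves on 15% of the beachfront. It requires
width ≥ 23 and height ≥ 10 so that at least 45 beach/beachfront cells exist
to seat the 40 land-based operators, and at least 10 beachfront cells to
base the boat and nearshore fleets. It is deterministic per seed and leaves
the caller's RNG stream untouched. What it does *not* emulate: a real
coastline's curvature, bays and islands, heterogeneous bathymetry, or
empirically clustered reef systems. Tests passing on these maps show the
mechanics are right under the standard initial conditions; they say nothing
about any real destination's geography.

## Numerical choices

* **Elevation intervals.** The code table's bounds are stored sorted
  (lo ≤ hi); the nearshore interval is printed in the reverse order in the
  source material. Inland cells span 10–100 m, matching the global elevation
  range; beach-row cells sit at a fixed 5 m, water's edge at 0, deep sea
  at −50.
* **Rounding.** Revenue settlement uses half-up rounding
  (`floor(x + 0.5)`), the convention of the original implementation
  platform, not R's round-half-even.
* **Diffusion apportionment.** On land the exported fraction splits equally
  among the same-or-lower-elevation neighbours (equal split is the unique
  choice that conserves mass without further assumptions); a cell with no
  eligible neighbour keeps its pollution. Coastline cells send the whole
  exported fraction to one uniformly chosen coastline neighbour.
* **Coral abundance.** The map encodes four cover levels but the
  biodiversity table distinguishes three: cover 3 reads as abundant, 1–2 as
  some, 0 as none. At initialisation a cell spawns one coral unit per cover
  level (cap 3), so cover and the reproduction cap agree.
* **Nearshore pollution map totality.** The special-case table for
  nearshore operators leaves `At = 2·Ae` between two branches; it is
  assigned to the `At/2 − Ae` branch (yielding 0 there), making the map
  total and continuous at the boundary.
* **Pollution chunking.** A remainder below 0.1 is treated as one final
  chunk, so remediation can always clear a cell completely.
* **Degradation spread.** Spreading copies the source value onto one
  uniformly chosen neighbour, additively capped at 1, and restarts the
  neighbour's event clock.
* **Maintenance after coastal reinforcement.** A reinforced cell raises the
  needed and default maintenance of operators on or next to it by 2 (by 1
  for water-based operators based there); the maximum maintenance rises by
  the same amount so allocations can still reach the new requirement.
* **Ties and degenerate inputs.** All tie-breaking among equally preferred
  cells, sites and categories is uniform. A water-based operator finding no
  admissible base leaves the population at set-up; marine life with no
  admissible destination stays put; an empty willing set (or a single
  willing operator) leaves links untouched.
* **Movement and the per-cell caps.** Reproduction enforces the per-cell
  caps directly; relocation of mobile marine life also skips destinations
  already at the cap, so the caps are invariants of the whole run rather
  than of demography alone.

## Design choices where the design was open

* **Willingness link terms** count all of an operator's out-links, not only
  links to affected operators, and an unaffected operator with balanced
  links can join a collaboration with probability 0.5 of a +0.15 willingness
  term — both read literally from the decision rules. This recruits
  bystanders into collective action occasionally, which is consistent with
  the role of social norms in the model.
* **Dive/boat base preference** (probability 0.1/0.2 of settling for an
  alternative location) is drawn once per operator at base selection.
* **Biodiversity sensitivity thresholds** are applied as written ("greater
  than 0.25 *or* greater than the sensitivity"), so for sensitivities above
  0.25 the fixed 0.25 term dominates.
* **Contribution-limit table, no-excess rows** are keyed by needs coverage
  and affectedness in printed row order (the saving-tendency column is not
  distinguished there).
* **Site memory of mobile operators** is pruned to cells that still belong
  to the operator's admissible geospatial types, which silently drops
  water cells lost to coastal change.
* **Saltelli base samples** are i.i.d. uniforms rather than a
  low-discrepancy sequence; the block structure (`2n(p+1)` rows with
  second-order blocks) and the Saltelli/Jansen estimators are standard, at
  the price of somewhat larger Monte-Carlo error for equal `n`. The
  analytic Ishigami decomposition serves as the estimator's test oracle.
* **PRIM** peels with a lenient objective (density gain per fraction
  peeled, not requiring monotone improvement), selects the densest point of
  the peeling trajectory, and pastes faces back while density does not
  drop. Successive boxes are induced on the points outside earlier boxes.
  Coverage and density of every reported box are re-verified by direct
  counting in the tests.

## Problem sizes used in the tests

The suite exercises the full standard initial conditions (75 operators on
30×30 synthetic maps) but keeps horizons short where dynamics are not the
point: determinism over 25 ticks, scheduler arithmetic over 70, the
end-to-end run over the full 1050-tick horizon once. Monte-Carlo
calibrations of the stated probabilities (0.75, 0.5, 1/3, 0.01) use 10⁴–10⁵
draws against three-sigma binomial intervals; the Sobol oracle uses
n = 2048–4096 base samples on the three-dimensional Ishigami function;
PRIM recovery uses 2000–4000 points. `scripts/acceptance.R` re-runs the
chunk-removal and reproduction calibrations at 10⁵ draws each.

## Known limitations

Tourists are not agents — their influence is collapsed into
`tourism-returns` and operator-generated pollution. There is no market
entry: the operator population can only shrink. Pollution diffusion is mass
conserving but not hydrodynamic; sudden events are spatially uncorrelated
coin flips rather than storm tracks. Cluster-scale experiment campaigns at the original scale (hundreds of
thousands of runs) are out of desk-scale reach; the
harness reproduces their machinery — design sizes, estimators, failure
definitions, box metrics — and is validated on analytic and planted-truth
oracles instead.
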