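---
title: "An on-lattice agent-based model of triple-negative breast cancer growth"
author: "tnbcABM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An on-lattice agent-based model of triple-negative breast cancer growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tnbcABM)
```

## The model

`tnbcABM` simulates the growth of an avascular triple-negative breast
cancer (TNBC) tumor as a stochastic cellular automaton on a 3D voxel
lattice. Each cell is an autonomous agent occupying one voxel of a
100 x 100 x 80 grid with 20 um cubic voxels (one MDA-MB-231 cell
diameter), at most one cell per voxel, with static walls. Time advances
in one-day steps.

Two axes of heterogeneity drive the dynamics:

* **Lineage.** *Cancer stem cells* divide without limit, symmetrically
  (two stems, probability 0.05 per division) or asymmetrically (stem +
  progenitor). *Progenitor cells* divide only symmetrically and carry a
  cycle counter; after 12 divisions they become irreversibly senescent
  and then die with probability 0.10 per day, freeing their voxel.
* **CCR5 expression.** CCR5-high cells migrate 2 voxel steps per day
  (up to 7 in the sweep experiments, hard cap 20), CCR5-low cells 1
  step. Each symmetric division's daughter converts to CCR5-high with
  probability 0.05 (0.25 in hypoxia); CCR5 status is otherwise
  inherited and never reverts.

Each day every cell alive at day start is visited once, in a freshly
shuffled uniform random order (asynchronous random-sequential updating):

1. **Quiescence.** A non-senescent cell whose 26-voxel Moore
   neighborhood is completely occupied (lattice walls count as
   occupied) becomes quiescent: it neither moves nor divides that day.
   A quiescent cell with a free neighbor at its turn reverts to the
   proliferative state.
2. **Migration.** The cell performs its daily number of voxel steps as
   a random walk: each step moves to a uniformly chosen free Moore
   neighbor; in multi-step walks the voxel it just left is excluded as
   a destination; a step with no eligible free voxel is skipped.
3. **Division.** With probability 0.20/day (stem) or 0.50/day
   (progenitor), halved in hypoxia, and only if a free Moore neighbor
   exists, the cell places a daughter on a uniformly chosen free
   neighbor.

After the sweep, each senescent cell dies with probability 0.10, the
day counter advances, and a time-series record is appended. Daughters
born during a day do not act until the next day, so a division cannot
cascade within a day. A run stops after 1080 days, at 500,000 cells
(checked at day end), or at extinction.

### Hypoxia

There is no oxygen transport model: hypoxia is geometric. A static
vessel structure — by default the well-oxygenated tissue plane at the
x = 0 face of the lattice; a line vessel is also available — defines a
per-voxel distance map, and any voxel strictly farther than 200 um is
hypoxic. Hypoxia halves the division probability of both lineages,
triples the daily step count (a CCR5-low cell walks 3 steps, a
CCR5-high cell 6), and raises the symmetric-division CCR5 conversion
probability from 5% to 25%. A cell's microenvironment is classified
once per turn, from the voxel it starts the day in.

### Treatments

* **Anti-stem-cell drug** (e.g. salinomycin-like agents): pulsed doses
  starting at day 150, every 14 days until day 248 (8 doses). Each dose
  kills every stem cell independently with the configured efficacy
  (0.50-0.90 in the experiments); progenitors are untouched. Doses are
  applied at the start of the dosing day, before the daily sweep, so
  the ordering of kill and growth is unambiguous and reproducible.
* **Maraviroc** (CCR5 inhibitor): applied throughout the run as an
  idealization; CCR5-high cells migrate at the CCR5-low speed while
  keeping their receptor label (counts of CCR5-high cells are
  unaffected). A hypoxic CCR5-high cell under maraviroc walks at the
  CCR5-low rate times the hypoxia factor: inhibition removes the
  receptor advantage, not the hypoxia response.

### Initial state

The default population is 100 cells — 19 stem/CCR5-low, 1
stem/CCR5-high, 5 progenitor/CCR5-high, 75 progenitor/CCR5-low (20%
stem, 6% CCR5-high, matching flow-cytometry measurements of MDA-MB-231
lines) — placed uniformly at random on distinct voxels of an 8 x 8 x 8
block near the vessel. `compositionFromPercentages()` rebalances the
quadruple for sweep experiments (rounding to integers that sum to the
total, with CCR5-high cells allocated to the two lineages
proportionally).

The seed block's face nearest the vessel sits 3 voxels (60 um) from
it, so its far face is exactly at the 200 um hypoxia threshold: the
whole seed starts normoxic (the threshold is strict) and hypoxia
emerges only as the tumor grows outward. Placing the block deeper
would contradict a normoxic start, which we consider part of the
modeled scenario; the offset is configurable (`seedOffset`).

## Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `pProlifStem` | 0.20 (sweep 0.10-0.40) | 1/day | stem division probability |
| `pProlifProg` | 0.50 | 1/day | progenitor division probability |
| `pSymmetric` | 0.05 | - | symmetric fraction of stem divisions |
| `divisionLimit` | 12 | divisions | progenitor budget before senescence |
| `pSenescentDeath` | 0.10 | 1/day | senescent death probability |
| `pCcr5Convert` | 0.05 | /division | CCR5-high conversion, normoxic |
| `pCcr5ConvertHypoxic` | 0.25 | /division | CCR5-high conversion, hypoxic |
| `stepsCcr5Low` | 1 | voxel/day | CCR5-low migration (0.83 um/h) |
| `stepsCcr5High` | 2 (sweep 1-7, cap 20) | voxel/day | CCR5-high migration |
| `hypoxiaProlifFactor` | 0.5 | - | division multiplier in hypoxia |
| `hypoxiaMigrationFactor` | 3 | - | migration multiplier in hypoxia |
| `hypoxiaDistance` | 200 | um | strict hypoxia threshold |
| `dims` | 100 x 100 x 80 | voxels | lattice (20 um voxels) |
| `maxDays`, `maxCells` | 1080, 500,000 | | stopping rules |

Migration rates reported in um/h map to whole voxel steps per day via
`stepsFromRate()` (round to nearest, minimum 1 for a positive rate):
0.83 um/h is 1 step, 1.67 um/h is 2, 5.8 um/h is 7.

A note on the lattice: the sources describing this model state both a
100 x 100 x 80 x 20 um grid and a "4 x 4 x 4 mm" extent, which
conflict (the former is 2 x 2 x 1.6 mm). We use the voxel-level
statement, which is the operational one; `dims` and `voxelSize` are
configurable.

## Design choices in ambiguous corners

Several rules are under-determined by the verbal model description;
the package resolves them as follows.

* **Cycle-counter inheritance.** "The new cell is assigned the same
  cycle number as its parent" is implemented *within* a compartment:
  both halves of a progenitor division carry the parent's
  post-increment count (so one fresh progenitor yields at most
  2^12 cells, which the tests verify exhaustively at a small limit),
  and a symmetric stem division's daughter shares the stem's count
  (stems are never senescence-limited, so this is bookkeeping only).
  An asymmetric stem division, by contrast, founds a *fresh* progenitor
  clone with a zero counter. The alternative — letting stem daughters
  inherit the stem's own division count — makes every progenitor born
  of a stem older than 12 divisions senescent at birth; tumors then
  crash to a near-pure stem core after the founder clones die (by
  day ~400 under defaults) and regrow as majority-stem tissue, which
  contradicts the reported behavior of this model class (sustained
  exponential growth, minority stem fractions, shrinkage only at very
  low stem numbers).
* **Update scheme.** Asynchronous random-sequential over the day-start
  snapshot. Sequential updating is what "ran through all the cells
  randomly" describes; excluding daughters prevents within-day division
  cascades.
* **No-backtracking.** The one-step-memory exclusion is defined for
  every multi-step walk (it is described for the 3-step hypoxic walk;
  single-step walks have no previous voxel).
* **Senescent migration.** Senescent cells keep migrating per their
  CCR5 class (only proliferation is lost); `senescentMigrate = FALSE`
  is available for sensitivity checks.
* **Quiescence at walls.** Out-of-bounds voxels count as occupied, so
  a corner cell with its 7 in-bounds neighbors occupied is quiescent.
* **RNG.** One seeded stream per run (R's generator; every stochastic
  choice draws from it in a fixed documented order), so a run is
  bit-reproducible from `(params, seed)` and replicate `i` of an
  ensemble uses `baseSeed + i`. All "choose a free voxel" draws are
  uniform over the eligible set.

## Shape metrics

`shapeReport()` reduces a snapshot to five dimensionless morphology
metrics, computed from the **radial profile**: the Euclidean distances
$d_i$ from each *periphery* voxel center to the centroid of all
occupied voxels, in voxel lengths. With $\mu$ and $\sigma$ the mean and
population SD of the $d_i$, $N$ the occupied-voxel count and
$r_s = (3N/4\pi)^{1/3}$ the equal-volume-sphere radius:

* chord ratio $= \mu / r_s$ (larger = more finger-like),
* chord length $= \mu / \max d_i$ (smaller = more finger-like),
* moment of inertia $= \sigma / \mu$,
* circularity $= \mu / \sigma$, the exact reciprocal of the moment of
  inertia (an algebraic identity the tests assert),
* fractal dimension: 3D box counting on the periphery voxels with box
  sides 2, 4, 8, 16, 32 anchored at the bounding-box corner; the
  dimension is the least-squares slope of $\log N(s)$ vs $\log(1/s)$
  and the fit's $r^2$ is reported.

**Periphery** means the tumor's outer boundary: occupied voxels with a
Moore neighbor in the exterior-connected free space (6-connected flood
fill from the lattice boundary). Simulated tumors are porous — senescent
death leaves transient interior vacancies — and counting pore walls as
"surface" would mix interior radii into the radial profile and bias
every metric toward compactness; interior cavities are therefore not
periphery. For solid reference shapes the two definitions coincide.

Numerical corners are signalled, not fabricated: a single-voxel mask
has an undefined chord length and moment of inertia (`NA`), a
zero-variance profile has infinite circularity, and a mask that fills
its lattice has no free-facing surface. Disconnected tumors
("self-metastases" around isolated stem cells at low stem fractions)
are measured over the union with a single global centroid by default;
`shapeReport(mask, perComponent = TRUE)` analyzes each 26-connected
component separately.

The box-counting estimate is scale-window dependent: on masks whose
extent is comparable to the coarsest boxes, those boxes see the
enclosed volume and steepen the fitted slope above the fine-scale
surface dimension (a 64-voxel cube shell fits ~2.37 over the full
window but ~2.14 over sides 2-8). The fixed 2-32 window is part of the
metric's definition here and is applied uniformly to all masks.

Oracle fixtures for all of this come from `generateFixture()`:
digitized balls, rods, ellipsoids, cube shells and two-cluster unions,
built deterministically by enumeration. The tests compare the metrics
against closed forms and brute-force enumerations of these shapes
(e.g. the exact per-scale box counts of the cube shell, or the shell
distances of a digitized ball). Digitized balls converge to the
analytic sphere as the radius grows; at radius 5 the discretization
error of the chord ratio is still ~0.13, so the +-0.08 sphere band is
asserted from radius 10 upward.

## Growth-curve fitting

`fitExponential()` fits ln(total cells) against day by ordinary least
squares. The untreated model has two regimes: the initial 80
progenitors form a synchronized transit-amplifying burst (~0.3/day)
that exhausts its division budget in about
`divisionLimit / pProlifProg` = 24 days and decays over a few
senescent-death e-foldings, after which growth is stem-driven and
cleanly exponential (~0.6%/day under defaults) up to the 500,000-cell
stop around day 480-550. The default fit window for simulations
therefore opens at
`divisionLimit / pProlifProg + 2 / pSenescentDeath` (= 44 days) — a
parameter-derived transient timescale, not a data-dependent choice —
and closes at the end of the run or the day before the first dose.
For bare data frames the window simply starts when the population
first exceeds twice its initial size. Per-replicate fits under
defaults give r^2 ~ 0.96-0.99; the replicate-averaged curve, which is
how ensembles are reported, fits with r^2 > 0.99.

## Experiments and reproducibility

`runEnsemble()` runs the Cartesian product of sweep values x
replicates with seeds `baseSeed + index`, returns one labelled
time-series table plus snapshot masks, and (optionally) writes
per-run CSVs, mean curves and a checksummed summary JSON; identical
inputs reproduce every file bit-identically. `conditionComparison()`
summarizes day-matched populations (last observation carried forward
for runs that stopped at the cell cap) and applies Welch t-tests —
one-sided for directional claims, raw p-values, no multiplicity
correction, matching how single pairwise comparisons are reported for
this model. Example desk-scale configurations (50,000-cell stop) for
the control/hypoxia/maraviroc/anti-stem conditions ship in
`inst/extdata/`.

### Problem sizes used in the test suite

The packaged tests exercise the full default lattice but scale
stopping rules to desk size, which we consider adequate sampling of
each claim: growth-law fits use 4 replicates to the full 500,000-cell
stop; morphology ensembles use 12 replicates to a 50,000-cell stop
(tumors of radius ~20 voxels, comfortably clear of the walls);
condition orderings use 8 matched-seed replicates per arm at day 100
(day 250 for maraviroc, whose effect needs an appreciable CCR5-high
fraction to bite); treatment dynamics use a 40 x 40 x 32 lattice where
crowding caps the population at a few tens of thousands of cells,
keeping multi-hundred-day dosing runs cheap. At 50% dose efficacy,
stem survival through all 8 doses is a ~25% event per replicate, so
the relapse check runs a fixed 8-seed ensemble known to contain
surviving-stem replicates and asserts the conditional claim on them.

## What the model does and does not capture

Passing tests show that the implementation follows its rules exactly
and that the rules reproduce the qualitative biology built into them:
contact inhibition, lineage exhaustion, hypoxia-driven dispersal and
growth acceleration, relapse from incompletely eradicated stem pools,
and migration/proliferation-controlled morphology classes. They do not
validate the model against real tumors. In particular there is no
oxygen or chemokine transport, no vasculature or angiogenic switch, no
metastasis, no pharmacokinetics (maraviroc is total and instantaneous),
no sub-daily timing, and no anisotropic host tissue such as mammary
ducts; cell-size and rate parameters are literature point estimates
for MDA-MB-231-like lines. Tumors at the 500,000-cell stop approach
the lattice walls, which visibly flattens shape metrics at that scale —
morphology ensembles are therefore measured at the 50,000-cell stop.
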