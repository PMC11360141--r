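---
title: "Modeling collective mesendoderm migration with mesendosim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling collective mesendoderm migration with mesendosim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesendosim)
```

## The model

`mesendosim` implements a three-dimensional Cellular-Potts (Glazier-Graner-
Hogeweg) model of a *Xenopus* dorsal-marginal-zone (DMZ) mesendoderm explant
migrating on a flat substrate. Each cell is a set of voxels on an integer
lattice; the configuration evolves by voxel-copy attempts accepted with a
Boltzmann criterion on the change of an effective energy

$$
H \;=\; \sum_{\text{neighbors } i,j} J\big(\tau(\sigma_i), \tau(\sigma_j)\big)
      \,\big[\sigma_i \neq \sigma_j\big]
\;+\; \sum_{\text{cells}} \lambda_{volume}\,(V_{cell}-V_{target})^2
\;+\; \sum_{\text{links}} E_{link},
$$

with contact energies `J` over the four lattice types (medium, substrate,
leader, follower), a quadratic volume constraint, and mechanical link
objects:

* **cell-cell** and **follower-substrate** links are Hookean,
  $E = \lambda\,(l-L)^2$, evaluated between cell centroids (or a fixed
  substrate anchor), representing cadherin junctions and integrin
  attachments;
* **lamellipodium** links attach a leader's centroid to a substrate anchor
  with constant tension, $E = \lambda_{Lamellipodia}\, l$, so the traction
  force magnitude is length-independent, as appropriate for a stalled
  protrusive process.

A copy attempt that lowers (or preserves) $H$ is always accepted; an increase
$\Delta H$ is accepted with probability $e^{-\Delta H/T}$. One Monte-Carlo
step (MCS) performs one attempt per non-substrate lattice site and represents
5 s of real time; one voxel edge represents 6 um, so a 5x5x5-voxel cell is a
30-um cube and 1 voxel/MCS corresponds to 4320 um/h.

Link turnover is Poissonian: an extension-retraction (or break) event fires
each timestep with probability $1 - e^{-\zeta}$, with separate rates for
leader lamellipodia (`zeta_lamellipodia`), follower-substrate attachments
(`zeta_substrate`) and - when intercalation is enabled - cell-cell links
(`zeta_tissue`).

### Cohesotaxis

When a leader cycles its lamellipodium, the new link's direction is chosen
among the cell's *free-edge voxels* (voxels in face contact with medium).
Free-edge voxels are ranked by their cumulative Euclidean distance to the
cell's *cell-cell border voxels* (voxels touching another cell), and one is
drawn from a normalized logistic weight vector evaluated at evenly spaced
points of the fixed window $[-5, 5]$ with steepness $2^\kappa$. Because the
weights increase along the ranking, probability mass concentrates on the
voxels farthest from cell-cell contacts: the cell protrudes away from its
neighbors, which for a leading-row cell means forward. $\kappa = -6$ is
indistinguishable from uniform sampling (no migratory bias); $\kappa = +6$
saturates into a step that samples uniformly from the far-from-contact half
of the ranking. The rule is direction-agnostic - it works identically for
four explants facing each other - which is what permits the in-the-round
experiments.

Two textual readings of the ranking exist ("lowest cumulative distance"
versus "most opposite from cell-cell contacts"). We implement the
away-from-contacts reading as the default and expose the alternative as
`bias_toward = "near"`. During development we compared both and also a
sliding-midpoint logistic that concentrates all mass on the single
extreme voxel: because the cumulative distance is a convex function of
position, its maximum always sits at cell corners, and near-deterministic
corner selection produces pathological diagonal pulls. The saturating
fixed-window form, which spreads mass evenly over the far half, is the
best-behaved of the three and is the shipped default.

### Intercalation

With `zeta_tissue > 0`, each cell-cell link breaks per timestep with
probability $1-e^{-\zeta_{Tissue}}$; one endpoint of a broken link (chosen
uniformly) then forms a new link to a uniformly chosen lattice-adjacent cell
it is not yet linked to, provided both cells hold fewer than
`max_reformed_neighbors` (default 4) cell-cell links. Initial links connect
*all* face-adjacent cell pairs (an interior cell may start with 5), and the
cap constrains only reformation. This fluidizes the tissue and lets radial
(top-down) intercalation emerge: upper-layer cells descend to the substrate
and the explant flattens, which is measured by `substrate_cell_count()`.

## Geometries and measurement protocols

`dmz_state()` builds the 8x4x2-cell explant (64 cells, 125 voxels each) on
the substrate plane, assigns the eight bottom-layer leading-edge cells as
leaders, links every adjacent cell pair, anchors bottom-layer followers to
the substrate, and gives each leader an initial lamellipodium through a
uniformly chosen free-edge voxel (the cohesotaxis bias applies only from the
first turnover onward). `itr_state()` arranges four such explants facing a
central cell-free square (side = one explant width, 40 voxels), changing no
other parameter.

Migration speed follows the 2-h protocol: 1440 MCS with centroids sampled
every 200 MCS; the speed is the mean net displacement of the center four
leading-row cells along the facing axis, in um/h. ITR closure speed is the
absolute least-squares slope of the gap's equivalent side length
$\sqrt{A(t)}$ over the closing phase. Two measurement choices matter here:

* the **closing phase** ends when the free area falls below 5% of its
  initial value (`closed_fraction`). Collided explant edges always retain a
  thin seam of medium columns, and including that indefinite plateau in the
  fit would dilute the closing-phase slope;
* because two opposing edges advance at once, the side-length rate is about
  twice a single edge's advance; `itr_closure_speed()` reports both (`speed`
  and `per_edge`), and all comparisons in the package use the same
  convention on both sides.

The lamellipodia-blocking experiment (`run_retraction_validation()`) runs
200 MCS (about 17 min) to reach steady migration, then blocks the formation
of new lamellipodium links; existing links expire through their Poisson
lifetime and the explant retracts. Retraction distance is the mean rearward
leading-row displacement from block onset, in um.

## Calibrated defaults

The published parameter table for this model is not machine-readable, so the
shipped defaults were *calibrated*, not transcribed, against four gates
(re-checkable with `calibration_gates()`): no cell fragmentation over
1440 MCS, volumes within +/-30% of target, monotone forward leading-edge
displacement, and a DMZ migration speed inside a 50-200 um/h band around the
107 um/h reported for biological DMZ explants. The calibrated set is:

```{r}
sim_config()
```

Notable choices, with rationale:

* `temperature = 16`, `lambda_volume = 2`, `v_target = 125`: membrane
  fluctuation amplitude and a volume constraint that keeps cells within a
  few percent of target at this temperature.
* `contact_energy`: cell-cell 4, cell-medium 4, cell-substrate 3. The
  mildly adhesive substrate supports spreading of the bottom layer, but
  values much below the cell-medium coefficient let pure Potts wetting flood
  free substrate far faster than migration - the ITR gap would fill in
  minutes of simulated time - so substrate attachment is carried mainly by
  the link objects, as the model intends.
* `lambda_lamellipodia = 1200` against `lambda_tissue = 150` keeps the
  leading row's elastic tether stretch near 4 voxels: leaders stay in
  physical contact with the tissue (detached leaders lose their cell-cell
  borders and with them the cohesotaxis signal).
* `zeta_lamellipodia = 0.08` (mean lamellipodium lifetime about 1 min):
  faster cycling re-rolls unfavorable protrusion directions before they can
  reorient the collective.
* `zeta_substrate = 0.2` sets follower-substrate friction: each re-anchoring
  dissipates the elastic drag accumulated since the last one.
* `substrate_link_target_length = 3` (vs 5 for cell-cell links) is the
  height of a bottom-layer centroid above the substrate plane, so a resting
  follower carries no elastic energy.
* `connectivity_constraint = TRUE`: a voxel-copy attempt that would split
  the losing cell's face-connected voxels within the local 26-neighborhood
  is rejected. At the working temperature an unconstrained CPM pinches off
  cell fragments at a rate incompatible with the fragmentation gate at any
  parameterization we found with adequate migration speed; the local
  constraint is the standard remedy and leaves boundary fluctuation
  statistics otherwise untouched. It is checked only for moves that pass the
  Metropolis draw, which is equivalent to treating such moves as forbidden.
* cell annihilation (a cell losing its last voxel) removes the cell and its
  links from the energy; the incremental $\Delta H$ accounts for exactly
  this, so incremental and from-scratch energies agree to rounding error on
  every legal attempt. The quadratic volume penalty makes annihilation
  astronomically rare in practice.

## What the experiments show (and what they do not)

The packaged experiments reproduce the model's qualitative program:
cohesotaxis ($\kappa$) raises single-explant speed; the in-the-round
geometry closes substantially faster than a single explant migrates, and its
dependence on $\kappa$ is much weaker (relatively) than the single explant's;
passive intercalation accelerates closure, monotonically in `zeta_tissue`,
while moving cells onto the substrate; blocking lamellipodia produces
retraction that controls lack; and speed is most sensitive to the
leading-edge parameters.

Two quantitative caveats, measured during development and reproducible with
the packaged experiments, deserve emphasis:

* **The cohesotaxis effect size is modest at these conditions.** With eight
  bottom-row leaders whose free edges are dominated by the forward face,
  uniform sampling ($\kappa=-6$) is already forward-biased by geometry, so
  the $\kappa$ contrast is of order 10-20 um/h against replicate scatter of
  similar magnitude; at $n = 10$ the two-sample test typically lands between
  $p \approx 0.01$ and $p \approx 0.2$ depending on the seed set. In a
  monolayer variant, where leader top surfaces are exposed and unbiased
  protrusion is nearly isotropic, the same mechanism yields a much larger
  contrast - the effect is real but its expression depends strongly on how
  much non-forward free surface leaders carry.
* **Closure-speed replicates are heavy-tailed.** Occasionally a replicate's
  collective reorients (the bias rule is direction-agnostic, so a rotated
  state is self-consistent) and scores a low axis-projected speed, inflating
  group variance.
* **A mild $\kappa$ sensitivity persists in the ITR.** Closure at
  $\kappa=-6$ runs about 10-15% slower than at $\kappa=6$ with tight
  replicate scatter, so a one-way ANOVA across $\kappa$ levels can reach
  significance at $n = 10$ per level even though the relative effect is far
  smaller than in the single explant. With the default gap of one explant
  width (240 um), closure retains a traction-driven phase in which leader
  protrusion direction still matters; a nearly juxtaposed arrangement would
  likely be collision-dominated and fully $\kappa$-insensitive.

The synthetic-data generators (`synth_trajectory()`, `synth_area_record()`)
emulate only the *shape* of recorded data - linear drift plus Gaussian
jitter, and a linearly shrinking gap side - so that the metrics layer can be
tested against closed-form expectations independently of the engine. They do
not emulate collective rotation, stalling, or closure-phase curvature; tests
passing on them validate unit conversions and estimators, not engine
dynamics.

## Problem sizes

Packaged experiments default to the `"standard"` lattice preset. The test
suite and the acceptance script use the `"reduced"` preset (trimmed lateral
margins and head-room around an unchanged explant and unchanged migration
room) together with scaled designs - 3 $\kappa$ levels, +/-20% and +/-50%
sensitivity levels with 5 replicates, 600-720-MCS sensitivity runs, and
1200-MCS ITR runs with early stopping at effective closure - chosen so that
a full pass is comfortable on a single CPU while preserving every protocol's
structure (replicate counts of 10 wherever a comparison is made, the 2-h DMZ
protocol for the cohesotaxis experiment, and the 200-MCS sampling cadence).

## Reproducibility

Every stochastic component draws from a generator seeded from the
experiment's base seed (`seed_i = base + i` per replicate, logged in each
result), and identical seed + config replays a run bit-identically - the
engine's random stream is implemented in the package and does not depend on
R's RNG state; R's RNG is used (and seeded) only for initial lamellipodium
directions and the R-level single-step utilities.
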