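---
title: "Methods: the nephrosim tumor-response model and its calibration"
author: "nephrosim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the nephrosim tumor-response model and its calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nephrosim)
```

## The cytokinetic model

`nephrosim` simulates the volume response of a Wilms' tumor to preoperative
vincristine/actinomycin chemotherapy with a deterministic, mean-field,
discrete-time compartment model. The state vector resolves, hour by hour
of age:

* stem cells in the cycle phases G1, S, G2, M and in dormancy (G0);
* LIMP progenitors (limited mitotic potential) in the same phases, further
  indexed by their remaining mitosis budget `NLIMP .. 1`;
* terminally differentiated cells (a single pool);
* apoptotic and necrotic cells awaiting product clearance, age-resolved up
  to `TA` and `TN` hours.

All transitions act as expected fractions of each equivalence class rather
than per-cell random events. This mean-field choice matters downstream:
it makes the predicted volume reduction a deterministic, monotone function
of the cell-kill ratio, which is what renders the binary-search adaptation
well posed. The hourly update is therefore one sparse nonnegative matrix
(`transition_operator()`), and cells are conserved except at mitosis (one
extra cell per completed M) and at apoptosis/necrosis product clearance.

Assumptions inherited from this formulation: no immune interaction, no
microenvironment (oxygen, nutrients, matrix), no pharmacokinetics or
resistance evolution, spatially homogeneous kinetics.

### Time step and phase split

The time step is one hour and all durations are rounded to whole hours;
the reference durations are already integer hours. The cycle length `Tc`
is split into G1:S:G2:M = 9:8:4:2 (the proportions of a 23 h mammalian
cycle), re-rounded by largest remainder so the phases always sum to the
rounded `Tc` with every phase at least one hour. Nothing downstream
depends on the split beyond the total cycle length, because drug effect is
not phase-specific; the constant is isolated in `split_cycle_phases()`.

### Growth rate and stable composition

The transition operator is block-triangular: only the stem block feeds
itself (stem daughters), LIMP budgets strictly decrease, and the
differentiated and dead pools are terminal. The dominant growth factor
$\lambda$ per hour is therefore the root of the stem block's renewal
equation
$$ K \lambda^{-T_c}\Big[(1-P_{sleep}) + P_{sleep}\,P_{G0\to G1}
   \sum_{j=1}^{T_{G0}} q^{\,j-1}\lambda^{-j}\Big] = 1,
   \qquad K = (1-R_A)^{T_c}(1+P_{sym}),\; q = 1-R_A-P_{G0\to G1}, $$
found by bisection to $10^{-13}$. When stem renewal is not sustained
(`growth_rate()` root $\le 1$ or absent), the code falls back to shifted
power iteration on the whole live sub-operator, whose dominant factor is
then set by the slowest-decaying lineage. The test suite cross-checks the
root against power iteration (agreement to $10^{-9}$) and against the
log-slope of a 2000-hour explicit trajectory (to $10^{-4}$).

The stable composition — the state an untreated, exponentially growing
tumor settles into — is the dominant eigenvector. Downstream of the stem
block every compartment is a pure aging chain, so the eigenvector is
assembled in closed form as geometric cascades in (survival/$\lambda$);
the tests verify $A v = \lambda v$ to machine precision and agreement with
a 3000-hour explicit run to $10^{-3}$ per aggregated fraction. With the
reference parameters the tumor is 27.3% proliferative, 19.4% dormant,
49.9% differentiated and 3.4% dead.

### Calibrating the clock to the doubling time

The parameter set contains both the mechanistic rates and a sampled tumor
doubling time `Td`, but the emergent doubling time of the raw reference
kinetics is about 3.7 days, not `Td`. How `Td` should constrain the
kinetics is genuinely open; we resolve it with a single *time dilation*
factor `s` in `[0.1, 10]`: all durations are multiplied by `s` and all
per-hour rates divided by `s`, so one hour of the dilated system is `1/s`
hours of the original dynamics. Dilation leaves the stable composition
and all per-cycle probabilities invariant — it only slows the clock —
which is exactly the degree of freedom `Td` should control. The search
starts from the exact continuous-time solution `s0 = 24 Td / d(1)` and
refines by bisection to absorb whole-hour rounding; the emergent doubling
time matches `Td` within 1%. Calibration is on by default
(`fit_ckr(calibrate = )` switches it off, leaving `Td` inert).

Two limitations follow. First, whole-hour rounding quantizes the
achievable doubling times; within the `[0.1, 10]` bracket the 1% match is
achievable in practice for every admissible draw we have tested. Second,
the bracket itself excludes roughly a third of the sampled virtual
patients (fast raw kinetics combined with a long sampled `Td`, or
non-growing parameter combinations); these are replaced by fresh draws,
which extends the exclusion of spontaneously regressing tumors and biases
the retained ensemble slightly towards shorter doubling times.

## Treatment effect

An administration at day `d` acts at the start of that day as an
instantaneous proportional kill: the drug-specific cell-kill ratio
(CKR<sub>VCR</sub> = 0.4·CKR<sub>Total</sub>,
CKR<sub>ACT</sub> = 0.6·CKR<sub>Total</sub>) of **every viable cell** —
cycling, dormant and differentiated — moves to the start of the apoptosis
clearance pathway. Same-day VCR and ACT are applied sequentially; for
proportional kills the order is immaterial. Total cell count is conserved
exactly; killed cells keep occupying imaging-visible volume until their
apoptotic products clear after `TA` (dilated) hours, consistent with
volumes that include regressive tissue.

Making the differentiated pool susceptible was a deliberate design
decision. The alternative — sparing differentiated cells and killing only
the proliferative + dormant pools — caps the attainable volume reduction
near the non-differentiated share of the stable composition (~50%), so
even the high-risk patient's observed 54.1% reduction would be marginal
and the low-risk patient's 91.6% unreachable at any CKR; no virtual
patient could then satisfy the adaptation criterion. Under the all-viable
reading (the CKR is defined as the fraction of *tumor cells* affected by
the dose), the observed reductions of all three patients sit comfortably
inside the attainable range and the adapted medians land on the expected
dyadic values without any tuning. The cost is that a purely proportional
kill leaves the *live* composition unchanged, so the model does not
reproduce a post-treatment shift towards differentiated tissue; capturing
that would require phase- or category-specific pharmacodynamics that the
single-CKR abstraction deliberately omits.

## Clinical adaptation

Ground truth per patient is the pre/post-chemotherapy volume pair — by
default from manual segmentations (126.25→10.58, 526.99→70.72,
235.64→108.22 cm³ for P1–P3), switchable to the ellipsoid-formula
database values — plus the recorded administration schedule (day offsets
from the pre-chemo MRI) and the post-surgical histology fractions. The
simulation runs from day 0 (pre-chemo MRI) to the last administration
plus the recorded post-treatment interval, anchored to the last
administration of any drug.

`binary_search_adapt()` starts at the midpoint of `[0, 1]`; each iteration
simulates the plan at `split_ckr(x)` and computes the clinical adaptation
error `100·|dv_pred − dv_obs| / dv_obs`. Within the 5% tolerance the
search stops; an over-prediction lowers the upper bound, an
under-prediction (including negative predicted reductions, i.e. growth —
signed values are compared) raises the lower bound; if the bounds close
below `1/1024` (ten halvings past the first iterate, below any reported
precision) the virtual patient has no admissible value. All tried values
live on the dyadic grid, which is why ensemble medians concentrate on
values like 0.875 and 0.500.

The *histology criterion* requires a virtual patient's initial
proliferative fraction to reach the patient's IFPC bound. The bound is
compared against the proliferative fraction alone (dormant cells are
excluded): the IFPC is constructed from blastema, the actively dividing
component. Because the stable proliferative fraction across sampled
virtual patients spans roughly 15–40%, the criterion is mild for the
low-risk patient (IFPC 8.2%) and strict for the high-risk one (32.8%),
which mirrors its clinical intent.

Virtual-patient sampling is uniform within ±50% of the reference values
(probabilities clipped to `[0, 1]`, `NLIMP` uniform on the integers
{2, 3, 4}), with a counter-based substream per (master seed, VP index) so
results are independent of execution order and exactly reproducible.

## Geometry

Masks are binary occupancy grids with per-axis spacing and origin in mm,
read and written in MetaIO (`.mhd` + `.raw`) and NRRD (attached header,
`raw` or `ascii` encoding); values are thresholded at > 0 because clinical
annotations arrive as label maps. Resampling to the 1 mm isotropic
simulation grid maps physical coordinates (spacing and origin, voxel-
centred, 0-based), not array indices, so the anisotropic thick-slice
spacings of clinical MRI are handled correctly; nearest-neighbour
interpolation preserves binary labels and, by the tests, volumes of
convex-ish shapes to within 5%.

The synthetic-mask generator replaces patient segmentations that cannot
be redistributed: a randomly oriented superellipsoid (exponent 2–3,
mild anisotropy) perturbed by a few seeded low-frequency cosine modes
(`irregularity` defaults to 0.15, reflecting that real Wilms' tumors are
non-ellipsoidal), voxelized and threshold-bisected to hit the target
volume within 1%. It emulates the size and smooth irregularity of real
tumors but not lobulation, necrotic cavities or infiltrative margins, so
geometric conclusions from these fixtures are limited to volume-level
behaviour — which is all the aggregate model consumes.

In spatial mode every occupied voxel carries its own compartment state
(seeded at capacity 10⁶ cells/mm³ in stable composition) and a
restructuring scan runs every 24 simulated hours: voxels below 10% of
capacity donate their contents to their least-loaded occupied 6-neighbour
and vacate; voxels above capacity spill the excess to their least-loaded
unoccupied-or-underfull 6-neighbour, occupying it if needed. The scan is
raster-ordered with seeded tie-breaks and conserves cells exactly. Note
that a *uniformly* diluted mesh consolidates only until every survivor
exceeds the removal threshold, so the occupied-voxel count tracks total
mass within a factor of about 1/threshold rather than exactly; boundary-
driven progressive shrinkage behaves more tightly. Because every rule is
proportional, aggregate and spatial modes agree on the predicted volume
reduction (tested to 0.1 percentage points); ensembles therefore run in
aggregate mode and spatial mode serves geometry-producing runs.

## Statistics

Group comparisons follow the nonparametric convention: tie-corrected
Kruskal–Wallis H (via `stats::kruskal.test`) with a χ² reference on k−1
degrees of freedom; Dunn's pairwise z from pooled-rank mean differences
with tie correction and Bonferroni adjustment (z is positive when the
first-listed group has the higher mean rank; the two-group z² equals H
identically); Mann–Whitney U with a tie-corrected normal z without
continuity correction, plus an exact enumeration method for untied
samples up to 8 per group. Effect size is r = |z|/√n with n the combined
size of the two compared groups — validated by 5.62/√40 = 0.89 and
17.60/√400 = 0.88 — labelled small/medium/large at 0.1/0.3/0.5.
Quartiles use linear interpolation (R type 7); the convention is isolated
in `summarize_values()`. Two-sided 0.05 is the significance threshold.

## Numerical choices and degenerate inputs

* Renewal-root bisection tolerance $10^{-13}$; power-iteration fallback
  stops when the eigenvalue estimate is stable to $10^{-13}$ over five
  iterations (shift 0.5 regularizes the near-periodic cycle structure).
* Calibration targets the doubling time within 0.5% internally, reported
  tolerance 1%.
* An empty treatment plan simulates free growth; a tumor that grows gives
  a negative reduction. A fully cleared tumor reports composition
  (0, 0, 0, 100) by convention so percentages always sum to 100.
* `split_ckr`, kill fractions, probabilities and histology fractions are
  validated to `[0, 1]`; vital-tissue fractions must sum to 1 within
  $10^{-9}$; empty filter subsets summarize as `n = 0` without error.
* Masks with non-3D headers, unreadable payloads, or targets smaller than
  one voxel raise typed errors.

## Problem sizes

The shipped test suite and the acceptance script are sized for a single
CPU: ensembles of 50–60 virtual patients per patient (the qualitative
medians are already stable from about 20), trajectories of 2000–3000
hours for the oracle comparisons, and sub-centimetre spatial fixtures for
the mode-equivalence and restructuring tests. A full 200-VP aggregate
ensemble for one patient takes well under a minute; spatial runs scale
linearly in occupied voxels and are intended for single simulations, not
ensembles.

## Known limitations

* Treatment is a phase-blind proportional kill; delayed drug effects,
  resistance, and composition shifts towards differentiated tissue are
  outside the abstraction.
* The clock-dilation bracket `[0.1, 10]` excludes some admissible-looking
  parameter draws (see above), slightly biasing ensembles.
* The histology criterion compares a model quantity (initial proliferative
  fraction) with a histology-derived bound; both are approximations and
  the comparison inherits their uncertainty.
* Mesh restructuring is one consistent realization of morphological
  adaptation; alternative donation rules would change geometry but not
  aggregate volumes, which all reported quantities are based on.
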