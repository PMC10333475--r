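---
title: "Arch morphometry and reduced-order coarctation hemodynamics: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Arch morphometry and reduced-order coarctation hemodynamics: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coarckit)
```

## Scope

Aortic coarctation (CoA) is a congenital narrowing of the aortic arch,
usually at the isthmus.  Pediatric CTA workups characterise the arch by its
shape family — *gothic* (triangular), *crenel* (rectangular), *romanesque*
(round) — classified by the height-to-width ratio A/T, by chord angles
(AAO-DAO, TAO-DAO), and by the level diameters AOA and D1–D5 whose ratios
to the ascending aorta define arch hypoplasia.  Doppler echocardiography
adds the peak systolic pressure gradient (PSPG) across the stenosis via the
simplified Bernoulli formula, and computational fluid dynamics can resolve
the pressure field itself.

`coarckit` implements this analysis chain end to end on *synthetic* data:
a parametric arch generator with cohort sampling, the morphometric
constructions, the group statistics, and a reduced-order (1D network)
pulsatile flow model of the stenosed gothic arch.  Because no imaging data
accompany the study conditions we target, the generator is first-class: it
provides the ground truth that every downstream stage is validated against.

## Parametric arch geometry

Arches are planar centerlines in an oblique-sagittal plane (x horizontal,
y vertical).  The centerline runs from the ascending end at the origin, up
a straight ascending limb, across a top section, and down a straight
descending limb through the mid-descending landmark, ending a configurable
distance below it.  The construction is closed-form:

* the two limb lines are tilted so their mutual angle equals the requested
  AAO-DAO angle (the split between ascending and descending tilt is a free
  parameter);
* for gothic and romanesque shapes the top is the circle inscribed between
  the limb lines whose topmost point sits exactly at height A; the crenel
  top is flat at height A with circular corners;
* the width T is the distance between the ascending-end and mid-descending
  landmarks, so A, T and A/T are exact by construction;
* the TAO-DAO angle is realised by a one-dimensional root solve on the
  position of one branch landmark along its limb.  Large angles move the
  LSCA landmark down the descending limb; small angles move the
  brachiocephalic landmark down the ascending limb.  Either way both
  chords stay exactly on the limb lines, preserving the AAO-DAO angle.

Radii come from a monotone cubic interpolant through the six station knots
(AOA, D1–D5), so measured level diameters reproduce the generator inputs
exactly; an optional stenosis multiplies the local radius by a
cosine-tapered factor reaching `1 - severity` at the throat.  Infeasible
parameter combinations (for instance a tall arch with a wide AAO-DAO
angle, which leaves no room for the inscribed top) raise errors naming the
conflicting parameters.

Cohorts are sampled per group from published `(mean, SEM, n)` summaries,
each variable as `Normal(mean, sem * sqrt(n))` truncated to its feasible
range.  Two points deserve emphasis:

* **The dispersion column is interpreted as SEM.**  Under this reading the
  summary-statistics one-way ANOVA reproduces six of the published group
  statistics to better than 1% (D1/AOA 1.168, D2/AOA 0.440, D4/AOA 3.155,
  D5/AOA 4.725, AAO-DAO 7.32, weight 2.754); under an SD reading none
  reproduce.  The remaining rows (D3/AOA, A/T, TAO-DAO, age, PSPG) do not
  reproduce under either reading — recomputation gives 5.95, 47.8, 1.69,
  2.05 and 0.64 — and are therefore excluded from validation.
* **Variables are sampled independently**, which can draw angle
  combinations that no planar arch realises (for example a near-vertical
  limb pair with TAO-DAO above ~110 degrees).  The sampler first scans the
  free limb-split parameter, and only if that fails redraws the *two
  angles alone*, leaving the A/T and diameter-ratio marginals exactly
  untruncated.  Mean A/T over ten thousand gothic draws sits within 0.001
  of the target.

Sampled cases carry their coarctation in the drawn D3 (a measured,
stenosed caliber), so their `stenosis_severity` is zero; the explicit
stenosis element is reserved for the hemodynamic phantom.  Group label and
A/T are deliberately independent inputs: the published gothic group mean
(0.70) lies below the 0.8 classification threshold, so labels in the
source cohort cannot have been pure threshold calls.

## Morphometry

All constructions are coordinate-free.  "Horizontal" means along the chord
between the ascending-end and mid-descending landmarks (the T-line) and
"vertical" its normal, which makes every output invariant to rigid motions
in the plane; the apex search is restricted to centerline points that
project between the two T-line landmarks so that the descending aorta
below the mid-descending landmark cannot masquerade as the apex.  The
AAO/DAO/TAO chords join landmark points along the centerline (an
inner-border offset was considered and rejected: only centerline+radius
is generically available, and the chord-angle contract must hold exactly
for the generator round trip).  AAO-DAO is reported as the acute angle
between the chord lines, matching the published magnitudes near 27-35
degrees; TAO-DAO as the interior angle at the LSCA landmark.

Level diameters on the analytic path evaluate the radius interpolant at
the station.  On voxel data the pipeline is: exact Euclidean distance
transform (compiled, separable lower-envelope algorithm), then a
medialness-weighted minimal path between the arch-end landmarks over the
foreground voxel graph — the edge cost scales the Euclidean step by
`(R_max / dt)^4`, which pins the optimum to the medial axis — followed by
spline smoothing with endpoint re-anchoring.  The maximal inscribed-sphere
radius (the distance-transform value) doubles as the local diameter,
searched over a ±2.5 mm arc-length window around each station
(configurable; the window matters only on extracted centerlines).  At
0.4 mm spacing the recovered A/T sits within 0.1% of truth, an order of
magnitude inside the 2% verification band.

Classification is a total piecewise-constant map with breakpoints at
A/T = 0.6 and 0.8 (both boundary values classify as romanesque — "in
between" is read inclusively); hypoplasia flags use strict inequalities at
60/50/40% of the ascending aorta; the coarctation flag compares the
narrowest level against half a reference caliber (default the
mid-descending D4).

## Cohort statistics

`anova_from_summary()` is the package's own contribution here: with
`sd = sem * sqrt(n)`, between-group and within-group sums of squares follow
directly from the triplets, and the statistic equals raw-data ANOVA
exactly whenever the summaries came from the raw data (the suite checks
this identity on random datasets to 1e-9, and the two-group special case
against the pooled t squared).  Raw-data batteries delegate to the
standard tests: Kolmogorov–Smirnov normality per group (parameters
estimated from the sample — the Lilliefors caveat applies and is the
reason the KS route is reported, not used for gating), mean-centered
Levene, then pooled ANOVA/Student t if Levene does not reject at 0.05 and
the Welch analogue otherwise.  The chi-square is the uncorrected Pearson
statistic.  No multiple-testing correction is applied across table rows
(none is stated for the source analysis); pairwise comparisons are plain
t-tests.

## Reduced-order hemodynamics

The reference 3D finite-volume simulation is replaced by a 1D rigid-tube
network that preserves every stated physical parameter: blood density
1050 kg/m³, dynamic viscosity 0.0035 Pa·s (the source calls this a
"kinematic viscosity coefficient", but the units are those of dynamic
viscosity and it is implemented as such), laminar rigid-wall flow, inlet
velocity peak 1.2 m/s, period 0.8 s, time step 0.005 s, at most 200
iterations per step, last-cycle extraction.  Each tapered segment
contributes viscous (Poiseuille integrated over the taper), convective
(dynamic-pressure exchange) and inertial losses; the coarctation is a
Young–Tsai-type element with viscous, turbulent-expansion and inertial
terms (`Kt = 1.52`, `Ku = 1.2`, `Kv = 32 (Ls/D0)(A0/As)^2` — the viscous
constant reduces exactly to Poiseuille flow through the throat).

At each time step the unknowns are the outlet flows and the inlet
pressure; the mass balance is eliminated exactly (hence machine-precision
conservation at every step) and the remaining per-outlet pressure
equations are solved by damped Newton iteration with a trust region.
Three numerical choices deserve a note:

* **Outlet discharge/entry losses.**  Outlets hold static pressures.  On
  discharge a fraction 0.3 of the dynamic head is charged (partial
  pressure recovery in the continuing vessel); on retrograde flow drawn
  *from* a reservoir the full dynamic head plus an entrance loss (1.2) is
  charged, since that fluid must be accelerated from rest.  Besides being
  the physically consistent static-to-static budget, the asymmetry makes
  flow circulating between equal-pressure outlets strictly dissipative —
  a purely reversible network admits spurious large-circulation
  equilibria that destabilise the diastolic solve.  Both coefficients are
  configurable and set to zero in the closed-form limit tests.
* **Trust region and substepping.**  The quadratic loss terms admit
  distant unphysical roots; Newton steps are capped, converged roots with
  flows far beyond the inlet scale are rejected, and a stalled step falls
  back to a cold start and then to halved backward-Euler substeps.
* **Laminar friction is retained even where Re exceeds 2300**, matching
  the stated laminar assumption; Reynolds numbers are reported as a
  diagnostic instead of switching closure.

The inlet waveform shape is unspecified in the study conditions (only the
peak); the default is a half-sine over a systolic fraction of 0.35 with
zero diastolic inflow.  Outlet pressures are likewise not printed; the
defaults are 120 mmHg at the three arch branches (upper-limb pressure in
an upper-body-hypertensive infant) and 65 mmHg at the descending outlet.
These levels matter: the transstenotic drop of a calibrated severe
coarctation is head-dominated, so the reported ~58 mmHg gradient is
reproducible precisely because the upper/lower pressure difference of a
severe CoA is of that order.  The default network calibers follow the
gothic-group morphometry at pediatric scale (ascending 12 mm tapering
over the arch to a 6.8 mm distal arch, isthmus reference widening to the
8.4 mm descending) with branch calibers sized so that the branches absorb
their flow share near the upper-limb pressure — the combination under
which the model reproduces the full set of reported flow conditions
(proximal stations 1.2–1.7 m/s, stenotic jet above 2 m/s) rather than any
one of them in isolation.

Calibration bisects the throat area ratio until the simplified Bernoulli
gradient `4 v_jet^2` from the solver's peak jet velocity matches a Doppler
PSPG target (default 57.2 mmHg) within 0.1 mmHg.  The jet velocity is not
monotone in the contraction ratio — it peaks where the throat begins to
limit descending flow — so calibration scans for the peak and then bisects
the *severe* (flow-limited) branch, the regime of a tight coarctation; a
`branch = "mild"` option selects the other side.  The transstenotic
pressure difference is read between the junction into the
stenosis-bearing segment (the pre-stenotic arch station) and the
mid-descending station at peak systole, which is the natural reading of a
drop quoted "across the stenosis" on an axial pressure curve.

## What the synthetic data do and do not show

The generator emulates group-level distributional structure (means, SEMs,
group sizes) and the geometric constructions, not patient anatomy: there
is no out-of-plane tortuosity, no branch-origin variation, no intensity
or segmentation noise, and the inter-variable correlations of real
cohorts are absent (variables are drawn independently, with feasibility
handled as described).  Passing round trips therefore validate the
measurement *constructions* and the statistical machinery — not
segmentation robustness on clinical CTA.  Similarly the 1D model cannot
resolve secondary flows, turbulence or wall shear stress; it preserves
stated parameters and the pressure-drop physics, and its agreement with
the reported gradient shows internal consistency of the reduced model
under the published boundary conditions, not 3D field fidelity.

## Problem sizes and determinism

The shipped validation uses 0.4–0.5 mm voxel grids (roughly 10^5
foreground voxels), one-hundred-arch round-trip batches, ten-thousand-draw
Monte-Carlo means, two-thousand-replicate null calibrations, and pulsatile
runs of 160 steps per cycle converging within three cycles; a full
calibration takes a handful of solver runs.  All randomness flows from a
single seed through per-stage derived seeds; pipeline outputs are
byte-identical across runs with the same seed.
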