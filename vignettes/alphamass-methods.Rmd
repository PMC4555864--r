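---
title: "Alpha-shape body-mass estimation: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alpha-shape body-mass estimation: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`alphamass` estimates body mass from the volume enclosed by an
alpha-shape fitted to a 3D point cloud of an articulated skeleton.

An alpha-shape of a point set *S* is parameterized by a radius α.
Conceptually, a sphere of radius α burrows through space and excavates
every region it can reach between the points; what remains is the shape.
Small α gives a tight, eventually fragmenting fit; α → ∞ gives the
convex hull. In the simplicial form used here the shape is the union of
the Delaunay tetrahedra of *S* whose circumsphere radius is below α, so
its volume is a sum of tetrahedron volumes. Interior voids (e.g. the
body cavity enclosed by a ribcage at intermediate α) arise naturally:
their large-circumradius tetrahedra are simply not retained. No
connectivity post-processing is needed or wanted — the volume of a
disconnected or void-containing shape is still the sum over retained
tetrahedra.

Because the method is a *calibrated correlate* rather than a
reconstruction, the fitted shape at the optimal refinement need not
approximate the living animal's outline: the shape volume is used the
way a femur circumference would be, as the predictor in an allometric
regression

&nbsp;&nbsp;&nbsp;&nbsp;ln(mass) = *a* + *b* · ln(α-volume),

fitted by ordinary least squares over a reference sample of skeletons
with known masses.

### Size normalization

A single global α would fit a large elephant skeleton more finely than a
boar: inter-bone spacing scales with the animal. The radius is therefore
set per specimen as α = *l*<sub>ref</sub> · *k*, with *l*<sub>ref</sub>
the mean Euclidean distance of cloud points from their centroid and *k*
a dimensionless refinement coefficient shared across the sample.
*l*<sub>ref</sub> is preferred over maximum height, maximum extent or
bounding-box diagonal because it is far better correlated with mass on
the reference sample and requires no landmarking; the alternatives are
still reported by `size_metrics()`.

### The sweep and model selection

`calibrate_sweep()` evaluates a grid of *k* values (default 200 values,
0.01–100, logarithmically spaced because the range spans four decades
and the interesting transitions — fragmentation, ribcage enclosure, limb
conjoining, hull convergence — are log-structured; the grid is
configurable and the reported optimum is grid-dependent). At each *k*
an OLS model is fitted and the *k* with the highest r² is selected;
ties break toward smaller *k* (tighter fits are less sensitive to
uncertainly mounted extremities such as scapulae). At very small *k*
some specimens have zero alpha-volume; those *k* carry no model and are
skipped in selection.

Each skeleton is first randomly downsampled (without replacement,
seeded) to a common point count, because LiDAR scans of a gallery give
constant *absolute* point density and therefore size-dependent *relative*
density. Downsampling is repeated (default 10 times) and repeat volumes
are averaged arithmetically before the log transform (geometric-mean
averaging is available via `average = "log"`). Per-repeat seeds derive
deterministically from the master seed and the specimen id, so adding a
specimen never changes another's subsamples, and every result is
reproducible bitwise.

### Regression conventions

- The reported m.s.e. is SSE/*n*, the convention of the published
  calibration tables this package reproduces; the 95% confidence
  intervals use the unbiased residual variance SSE/(*n*−2) with a
  t(*n*−2) quantile. Both conventions are exercised against the packaged
  reference table in the tests.
- Prediction uses the naive back-transform exp(*a* + *b* ln *V*),
  matching the published arithmetic; the log-normal smearing correction
  exp(mse/2) is available behind `correct_bias = TRUE` but off by
  default.
- No phylogenetically corrected regression is offered: on this
  calibration sample phylogenetic correction was found to make no
  appreciable difference, and applying a phylogenetic model to a species
  outside the sample is itself problematic.
- Fossil clouds should be downsampled to the same point count as the
  calibration; the model file records `n_points` and
  `predict_from_cloud()` warns on mismatch. A cloud smaller than the
  target is used in full, with a warning.

## Numerical design

**One tetrahedralization per cloud.** The Delaunay tetrahedralization
dominates the cost, so `alpha_complex()` computes it once, sorts the
tetrahedra by circumradius and stores prefix sums of their volumes; the
volume at any α is then a binary search plus a lookup. A 200-value sweep
costs one tetrahedralization, not 200.

**Retention rule.** A tetrahedron is retained when its circumradius is
*strictly* below α. The strict/non-strict choice only matters on
measure-zero ties (it is exposed as `strict` in `alpha_volume()`); real
scan noise never produces ties, and the single-tetrahedron fixture in
the tests pins the convention.

**Degeneracy.** Tetrahedra with volume below 10⁻¹² × (bounding-box
diagonal)³ receive an infinite circumradius sentinel and are never
retained at finite α — near-flat slivers otherwise contribute
arbitrarily large circumradii with negligible volume. A practical
consequence worth knowing: sliver circumradii can exceed the hull
diameter by orders of magnitude, so the r²(k) curve provably equals the
hull model only for *k* beyond (max finite circumradius)/*l*<sub>ref</sub>,
not merely for "large" *k*.

**Exactly degenerate inputs.** Grids, cube corners, and synthetic
surfaces with exactly coplanar patches (e.g. noise-free cylinder caps)
defeat double-precision incremental Delaunay. When the tetrahedralizer
reports a degeneracy — an exact predicate tie, or failure of the
hull-volume conservation check below — the cloud is perturbed by a
seeded uniform jitter and rebuilt. The jitter magnitude escalates
through 10⁻⁹, 10⁻⁷, 10⁻⁵ × the bounding-box diagonal, keeping the
smallest magnitude that yields a consistent triangulation: at metre
scale, 10⁻⁹ relative perturbations sit at the edge of double-precision
predicate reliability, so a single fixed magnitude is not always
sufficient. Real museum scans carry natural noise and never trigger the
ladder.

**Validation by construction.** Every triangulation is checked against
an independent volume computation: the sum of all finite Delaunay
tetrahedron volumes must equal the QuickHull convex-hull volume of the
same points to 10⁻⁹ relative. The boundary mesh provides a third route
(divergence-theorem volume of the outward-oriented boundary facets),
asserted in the tests to 10⁻⁶ relative. During development the engine
was additionally cross-checked against an external Delaunay
implementation on shared fixtures (circumradius multisets agreeing to
~10⁻¹¹ m).

**Circumradii** are computed by the circumcenter closed form (3×3 solve)
in double precision; no exact arithmetic is used, as the α values of
interest are far from ties at realistic noise levels.

## The synthetic specimens

Because the original museum clouds cannot be redistributed, the package
generates skeleton-*like* clouds with exactly known enclosed volume:

- a trunk of 8 transverse elliptical slabs ("rib rings", 0.35 × 0.30 m
  half-axes, 0.06 m thick, 0.10 m gaps at scale 1);
- four vertical limb cylinders (radius 0.06 m, length 0.70 m, stance
  0.44 m, fore/hind separation 0.90 m);
- an inclined neck cylinder (radius 0.08 m) and an ellipsoidal head
  (0.18 × 0.10 × 0.12 m).

The solids are pairwise disjoint (small gaps), so the true volume is an
exact sum of closed forms — about 0.207 m³ at scale 1, i.e. ~207 kg at
soft-tissue density, a realistic pony-sized quadruped. All linear
dimensions scale with `scale`, making families exactly isometric;
masses follow mass = c·V<sup>β</sup> with defaults c = 1000 kg·m⁻³ and
β = 1, optionally with multiplicative log-normal noise. Surfaces (not
interiors) are sampled, matching what LiDAR and photogrammetry capture;
cylinder sampling is area-weighted between side and caps, while the
ellipsoidal head uses direction sampling that is only approximately
area-uniform (immaterial here: only the enclosed volume enters the
pipeline, and it is analytic).

The geometry reproduces the qualitative alpha-shape phenomenology of
real skeletons within the default sweep window: total fragmentation
below the point spacing, a shrink-wrap regime near the true volume,
rib-gap bridging, limb conjoining, and hull convergence. What it does
*not* emulate: real bone shapes, articulation/pose variation, occlusion
and registration artefacts of real scanners, and non-isometric shape
variation across a clade. Passing the synthetic recovery tests therefore
demonstrates the *pipeline* (geometry engine, normalization, sweep,
selection, prediction) is sound, not that any particular biological
sample satisfies the regression's assumptions.

## Problem sizes used in the tests

The shipped tests run the pipeline at reduced sizes chosen as the
smallest that exercise each property cleanly: calibration sweeps on 4–7
specimens at 2 500–10 000 points with 2–3 repeats; exponent recovery
(β ∈ {0.9, 1.0, 1.1}, recovered within ±0.1; ±0.15 under mass noise of
sd 0.1 across 20 seeds) on a 7-specimen family at 10 000 points with a
50-point grid; downsampling stability on a 60 000-point quadruped
subsampled to 50 000/10 000/1 000 with 10 repeats. Geometry oracles use
up to 20 000 points (uniform ball vs 4π/3). The published-table
reproductions are exact-arithmetic checks and run in milliseconds.

## Known limitations

- Double-precision predicates with jitter escalation, not exact
  arithmetic: pathological inputs are resolved by perturbation rather
  than symbolically, so outputs on exactly degenerate inputs are those
  of a jittered copy (consistent to ~10⁻⁹–10⁻⁵ of the bounding box).
- The optimum *k* is a property of the calibration sample and its grid;
  it should be re-estimated for new datasets and is not meaningful to
  three decimal places.
- Prediction intervals do not propagate calibration uncertainty; the
  per-repeat spread reported by `predict_from_cloud()` reflects
  downsampling variability only.
- Centre-of-mass and inertial properties are out of scope: the fitted
  shape's volume distribution has no established mapping to tissue
  distribution.
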