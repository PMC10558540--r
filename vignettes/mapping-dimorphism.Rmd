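---
title: "Mapping a binary signal onto 3D landmark configurations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping a binary signal onto 3D landmark configurations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosignal)
```

## The problem

Classical geometric morphometrics asks *whether* two groups — here females
and males scored on a cranium-like surface — differ in shape, size, or form.
It usually answers globally: one discriminant analysis, one ordination, one
p-value for the whole configuration. The question this package addresses is
*where* the signal lives. Given a few hundred specimens digitized as ordered
3D landmarks and surface semilandmarks, it produces a per-point map of how
well the binary label can be predicted from a small patch of the
configuration around each point, in three feature spaces:

* **shape** — Procrustes-aligned coordinates with size removed;
* **form** — the same coordinates with the natural log of centroid size
  appended as one extra variable;
* **size** — the log centroid size of the local patch alone.

The core loop is deliberately simple and statistically conservative. For
every point we take its neighborhood of `k = 10` points (the point plus its
9 nearest neighbors on the consensus shape), and repeat `n_perm = 100`
times: split the specimens into a stratified 70% training / 30% test set;
run a generalized Procrustes analysis (GPA) *on the training subset of the
neighborhood only*; build the features of the requested space; reduce them
by a PCA fitted on the training set, keeping components up to 90% of the
variance; fit a two-class linear discriminant with pooled within-class
covariance; and score it on the held-out specimens, which are projected
into the training frame by ordinary Procrustes superimposition (OPA) and
the training PCA axes — never refitted. The map value at a point is the
mean test accuracy over the permutations, reported overall and per class.
A full map therefore runs `n_points * n_perm` independent discriminant
analyses; each local GPA makes neighboring maps statistically independent
of one another and of the global superimposition.

## Model assumptions and their consequences

**LDA with pooled covariance.** The local classifier assumes the two
classes share a within-class covariance on the retained PC scores. Priors
default to training class frequencies, with an `"equal"` switch. If the
pooled covariance is singular (possible at very small training sets after
truncation) a ridge of `1e-8 * trace / k` is added rather than failing,
because one degenerate permutation should not hole the map.

**Training-only fitting.** Both the local GPA and the PCA are estimated on
the training split alone. Test specimens are centered, rescaled to unit
centroid size (mirroring the treatment of the training specimens), rotated
onto the training consensus, and pushed through the training mean and axes.
Re-estimating either step on the pooled sample would leak test information
into the classifier and bias every map value upward.

**No tangent-space projection.** Aligned coordinates are used as-is, without
projecting to the tangent space of shape space. At the small shape
variation typical of within-species cranial data the difference is far below
the Monte Carlo resolution of the maps; the choice is recorded here so it is
explicit rather than implicit.

**Neighborhoods are fixed once.** Neighborhoods are computed from the
full-sample consensus, not per split, so the spatial support of a map value
is identical across permutations. `k` counts the focal point; a
`k_excludes_focal` switch gives the other reading of "k points around a
point". `k < 4` is rejected because a 3D Procrustes fit of fewer than 4
points is degenerate.

**Canonical orientation.** GPA solutions are only defined up to a global
rotation. `gpa()` rotates every solution onto the principal axes of its
consensus with a deterministic sign rule, so that the aligned coordinates —
not just their invariants — are reproducible regardless of how the input
specimens happened to be oriented. For (near-)spherical consensus shapes
with ties among principal axes the canonical frame can switch between
near-equivalent solutions; all accuracy results are invariant to this.

## The supporting statistics

* `procrustes_lm()` partitions the total variance of the flattened shape
  variables over model terms with *sequential* sums of squares (default
  order `size`, `sex`, `size:sex`), summed across coordinates; p-values come
  from Freedman–Lane residual randomization of the reduced model, with the
  `+1/(n+1)` estimator so p is never zero.
* `allometric_regression()` fits each coordinate on (optionally log)
  centroid size, per group; the stacked coefficients are the allometric
  trajectory. `trajectory_angle()` is the angle between unit-normalized
  trajectories; `angle_permutation_test()` shuffles group labels with group
  sizes preserved. The predictor defaults to raw centroid size with a
  `log_predictor` switch, since both conventions are in routine use.
* `repeatability()` runs a one-way Procrustes ANOVA across individuals on
  jointly superimposed replicate digitizations and reports
  `(MS_among - MS_within) / (MS_among + (r - 1) MS_within)` as a percentage,
  for balanced designs only.
* `symmetrize()` removes the asymmetric component by averaging each
  configuration with its reflected, pair-relabeled copy after an OPA without
  scaling, iterated to a fixed point. The reflection axis is immaterial:
  any two reflections differ by a rotation, which the OPA absorbs, so no
  midsagittal pre-alignment is needed.
* `compare_maps()` validates maps across subsamples by Pearson correlation
  of the per-point accuracies, optionally restricted to the points above a
  quantile of the first map (linear-interpolation quantile convention).

## What the synthetic generator emulates — and what it does not

`simulate_landmarks()` plants every piece of structure the pipeline is
meant to detect, so that each claim in the test suite is checked against a
known truth:

* a smooth bilaterally symmetric base surface (an ellipsoid lattice from
  `make_base_shape()`, with exact left/right pairing and a valid
  triangulation);
* a localized mean-shape difference: group M displaced along outward
  normals on a chosen patch, scaled in units of the mean nearest-neighbor
  spacing;
* group size dimorphism: log-normal centroid sizes, default means 950 mm
  (F) and 1000 mm (M) with 3.5% log spread — roughly the 5% male-larger
  size dimorphism and overall scale of adult human crania sampled at
  a few hundred points;
* shared or diverging allometry: a per-group unit direction field added in
  proportion to the specimen's log-size deviation (`allometry_vectors()`
  constructs two fields at any chosen angle);
* digitization noise: isotropic Gaussian displacement (default 0.5 mm)
  applied after a random rigid motion of each specimen, so the error is
  frame-independent; and optionally
* among-individual biological variation (`individual_sd`), shared by the
  replicate digitizations of an individual — this is what gives
  repeatability designs a planted among:within variance ratio.

The base-shape lattice is a latitude–longitude grid with poles on the
bilateral axis and seeded longitude phases: this guarantees an *exactly*
symmetric pairing and a watertight triangulation in plain code, at the cost
that the realized point count snaps to the nearest lattice size (a request
for 150 points yields 146) and that point density is somewhat higher near
the poles than a perfectly uniform spiral would give. Neither property
interacts with the statistics being validated.

What the generator does **not** emulate: real cranial anatomy and its
spatially structured, anisotropic covariance; population structure and
ancestry mixtures; correlated (non-isotropic) digitization error; missing
landmarks. Passing tests therefore demonstrate that the machinery recovers
planted structure of realistic magnitude under clean assumptions — they do
not certify accuracy values on any particular real sample.

## Numerical choices

* GPA convergence is the RMS change of the consensus between sweeps,
  tolerance `1e-10`, at most 100 sweeps; the consensus is re-normalized to
  unit centroid size each sweep when scaling, and the stored consensus is
  exactly the arithmetic mean of the final aligned coordinates.
* Rotations use the SVD of the cross-covariance with the standard sign fix,
  so reflections are never introduced (`det R = +1` always).
* Nearest-neighbor ties in `build_neighborhoods()` break toward the lower
  point index; PCA component signs are fixed by the largest-|loading| rule.
* Stratified splits take `floor(train_fraction * n_class)` training
  specimens per class, sampling positions within each class ordered by
  specimen id — so maps do not depend on storage order. Each
  (point, permutation) pair derives its own RNG stream from the single map
  seed, making maps reproducible and safely parallelizable.
* A permutation whose local training fit is degenerate is skipped and
  counted; a point where more than half the permutations fail reports `NA`
  rather than a silently thinned average.
* Thin-plate-spline warps use the 3D kernel `U(r) = r` with an affine term,
  solved densely; coplanar or duplicated sources raise a singular-system
  error rather than a regularized guess.

## Scale of the bundled validation studies

The package's own acceptance study uses two groups of 60 specimens on a
146-point configuration with `k = 10` and 100 permutations per point —
about 15,000 local discriminant fits per map, which keeps a full
three-space calibration run in the minutes range on one core while leaving
the per-point Monte Carlo error (binomial error at a test set of 36,
averaged over 100 splits) small against the planted effects. Parameter
recovery studies use up to 200 specimens per group. One calibration note:
with 120 specimens, the per-point *mean* accuracy on null data keeps a
dataset-level wobble of a few percent that 100 shared-data permutations do
not average away, so individual null-map points can stray slightly beyond
±0.08 from chance even though the map mean sits within a percent of 0.5;
the acceptance suite records this exactly as observed.

## Known limitations

* Binary signals only; no multiclass or continuous-trait mapping, no
  spatial smoothing of maps, and no multiple-testing control across points
  (maps report raw mean accuracies, not p-values).
* Sliding of semilandmarks is out of scope: the package consumes
  already-slid or fixed points.
* Balanced replicate designs only for repeatability.
* The fcsv reader handles the Slicer markups dialects (RAS/LPS); mesh
  ingestion is limited to a triangle list.
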