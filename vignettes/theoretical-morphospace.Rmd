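---
title: "Theoretical morphospace and Pareto adaptive landscapes for jaw outlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Theoretical morphospace and Pareto adaptive landscapes for jaw outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jawscape)
```

This vignette is the package's account of its methods: the models and their
assumptions, the parameters that matter, what the synthetic generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The analysis in one paragraph

A sample of closed lateral jaw silhouettes is turned into a low-dimensional
shape space by elliptic Fourier analysis (EFA) and PCA. The space is then
treated *theoretically*: an evenly spaced grid of PC1–PC2 coordinates is
inverted back into outlines, including shapes no organism ever realized.
Each constructible (non-self-intersecting) theoretical shape is meshed and
tested for two functions that plausibly trade off in a biting lever — speed
of closure (rotational efficiency, RE) and strength (median von Mises
stress, VMS, inverted) — under randomized boundary conditions that express
our uncertainty about joint, bite and muscle placement. A bidirectional
Pareto ranking converts the two performance surfaces into a single
optimality score in [0, 1] over the morphospace: the adaptive landscape.
Empirical taxa, and ancestors reconstructed under Brownian motion on a
time-calibrated tree, are projected onto this landscape, and disparity and
mean optimality are tracked through stratigraphic time bins.

## Outline representation and EFA

Outlines are counterclockwise closed polygons. Before decomposition they
are resampled to equal arc length (default 600 vertices — dense enough that
polygon chord error is negligible against the 12-harmonic truncation) and
put into a canonical anatomical frame: major axis along x, the tapering
(anterior) end toward +x, and the blade's bulk ventral, so that the
tooth-bearing margin faces +y. This frame matters twice: it resolves the
reflection that EFA normalization deliberately does *not* remove (chirality
is anatomical information), and it lets the biomechanics module find the
jaw joint and bite point as the posterior-most and anterior-most boundary
nodes with near-vertical outward normals.

The decomposition is the Kuhl–Giardina closed-polygon formulation: harmonic
n contributes coefficients (aₙ, bₙ) to x(t) and (cₙ, dₙ) to y(t), t being
arc length. Normalization uses the first harmonic: the parameter origin is
rotated to the first ellipse's semi-major axis, the coordinate frame to its
orientation, and all coefficients are divided by the semi-major axis
length. This pins a₁ = 1, b₁ = c₁ = 0 (snapped exactly), leaving 4H − 3
free parameters — 45 at the default H = 12. Two genuinely open conventions
were closed as follows:

* **Normalization variant.** First-ellipse normalization (not
  longest-radius); it is the standard choice and the only one consistent
  with a 4H − 3 parameter count.
* **Phase branch.** The half-angle formula for the starting phase has two
  critical points (semi-major vs semi-minor) and a residual half-turn
  ambiguity. The branch with the larger first-harmonic cosine amplitude is
  taken, and the remaining θ vs θ + π choice is resolved by lexicographic
  comparison of the two candidate coefficient vectors. Both rules are
  invariant to rotation, scale and digitization starting point, which the
  test suite verifies to 1e−6 over random transforms.

A consequence of arc-length parameterization worth knowing: the first
harmonic of an *ellipse* is not exactly its semi-axes (a 2:1 ellipse gives
(1.8284, 1.0730), not (2, 1)); the package's tests pin this against an
independent dense Fourier quadrature rather than against the naive
expectation.

## Morphospace and the theoretical grid

PCA is centred and unscaled (`stats::prcomp`); scores, loadings and
variance fractions are exposed, and projection/inversion are exact linear
maps, so `inverse → project` round-trips to 1e−8 in the tests. The
theoretical grid defaults to 23 × 21 = 483 nodes. Axis limits are the
empirical [min, max] per axis expanded on both ends by 20% of the *PC1*
range; the border is applied symmetrically to both axes (the uniform-margin
reading; the alternative — scaling PC2's border by PC2's own range — is a
one-line change in `build_theoretical_grid()`). Higher PCs are held at
exactly zero: theoretical shapes vary only in PC1–PC2. Reconstructed nodes
are screened with an exact segment-intersection test; self-intersecting
shapes are geometrically impossible as silhouettes and are masked from all
functional analysis. Valid shapes are isotropically scaled to unit area so
that performance differences reflect shape only.

## Meshing

No triangulation library is part of the package's dependency set, so the
mesher is built in: boundary nodes are placed at ~h spacing along the
outline (h chosen so an equilateral lattice yields the target element
count), genuine corners — including the sharp anterior/posterior tips of
jaw silhouettes, detected by a 10° turning-angle threshold with sub-h
corner clusters merged to the sharpest member — are preserved exactly;
interior nodes come from a hexagonal lattice kept 0.6h clear of the
boundary; connectivity is a Bowyer–Watson Delaunay triangulation computed
on deterministically jittered copies of the points (breaking exact
cocircular/collinear degeneracies) and clipped to the polygon by centroid
test; two rounds of Laplacian smoothing with re-triangulation follow, and
the lattice pitch is adjusted until the element count lands within 10% of
the target. Everything is deterministic: the same outline and target give
bitwise-identical meshes.

Mesh quality: interior minimum angles are typically 22–32°. Where the
outline itself has a tip angle below the 20° floor (strongly concave dorsal
margins), no conforming mesh can beat the geometry; `triangulate()` then
warns rather than errors, and the constant-strain elements remain valid.
Area is conserved exactly with respect to the boundary-node polygon (all of
whose vertices lie on the input outline), to ~0.01% of the smooth outline's
area at default densities.

## Biomechanics

**Rotational efficiency.** With element masses mᵢ = density × areaᵢ and
rᵢ the centroid distance to the jaw joint, I = Σ mᵢ rᵢ² and the bite-point
speed under one unit of rotational kinetic energy is RE = L·sqrt(2/I)
(E = ½Iω² = 1 ⇒ ω = sqrt(2/I)), L the joint–bite distance. The moment of
inertia is taken about the *joint* — the rotational axis — which is the
only reading consistent with the energy argument. Units are relative
(density, thickness and force are 1): only ranking matters.

**Stress.** Plane-stress constant-strain triangles with E = 2×10⁹ Pa,
ν = 0.3. The solver assembles a sparse stiffness matrix and passes the
constant-stress patch test to machine precision; a ~2500-element slender
cantilever reproduces Euler–Bernoulli tip deflection within 1%. The summary
statistic is the *median* element VMS, robust to the singular stress
concentrations at constraints. The constraint scheme is a design decision:
the joint is fixed in x and y and the bite point in y only ("lever"
scheme), because fully fixing both ends would suppress the lever mechanics
of a biting jaw; `"pinned"` is available for comparison.

**Randomized boundary conditions.** For RE, joint and bite are displaced
independently along the boundary by uniform offsets within ±5% of the
perimeter. For VMS, the constraints stay at the base landmarks (so one
matrix factorization serves all replicates) and only the muscle force is
randomized: its node starts one-third of the way along the *dorsal*
boundary path from joint to bite (the muscle-attachment side, chosen as the
candidate path with the higher mean y), is displaced within the same ±5%
window, and its unit direction is the outward normal rotated by a uniform
angle within ±45°. Uniform distributions are used throughout —
"pseudo-randomized" placement with hard bounds and no distributional
commitment beyond them. Summaries per shape are the mean and the 5th/95th
empirical percentiles (linear-interpolation quantiles) of each metric.

## Pareto ranking and the adaptive landscape

Goldberg peeling assigns front 1 to the non-dominated set (dominance =
better-or-equal in both metrics and strictly better in at least one, so
duplicates never dominate each other), removes it, and repeats. Running the
peeling twice — once maximizing RE / minimizing VMS (R_O), once with both
directions reversed (R_S) — gives the combined rank
(R_S − 1)/(R_O + R_S − 2), linear from 0 to 1. Mean-over-replicates
performance per node is ranked, matching how the landscape is drawn from
mean surfaces.

One degenerate case needs a rule the formula does not supply: a point on
the first front in *both* directions (0/0). This happens for singletons and
for the extreme corners of pure trade-off sets — in a set where every point
is on both first fronts, *all* ranks are degenerate. The package assigns
0.5, the symmetric bounded midpoint, and exposes `degenerate_rank` for
sensitivity analysis. Ranks are invariant to strictly monotone transforms
of either metric (dominance is ordinal), and reversing both directions maps
rank to 1 − rank away from the degenerate points; both are tested exactly.

Taxon optimality is bilinear interpolation over the four surrounding grid
nodes; queries outside the grid or in cells with an invalid corner are out
of domain and raise an error naming the offending taxa (or yield NA under
`strict = FALSE`).

## Phylogenetic comparative layer

Ancestral states under Brownian motion are the GLS/ML conditional
expectations: root = (1′C⁻¹Y)/(1′C⁻¹1) and internal nodes
root + C_at C⁻¹ (Y − root), with C the shared-path covariance. Traits are
handled independently, which is exact for BM point estimates regardless of
trait covariance because the estimator is linear. The implementation is
cross-checked in the tests against an independent one (`phytools::fastAnc`)
to 1e−8 and against closed forms on two-tip and star trees exactly.
Ancestors are *not* included in the PCA; they are projected with the fitted
loadings.

Phylogenetic signal is the multivariate K statistic: the ratio of among-tip
to phylogenetically corrected variation scaled by its Brownian expectation,
so K ≈ 1 under BM on the given tree (verified by simulation within
[0.85, 1.15] on 99-tip trees). Significance comes from permuting tip rows;
the p-value is one-sided, p = (#{K_perm ≥ K_obs} + 1)/(n + 1) — phylogenetic
signal has a natural directional alternative, and this matches how the
statistic is conventionally tested.

## Time bins, disparity and trends

Default bins are one merged late Silurian bin (Ludlow + Pridoli,
427.4–419.2 Ma) plus the seven Devonian stages with ICS 2020 boundaries;
any contiguous old-to-young table can be substituted. Membership is
interval overlap plus range-through: a taxon occupies every bin between its
first and last occupied bin. Disparity is computed on the 45 harmonic
coefficients (not PC scores): sum of per-trait sample variances (n − 1
denominator — the conventional unbiased choice; the alternative n
denominator only rescales, never reorders, the series) and mean pairwise
Euclidean distance. Bootstrap CIs are empirical 2.5/97.5 percentiles of
10,000 row resamples. Trends old→young are Spearman rank correlations
(exact p for the short series arising from ≤ 9 bins, via `stats::cor.test`);
the disparity–optimality association is Pearson's r.

## The synthetic generator: what it emulates, and what it does not

`generate_jaw_outline()` builds a blade from a convex ventral margin
(0.85·sin πt), a near-straight dorsal margin (0.15·sin³πt) displaced by a
`dorsal_curvature` sine term (positive = concave, negative = convex), an
anterior `taper` factor, and an optional band-limited roughness pushed
outward on both margins so it can never cause self-intersection. The three
interpretable knobs were chosen to span the two axes that dominate
empirical jaw shape variation: elongation (length/depth) and the
convex↔concave dorsal transition. Within the documented parameter box
(ratio 1.5–8, |curvature| ≤ 0.5, taper ≤ 0.8, roughness ≤ 0.02) outlines
are provably simple, and generation refuses outside it. Default population
distributions — log-normal ratio centred near 3.5, Gaussian curvature
(sd 0.15) truncated to the box, uniform taper 0.15–0.55, clade proportions
57:48:8:8, exponential range durations (mean 10 Ma) inside the
427.4–358.9 Ma span — are fixed realistic choices, not tuning knobs.

What it does *not* emulate: real digitization noise and photographic
distortion, 3D relief collapsed into silhouettes, taphonomic loss,
correlated trait-and-tree history (ranges and shapes are drawn
independently of the simulated phylogeny), and any taxon-specific anatomy.
Consequently, passing tests demonstrate that the *machinery* is correct and
calibrated — not that empirical early-gnathostome results are reproduced;
those depend on fossil data this package deliberately does not ship.

## Problem sizes and numerical choices in the shipped tests

The test suite exercises the full design at reduced scale chosen for a
single CPU: the end-to-end run uses 50 taxa, a 9 × 9 grid, 800-element
meshes, 100 Monte-Carlo replicates and 1000 bootstraps; mesh convergence is
checked between 2500- and 3000-element meshes of five jaws under
deterministic base boundary conditions (agreement < 2%); K_mult calibration
uses 200 BM simulations on a 99-tip tree. Tolerances follow the quantity:
machine-precision for exact identities (patch test, Pareto formulas, PCA
round-trips), 0.5% for the meshed-rectangle RE against its closed form, 10%
for CST-vs-beam-theory deflection, and sampling-error bands for Monte-Carlo
calibrations.

## Known limitations

* Strictly 2D: plane stress, uniform thickness and density; no material
  heterogeneity, contact, or muscle architecture.
* The landscape is built on PC1–PC2 only; variation on higher axes is
  quantified (distance-to-plane) but not ranked.
* Mesh minimum angles cannot exceed the outline's own tip angles; strongly
  concave dorsal margins produce a few sub-20° elements (warned, not
  fatal).
* Bilinear interpolation is undefined in cells touching invalid grid nodes;
  taxa falling there must be handled explicitly (`na_action` in
  `disparity_through_time()`).
* K_mult's permutation test assumes exchangeable tips under the null; its
  p-value is one-sided by design.
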