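---
title: "Serous PED segmentation in SD-OCT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serous PED segmentation in SD-OCT: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pedseg)
```

`pedseg` segments serous pigment epithelium detachment (PED) — an
arch-shaped, fluid-filled lift of the RPE off Bruch's membrane (BM) — in 3D
SD-OCT volumes. This vignette explains each stage's model, the parameters
that matter, the numerical choices behind them, and what the synthetic
phantom does and does not establish about performance on clinical data.

## Conventions

A volume is an `nx × nB × nz` array indexed `(x, B, z)`: lateral position,
B-scan, and axial depth *increasing downward*. All public coordinates and
surface heights are 0-based voxel indices. A surface height `z(x, B)` marks
the deepest voxel of the tissue *above* the interface, and the slab
"between surfaces A and B" is the half-open range `(z_A, z_B]`; adjacent
slabs therefore partition the retina with no overlap or double counting.
The retina is everything in `(ILM, BM]`; the PED is `(RPE floor, BM]`.

## Speckle denoising (MCDE)

OCT speckle is multiplicative interference noise. The modified curvature
diffusion equation

$$u_t = |\nabla u|\,\nabla\!\cdot\!\Big(c(|\nabla u|)\,\frac{\nabla u}{|\nabla u|}\Big),
\qquad c(g) = e^{-(g/K)^2},$$

smooths level sets by curvature flow modulated by the conductance `c`, so
strong edges (large gradient) barely diffuse. It is applied per B-scan in
2D: at ~94 µm the B-scan spacing is 8–27× the in-plane voxel size, and
diffusing across it would mix unrelated tissue.

The discretization evaluates, on each of a pixel's four half-point faces,
the one-sided normal derivative and the averaged tangential derivative,
forms the face gradient magnitude and flux `c(g)/max(g, ε) · d_n`, and
updates `u ← u + dt · |∇u|_central · Σ fluxes` with replicate boundaries.
A constant image is an exact fixed point. Parameters: conductance `K`
(grey levels; default 25 on the 0–255 scale — edges in OCT bands are an
order of magnitude above this), `iterations` (default 5) and `time_step`
(default 0.125; the explicit 2D stencil requires `dt ≤ 0.25`). The
vectorized update is verified against an independent scalar
(pixel-by-pixel) implementation of the same definition.

## Optimal-surface layer segmentation

A retinal boundary is one depth `z` per `(x, B)` column. The search
minimizes the summed edge cost subject to smoothness bounds
`|z_i − z_j| ≤ Δ` between adjacent columns and per-column feasibility
bands. Two exact solvers are provided:

* a per-B-scan dynamic program (used by default; B-scans decoupled), and
* the minimum-closed-set construction solved by *s–t* min-cut, which also
  enforces the cross-B-scan bound `Δ_B`.

Both return, among equal-cost optima, the surface with pointwise-smallest
heights: the set of optimal surfaces is closed under pointwise minimum
(the meet of two feasible surfaces is feasible and their costs exchange),
so the minimal optimum exists, and the min-cut's residual-reachability
source side realizes it; the DP reconstructs it greedily left-to-right.
Both are tested against exhaustive enumeration, including the tie rule.
The max-flow engine is a Dinic implementation in C++ — augmenting-path
solvers are the standard choice for grid-structured vision graphs, where
generic push-relabel implementations scale poorly.

**Edge cost.** The cost at voxel `z` is `∓(I(z+1) − I(z−1))` (sign per
polarity: dark→bright for the ILM and EZ roof, bright→dark for the RPE
floor). The symmetric difference is deliberate: after axial down-sampling
a one-sided difference can lose up to half the edge contrast depending on
how the edge lands on the coarse grid, which is enough to make the coarse
search lock onto a different boundary. Exact ties across an edge resolve
to the shallower voxel via the tie rule.

**Multi-scale scheme.** The full-resolution cost raster is mean-pooled
axially by 2, twice (three scales). The coarsest scale is searched over
the whole band; each finer scale searches only ±`margin` voxels (default
8) around the up-sampled coarser surface. Two details matter and were
chosen after the obvious alternatives failed on constructed cases:

* the *cost* is pooled, not the volume. Re-deriving the cost from a pooled
  volume lets closely stacked same-sign edges (the EZ roof and RPE floor
  bound an ~12-voxel bright band) merge into one stronger composite edge
  at coarse scales, and the refinement band then never recovers;
* feasibility bands round *inward* at each pooling (`⌈lo/2⌉`,
  `⌊(hi−1)/2⌋`), so no coarse voxel pools cost from outside the band —
  otherwise a strong out-of-band edge (the ILM, for the EZ search) leaks
  into the boundary coarse voxel. `Δ` is divided by the pooling factor
  (rounded up) to match the halved height units.

**Stage order and defaults.** ILM first (`Δ = 1`; it is the strongest
dark→bright edge and nearly unaffected by PED), then the EZ roof and RPE
floor (`Δ = 4` — the arch needs a loose bound; a cap whose rim climbs
faster than `Δ` per column needs a larger value, and the parameter is
exposed) in bands starting `min_gap = 2` voxels below the previous
surface, which guarantees ordering by construction. These values are
configuration, not printed constants of the method.

**BM and the initial mask.** Per B-scan, BM is the maximal-z boundary of
the convex hull of the RPE-floor trace — equivalently the pointwise
maximum over all chords between trace points (verified against that brute
force). It may take sub-voxel values between hull vertices and is the one
non-integer surface. The initial PED mask is the slab `(z_RPE, z_BM]`.

## Region features and AdaBoost filtering

Hull estimation is deliberately greedy: every concavity of the detected
floor becomes a candidate region, so the initial mask has near-perfect
sensitivity and many false positives. Each 8-connected 2D component gets
62 features: area, perimeter (exposed 4-neighbour faces), moments-ellipse
axes/eccentricity/orientation (normalized second central moments with the
1/12 pixel-variance term), Euler number, bright-pixel count (above the
B-scan's Otsu threshold — "bright" needs a definition and Otsu is
parameter-free), equivalent diameter, solidity and convex-hull area
(pixel centres inside the hull polygon), extent, intensity extrema/mean;
signed centroid distances to ILM/EZ roof/RPE floor/BM; centroid and
axis-aligned bounding box; the extremum pixel (position + intensity) in
each of 8 compass directions (maximal projection, raster-order ties); and
regional means of the two Hessian eigenvalues (|λ1| ≤ |λ2|, the
blob-detection ordering) of Gaussian-derivative filters at scales 1, 3,
6, 9, 14. The derivative kernels are calibrated (zero sum, exact unit
response on ramps and quadratics), so a constant-curvature image yields
its analytic eigenvalues away from the boundary.

Features are in voxel units: spacing is constant within a study, so
physical units would only rescale each feature, and the classifier is
scale-free per feature (a configuration switch could convert to µm).

The filter is discrete AdaBoost over depth-1 decision stumps (exhaustive
midpoint threshold search, both polarities; ties to the lowest feature
index, then lowest threshold). Round weight `α = ½ ln((1−ε)/ε)`; weights
update `w ← w·e^{−αyh}` and renormalize, leaving exactly half the mass on
the misclassified samples — an identity the tests verify, along with the
exponential training-error bound `∏ 2√(ε_t(1−ε_t))`. `N = 50` rounds with
early stop at `ε = 0` (recorded) or `ε ≥ 0.5`. Training labels come from
truth overlap: a region is positive iff ≥ 50% of its pixels fall in the
truth mask. Regions are kept or deleted whole; a region that merges a true
PED with an attached sliver is therefore kept in full, and later stages
must trim it.

## Shape-constrained graph cut

The final segmentation minimizes, over binary labelings `f`,

$$E(f) = \sum_p \big[\lambda_R R_p(f_p) + \lambda_S S_p(f_p)\big]
 + \lambda_B \sum_{(p,q) \in N_6} B_{pq}\,[f_p \ne f_q],$$

with `λ_R + λ_S + λ_B = 1` (defaults 0.4 / 0.2 / 0.4; estimable from
training data). Terms:

* **Region** `R_p(f)`: negative log-likelihood of the voxel intensity
  under a 32-bin histogram of the corresponding seed intensities
  (Boykov–Jolly). Smoothing uses a small floor (ε = 0.01 pseudo-counts),
  not add-one: with add-one smoothing an intensity *never seen* among the
  foreground seeds was barely less likely than a rare-but-seen background
  intensity, the per-voxel margin collapsed to ~0.1, and flat far-field
  structures could flip label wholesale.
* **Shape** `S_p(obj) = min(d(p)/r, 1)`, `S_p(bg) = 1 − S_p(obj)`, with
  `d` the Euclidean distance (voxel metric, exact squared distance
  transform, Felzenszwalb–Huttenlocher) to the refined region and `r` the
  region's enclosing-sphere radius (Ritter's deterministic two-pass
  bounding sphere — always enclosing, within a few percent of minimal,
  which is ample for a prior scale factor).
* **Boundary** `B_{pq} = exp(−(I_p − I_q)²/2σ²)` on the 6-neighbourhood
  (unit distances), σ = the standard deviation of neighbouring intensity
  differences in the working crop.

Seeds are automatic, per 26-connected refined region: foreground = ball
erosion with radius `round(0.143·V^{1/3})` (`V` = region voxels; an empty
erosion falls back to the distance-transform maximum), background = the
complement of the ball dilation with coefficient 1.143, inside a working
box of 3× the dilated extent. Each region's background is the complement
of *its own* dilation (minus all foreground seeds, keeping the global
sets disjoint): using the union of all dilations left small regions' cuts
with vast under-seeded free space and caused flooding. Seed voxels are
hard constraints, contracted into the terminals so the max-flow spans only
the free voxels. Before the cut, a per-column affine brightness remap
anchors the vitreous median and RPE-band-slab median to fixed levels,
normalizing illumination without reordering any column's intensities.

The cut runs in 3D with the 6-neighbourhood — the smallest neighbourhood
that keeps the energy submodular — independently per region in its
working box. Voxel distances ignore the anisotropic spacing (the same
voxel metric the distance field uses), a simplification that matters most
across B-scans; it is the main reason performance on thin (few-B-scan)
regions is weaker than in-plane.

Weight estimation (`estimate_weights()`) is projected finite-difference
ascent of mean Dice over `(λ_R, λ_S)` on the simplex, with backtracking
and monotone acceptance, exactly as simple as the problem warrants (the
objective is a 2-variable, noisy, cheap-to-evaluate function).

## Adaptive morphology

All structuring elements are Euclidean balls with the region-adaptive
radius `r = round(c·V^{1/3})` — dimensionally a length from a volume, with
`c < 1` shrinking and `c > 1` growing relative to the region scale. Ball
erosion/dilation are computed exactly through the squared distance
transform (a voxel is eroded iff its distance to background exceeds `r`),
verified against brute-force ball enumeration.

Post-processing runs per 26-connected region: geodesic reconstruction
(6-neighbourhood) of the ball-eroded marker (`c = 0.200`) inside the
region, then ball closing (`c = 0.700`) on an `r+1` pad so the volume
border does not erode the result. Reconstruction removes isolated specks
and diagonally attached spurs while restoring the 6-connected body
*exactly* — a reconstruction bounded by the original region necessarily
restores any 6-connected protrusion, so "spur removal" here means the
26-but-not-6-connected kind; regions whose erosion marker is empty are
dropped. Closing fills interior holes and grooves. The composite is
idempotent on the masks the pipeline produces (property-tested on random
blob masks), and the 26-connected region count never increases.

## Evaluation

With `V_a` (automatic), `V_g` (truth) and `V_t` (retina between ILM and
BM): TPVF = |a∩g|/|g|, FPVF = |a∖g|/(|t|−|g|), DSC = 2|a∩g|/(|a|+|g|),
PPV = |a∩g|/|a|. The FPVF denominator is the false-positive-*eligible*
volume (the Udupa convention); empty denominators report 0 with an
explicit flag rather than NaN. Volume-series agreement uses OLS with R²
and Bland–Altman limits `mean ± 1.96·sd` (sample sd), and paired
two-sided *t*-tests (constant differences are flagged degenerate).
Identities such as DSC symmetry and TPVF(a,b) = PPV(b,a) are
property-tested.

## The phantom: what it emulates, and what it does not

`generate_phantom()` paints intensity bands between four surfaces:
vitreous (20), NFL band (170), ONL (55), EZ (140), RPE (200), PED/pocket
fluid (40) and choroid (90) on a 0–255 scale. The ILM undulates smoothly
(sd 0.8 voxels, correlation length 24); the BM baseline is much stiffer
(sd 0.4, length 40) — BM is nearly planar anatomy, and the level choices
keep the vitreous→NFL step the strongest dark→bright transition,
*including* composites of stacked deeper edges, which is the ILM's
defining property in OCT. PED caps lift the RPE floor above BM by a
half-ellipsoid (`h·sqrt(1 − ((x−cx)/a)² − ((B−cB)/b)²)`); confounding
fluid pockets carve the same shape into the bright band just *above* the
floor, so the bright→dark edge jumps to the pocket roof and the initial
mask acquires a genuine false-positive region whose truth label is
negative. Overlapping cap footprints are rejected (they would force
surface crossings). Speckle is unit-mean multiplicative gamma noise
(default sd 0.25), the standard first-order OCT speckle surrogate.

The default experiment (`phantom_experiment()`, also run by
`scripts/acceptance.R`) uses 128 × 16 × 160-voxel phantoms — large enough
for every stage to operate at realistic geometry, small enough that the
20-train/10-test study runs in about two minutes on one CPU. Caps are
drawn with half-width 18–30 voxels, apex 10–18; pockets with half-width
5–9, apex 3–6, placed with disjoint footprints.

What passing these tests shows: every algorithmic component is correct
against independent oracles, the stages compose, and the trained filter
separates arch-shaped PEDs from pocket confounders and hull slivers under
multiplicative noise. What it does not show: performance on clinical
data. The phantom has piecewise-constant tissue, no shadowing, vessel
artifacts, motion, roll-off or real speckle correlation, and its
confounders are geometrically simple. Clinical validation would require
expert-annotated volumes.

## Known limitations

* Feature extraction is 2D per B-scan; regions are kept or deleted whole,
  so a confounder that merges with a true PED region through a thin
  sliver on a B-scan is retained by the filter (the graph cut and
  morphology then trim what intensity and shape allow).
* The graph metric ignores voxel anisotropy.
* BM estimation by convex hull cannot follow a genuinely concave BM
  (e.g. posterior staphyloma) and assumes pathology lifts the floor
  *upward* only.
* The DP solver decouples B-scans; enable the min-cut solver
  (`delta_b` finite) when cross-B-scan smoothness matters more than
  runtime.
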