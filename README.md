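# pedseg

Automated 3D segmentation of **serous pigment epithelium detachment (PED)**
in spectral-domain OCT volumes, with a synthetic-phantom workbench for
training and validating every stage without clinical data.

A serous PED is a fluid-filled, arch-shaped separation of the retinal
pigment epithelium (RPE) from Bruch's membrane (BM). On an OCT B-scan it
appears as a smooth hyporeflective dome between the lifted **RPE floor**
and the near-straight BM baseline. Quantifying its volume and extent
matters for managing AMD, central serous chorioretinopathy and polypoidal
choroidal vasculopathy; `pedseg` is aimed at image-analysis researchers who
need a reproducible, fully automatic pipeline for that task.

## The method

For an intensity volume `I(x, B, z)` (lateral, B-scan, depth):

1. **Denoising** — modified curvature diffusion equation,
   `u_t = |∇u| div( c(|∇u|) ∇u/|∇u| )` with `c(g) = exp(−(g/K)²)`,
   run per B-scan: speckle is smoothed while layer edges (large `|∇u|`)
   diffuse weakly.
2. **Layer segmentation** — three sequential optimal-surface searches
   (minimum total edge cost over all surfaces with one `z` per column,
   subject to a smoothness bound `|z_i − z_j| ≤ Δ` between adjacent
   columns), each run at three axial scales: ILM, photoreceptor
   ellipsoid-zone roof (dark→bright polarity) and RPE floor (bright→dark).
   The solver is a per-B-scan dynamic program or a minimum-closed-set
   *s–t* min-cut when B-scans are coupled.
3. **BM estimation** — per B-scan, the maximal-z boundary of the convex
   hull of the RPE-floor trace; the slab `(z_RPE, z_BM]` is the initial
   PED mask.
4. **False-positive filtering** — each 2D connected candidate region gets a
   62-dimensional feature vector (shape moments, intensity statistics,
   distances to the four surfaces, directional extrema, multi-scale Hessian
   eigenvalue means); a discrete AdaBoost ensemble of decision stumps
   (`α_t = ½ ln((1−ε_t)/ε_t)`) deletes background regions.
5. **Shape-constrained graph cut** — energy
   `E(f) = Σ_p [λ_R R_p(f_p) + λ_S S_p(f_p)] + λ_B Σ_{pq} B_{pq}[f_p ≠ f_q]`
   with Boykov–Jolly histogram likelihoods `R`, shape term
   `S_p(obj) = min(d(p)/r, 1)` from the distance `d` to the refined region
   and its enclosing radius `r`, and gradient-modulated boundary weights
   `B_{pq} = exp(−(I_p−I_q)²/2σ²)`. Seeds are derived automatically by
   adaptive ball morphology — erosion with radius `r = round(0.143·V^{1/3})`
   for foreground, dilation with `c = 1.143` for background — and the
   energy is minimized exactly by max-flow.
6. **Morphological refinement** — per region, geodesic reconstruction of
   the ball-eroded marker (`c = 0.200`) then ball closing (`c = 0.700`),
   removing specks/spurs and filling grooves.
7. **Evaluation** — TPVF, FPVF, DSC, PPV against a reference mask, plus
   regression/Bland–Altman agreement and paired *t*-tests for volume series.

The phantom generator (`generate_phantom()`) builds seeded volumes with
known surfaces, half-ellipsoid PED caps, optional confounding fluid pockets
and multiplicative gamma speckle, so the whole pipeline is trainable and
testable end to end.

## Worked example

```r
library(pedseg)

# a 128 x 16 x 160 phantom with one PED cap, plus speckle
params <- phantom_params(seed = 42)
ph  <- generate_phantom(params)
vol <- add_speckle(ph$volume, scale = 0.25, seed = 42)

res <- run_pipeline(vol, clf = NULL, truth = ph$truth)
res$metrics
#> TPVF 99.95%  FPVF 2.610%  DSC 65.70%  PPV 48.93%

# train the false-positive filter on 20 phantoms, test on 10
ex <- phantom_experiment(n_train = 20, n_test = 10, seed = 1)
ex$metrics[ex$metrics$volume == "mean", c("tpvf", "fpvf", "dsc", "ppv")]
#>      tpvf        fpvf       dsc       ppv
#> 0.9973158 0.003667086 0.9226776 0.8606494
```

The first run passes `clf = NULL`, so every candidate region of the
initial mask survives: sensitivity is near-perfect (TPVF 99.95%) but the
thin false-positive slivers along the estimated Bruch's membrane drag the
Dice coefficient down to 66%. With the AdaBoost filter trained on 20
disjoint phantoms, the mean Dice coefficient over 10 test phantoms rises
to 92% and the false-positive volume fraction falls to 0.37% of the
non-PED retina — the filter is what turns the over-sensitive initial
segmentation into a usable one.

A command-line driver with per-stage subcommands (`simulate`, `denoise`,
`layers`, `features`, `train`, `classify`, `segment`, `evaluate`, `run`)
is installed at `inst/cli/pedseg.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "pedseg.R", package = "pedseg"))')" \
    simulate --out vol.nii.gz --truth-dir truth/ --seed 1
```

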