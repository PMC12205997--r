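---
title: "Multiscale cortical morphometry: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale cortical morphometry: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Conventional cortical morphometrics — total pial surface area, mean
cortical thickness — are measured at a single spatial scale: the
resolution of the surface reconstruction. Folding, however, is organized
across scales, from sub-millimetre sulcal detail to lobe-level
undulation, and different scales can age differently. This package
measures morphometry as a *function of scale*: the reconstructed
pial/white surface pair is re-rendered at a ladder of cut-off lengths
λ, folding features smaller than λ are deleted, and area and thickness
are recomputed at each λ. The outputs feed two statistical analyses:
normative lifespan trajectory models per (structure, λ, metric), and a
brain-age comparison demonstrating that area measured at two scales is
more informative than at either alone.

# Coarse-graining procedure

For each scale λ the pipeline:

1. **Voxelizes** the closed pial and white meshes at voxel side λ. A
   voxel is white matter if its center lies inside the white mesh, gray
   matter if inside the pial mesh only. Inside/outside is decided by
   scanline ray-casting parity (one ray per voxel row), which the test
   suite cross-checks against the generalized winding number. The grid
   is aligned to the pial bounding box with a one-voxel background
   margin and its origin snapped down to a multiple of λ, so placement
   is deterministic; metrics still carry O(λ) placement jitter, which is
   why geometric tests use tolerances. A fixed user-supplied origin is
   supported.
2. **Re-renders surfaces** from the binary masks (gray∪white for the
   coarse pial, white alone for the coarse white) by isosurface
   extraction at level 0.5. Cells are contoured by polygon tracing: the
   surface/cube-face intersection segments are determined per face (with
   the bilinear asymptotic decider for ambiguous faces), chained into
   loops and fanned. Because a face's segments depend only on that
   face's values, adjacent cells always agree and the mesh is watertight
   by construction. Vertices interpolate linearly along cell edges.
3. **Builds exposed surfaces**: the convex hull of the coarse pial
   (quickhull), and optionally a closing-based outer surface (binary
   closing with a 15 mm-diameter ball via exact Euclidean distance
   transforms; the ball radius rounds *up* in voxels, erring toward the
   physical 15 mm ball at coarse λ).
4. **Computes hemisphere metrics**: `A_t` (triangle-area sum of the
   coarse pial), `A_e` (hull area by default; closing-surface area by
   configuration), `V_GM` (gray voxel count × λ³) and the ratio
   thickness `T = V_GM / A_t`.
5. **Computes lobe metrics**: labels transfer from the original pial
   surface by nearest vertex (ties to the lowest index); triangles are
   assigned to the 2-of-3 majority label of their vertices, which makes
   lobe areas an exact partition of `A_t`; lobe thickness is the mean
   minimum pial-vertex-to-white-surface distance (exact point-to-triangle
   projection with grid-pruned candidates); insular area and thickness
   are redistributed to frontal/parietal/temporal lobes proportionally
   to their areas.

One "native" row per subject is computed from the input meshes directly:
`A_t` from triangles, `A_e` from the hull of the original pial, and
hemisphere `T` as (pial volume − white volume)/`A_t` for consistency
with the coarse-grained ratio definition. Surface-reconstruction
toolchains report native thickness differently (vertex-paired
distances), so native `T` here is comparable *within* this pipeline, not
across tools.

The ladder is λ_k = 10^(−0.5 + 0.07k): 0.32 mm to 3.02 mm for
k = 0..14, log-spaced because reconstructions change fastest at small λ.
The display value "1.86 mm" is ladder index k = 11; full-precision λ is
the join key in all tables, the 2-dp value only a display column.

## Why the masks are box-smoothed before contouring

Contouring a *raw binary* mask at level 0.5 places every vertex at an
edge midpoint. The resulting staircase facets overestimate the area of a
smooth surface by ≈8% — and the bias does not vanish with resolution
(measured on voxelized spheres from radius 10 to 60 voxels). Applying
the conventional 3×3×3 box filter to the indicator before contouring
removes the bias: the sphere area is then correct to ~0.3% at
λ = R/60. `extract_isosurface(smooth = TRUE)` is therefore the default
everywhere; `smooth = FALSE` reproduces the literal binary behaviour (a
single voxel yields the midpoint octahedron of area √3 λ²), retained
because the binary variant is the cleaner object for unit-level
reasoning. The cost of smoothing is an effective extra smoothing window
of 3λ: at the coarsest scales it attenuates marginally-resolved folds
somewhat more aggressively than voxelization alone.

## Exposed area: hull versus closing

Hemisphere-level exposed area uses the convex hull; lobe-level exposed
area uses the closing-based surface (labels transfer poorly to a hull,
whose facets span sulci far from any one lobe). Both are implemented and
`sweep_config(ae_mode=)` switches the hemisphere definition.

# Synthetic study conditions

Real structural MRI and its surface reconstruction are out of scope; the
generators produce inputs with known answers.

**Folded phantom.** The pial surface is
r(θ, φ) = R + a·sin(mθ)·sin(mφ) triangulated over a subdivided
icosahedron; the white surface is the same surface offset inward by t
*along the ray*, so the pial-to-white distance is exactly t radially —
an analytic thickness oracle (tests use 2% tolerance for the
mesh-sampling error). A separable sinusoid was chosen over spherical
harmonics because it has one unambiguous dominant arc-wavelength,
2πR/m — the single knob for "feature size" that the fold-removal tests
need. The radial (not normal) offset avoids self-intersection at high
fold amplitude. Headline phantom: R = 30 mm, a = 3 mm, m = 12
(wavelength ≈ 15.7 mm), t = 2.5 mm, icosphere subdivision 4 (5120
faces; the tests' problem size — subdivision 5+ changes results by well
under the test tolerances). With a = 0 the generator produces
concentric spheres whose area, volume and thickness have closed forms;
these anchor the trust chain for every downstream operator.

**Quadrant labels.** Four azimuthal sectors (octants merged across the
equator) play the role of lobes, plus a small circular "insula" cap
(angular radius 25°, <5% of vertices) centered in the frontal sector —
the minimal topology exercising label transfer and insula
redistribution.

**Cohort.** n = 800 subjects, ages uniform on [6, 88] years, two sites,
balanced sexes — a desk-scale stand-in for a pooled two-site lifespan
sample. Mean trajectories (see `cohort_preset()`): native-scale area
declines ~10% across life; 0.32 mm area is nearly flat (−3%); 1.86 mm
area *rises* ~25%; thickness declines at every scale, steepest in
childhood (exponential with 15-year constant), with both the decline
fraction and the offset increasing with scale. Site and sex act
additively (site −1800 mm² / −0.05 mm; sex ±3800 mm² / ±0.02 mm);
residual noise is Gaussian, ~3% of the area means. That noise level is
what makes the brain-age comparison informative rather than trivial:
each single-scale model explains age only moderately (adjusted R² ≈
0.4), while the two opposite-signed predictors together reach ≈ 0.55.
These curve shapes are this package's own choices — only their signs and
orderings are meaningful, and no test asserts their particular values.

What the generators deliberately do **not** emulate: reconstruction
artifacts and topology errors, regional heterogeneity of folding,
hemispheric asymmetry, non-Gaussian site batch effects, longitudinal
structure. Passing tests therefore validate the *operators*, not claims
about real cohorts.

# Normative trajectory model

Per (structure, λ, metric), the metric y (log10-transformed by default,
matching the log-scale on which such metrics are usually displayed) is
modelled with a four-parameter Box–Cox power exponential distribution:
μ (location, log link), σ (scale, log), ν (Box–Cox power / skew,
identity), τ (tail weight, log; τ = 2 is Box–Cox normal). The usual
centile-estimation convention of neglecting the Box–Cox truncation mass
is followed. A Gaussian location-scale family (ν, τ fixed) is available
via `normative_config(family = "gaussian")`.

Each distribution parameter gets a cubic P-spline in age — 20 equally
spaced knots on [6, 88], second-order difference penalty — plus additive
site offsets on μ and log σ and a sex contrast on μ, log σ and ν,
both ridge-penalized (weight 0.01). The ridge stands in for
random-effect shrinkage: exact integrated-likelihood random effects are
out of scope, and for a 2-site design at these sample sizes the
penalized-offset estimate coincides with the shrinkage limit for
practical purposes (site-contrast recovery is within ~4% in the
acceptance run).

Fitting is cyclic backfitting: for each parameter in turn, the score and
curvature of the log-likelihood with respect to that parameter's linear
predictor are evaluated by central finite differences (step 10⁻⁴,
curvature floored at 10⁻⁶ and replaced when non-finite), a working
response is formed, and a penalized weighted least-squares update is
solved; step-halving (down to 2⁻¹⁴ of the step) guarantees the deviance
never increases, and the deviance path is stored so the monotonicity
invariant is checkable. Shape parameters are frozen for the first 3
outer iterations. Convergence is an absolute deviance change below 10⁻³
(at most 200 outer iterations; non-convergence flags the model and
raises a warning rather than failing silently). The smoothing multiplier
is chosen on the grid {1, 10, 100, 1000} (base weights 1 for μ, 10 for
σ/ν/τ) by generalized AIC with penalty 2·edf, where edf sums
tr((XᵀWX + P)⁻¹XᵀWX) over parameters. The grid's top end matters: with
pure-noise input, GAIC must be able to buy an essentially constant
location curve.

Population quantile curves marginalize covariates: site offsets are
averaged with training proportions on the predictor scale, the two
sex-specific *natural-parameter* sets are averaged with training sex
proportions, and the family CDF is inverted at the averaged parameters —
one overall trajectory for both sexes. Individual deviation scores are
quantile residuals, Φ⁻¹(F(y)), using the subject's own offsets; unseen
sites score with a zero offset and are flagged. On data simulated from a
fitted model the scores are standard normal (Kolmogorov–Smirnov checked
in the tests).

# Brain age

Three additive models predict age from pial area: a thin-plate smooth of
the native-scale area, of the 1.86 mm area, or both, each with fixed
effects of sex and site, fitted by `mgcv::gam` with GCV smoothing
selection (basis dimension 10 per smooth). Adjusted R² is
1 − (1 − R²)(n − 1)/(n − edf − 1) with edf the *effective* degrees of
freedom of the penalized fit (intercept excluded) — stated explicitly
because the raw coefficient count would over-penalize the smooths.
Uncertainty comes from a case-resampling bootstrap (subjects resampled
with replacement, full refit per replicate; seeded and bit-reproducible;
replicates that lose a factor level refit without that term and are
flagged). No regression-to-the-mean bias correction is applied to the
predictions, so the predicted-versus-actual slope sits strictly between
0 and 1 on noisy predictors — the attenuation is reported, not hidden.

# Numerical choices and degenerate inputs

- Isosurface ambiguity ties (saddle exactly at level, the generic binary
  case) resolve to "diagonal corners separated", a convention that
  depends only on the shared face, preserving watertightness.
- Loop orientation uses the trilinear field gradient at the loop
  centroid; outward is down-gradient.
- Quickhull treats points within 10⁻¹⁰·(bounding diagonal) of a face
  plane as interior, so cospherical inputs terminate; degenerate
  (coplanar) inputs raise classed errors.
- Closing with a ball smaller than one voxel is the identity; the grid
  is padded by the ball radius so dilation never clips.
- `voxelize_pair` refuses λ larger than the mesh bounding box
  (degenerate grid) and empty-tissue isosurface requests fail loudly.
- Nearest-vertex ties in label transfer go to the lowest vertex index;
  empty lobes yield `NA` thickness (never silent zeros).
- A white mesh coincident with the pial mesh voxelizes to zero gray
  voxels and is handled (the empty-shell case).

# Known limitations

- The hull-versus-pial area comparison inverts at the coarsest scales on
  the folded phantom: once folds are essentially removed (λ ≈ 2.5–3 mm
  against a 15.7 mm fold wavelength), the re-rendered surface is a
  faintly dented sphere, and a dented sphere has *less* area than its
  convex hull (a dimple replaces a spherical cap with a flatter, smaller
  patch). Measured hull/pial reaches 1.003 there, against 0.95–0.99 at
  resolved scales. This is a property of the phantom's single-wavelength
  folding, not of the operators; strongly folded inputs keep hull areas
  below pial areas across this ladder. Acceptance asserts strict
  inequality where folding is resolved (λ ≤ 2.2 mm) and a 1% bound on
  the ratio over the full ladder.
- Binary-mask isosurface areas are only unbiased *because of* the box
  pre-filter; turning smoothing off trades unbiased areas for the exact
  midpoint geometry.
- The trajectory fitter is a purpose-built penalized backfitting
  estimator, not a re-implementation of any particular GAMLSS software;
  equality with other implementations is not claimed (an independent
  location-scale smoother from `mgcv` agrees with it to well under the
  residual noise in the tests).
- Native-scale thickness uses the volume/area ratio, which runs ~8%
  below the radial-offset truth on a thick spherical shell (the exact
  V/A geometry of a shell); the distance-based lobe definition does not
  share this offset. The two definitions agree within 15% on thin
  shells, and the tests pin both behaviours.
- Metrics carry O(λ) grid-placement jitter by design; only
  multiple-of-λ translations leave them exactly invariant.

# Problem sizes

Tests run the phantoms at icosphere subdivision 3–4 (up to 5120 faces)
with full 15-scale ladders hemisphere-level and k ≤ 2 ladders
lobe-level; the fold-retention check uses a subdivision-6 phantom
(81 920 faces) at two scales. Cohort analyses use n = 800 with 200
bootstrap replicates in tests and B = 1000 in the analysis scripts.
These sizes keep the whole suite within a few minutes on one CPU while
leaving every tolerance comfortably dominated by method error, not
sampling error.
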