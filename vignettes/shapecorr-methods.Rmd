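---
title: "Statistical shape modeling with particle-based correspondences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical shape modeling with particle-based correspondences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shapecorr)
```

## The problem

Developmental studies frequently need to decide whether two groups of
specimens — say, wildtype versus gene-deficient mice — differ in the
*shape* of an anatomical structure, beyond differences in size. Classical
landmark-based morphometrics requires an expert to click a handful of
homologous points on every specimen. `shapecorr` instead computes dense
correspondences automatically: it places k particles on every segmented
surface so that index i on specimen 1 is geometrically homologous to index
i on every other specimen, then treats the flattened particle
configurations as multivariate observations for standard statistics.

The pipeline is:

1. binary segmentation → signed-distance implicit surface
   (`mask_to_sdf()`),
2. particle-based correspondence optimization over the whole ensemble
   (`optimize_correspondence()`),
3. per-shape normalization — centroid removed, root-mean-square point
   radius scaled to 1 — plus optional generalized Procrustes rotation
   (`center_and_scale()`, `procrustes_rotate()`),
4. PCA of the n × 3k shape matrix with mode retention by parallel analysis
   (`fit_pca()`, `parallel_analysis()`),
5. two-group inference on the retained loadings: Hotelling T² with
   parametric and permutation p-values, a multivariate Levene battery for
   dispersion differences, and the Fisher discriminant mapped back to
   shape space as per-particle arrows (`compare_groups()`).

A synthetic population generator (`generate_population()`) with planted,
parameterized group effects makes every stage testable end to end without
external data.

## The correspondence model

Each shape is the zero level set of a signed distance field φ (negative
inside). A particle system is a set of n × k surface points. The optimizer
minimizes the combined model entropy

Q = w_e · n · H(Z) − w_s · Σₐ H(Pₐ),

where H(Pₐ) is a Parzen-window entropy of the particles on shape a
(maximizing it spreads particles uniformly; its negative acts as pairwise
Gaussian repulsion) and H(Z) = ½ Σⱼ log(λⱼ + α) is the entropy of the
ensemble of flattened configurations, with λⱼ the eigenvalues of their
sample covariance computed through the dual n × n problem. Minimizing H(Z)
drives the ensemble toward a compact, low-rank statistical model — which
is precisely what makes the particle indices correspond.

Numerical realization:

* **Kernel widths.** Each particle's Gaussian σ is bisected so its
  weighted neighbor count hits `target_neighbors` (default 6), then capped
  at 1.3× its nearest-neighbor distance. The cap matters after splits:
  with a twin at close range the count criterion inflates σ past the local
  spacing, which flattens the repulsion and stalls spreading.
* **n-scaling of the ensemble term.** The gradient of H(Z) with respect to
  a single shape's particles shrinks roughly like 1/n, while the sampling
  gradient is n-independent. The term therefore enters as
  `ensemble_weight · n · H(Z)`; with the default `ensemble_weight = 0.1`
  this reproduces a classical 1:1 balance at n = 10 and keeps
  correspondence anchoring effective at n = 36, where a fixed 1:1 weight
  measurably loses correspondence (within-group particle deviation grows
  to ~50% of a semi-axis).
* **Schedule.** Particles are split 1 → 2 → … → k, children displaced by
  the *same* seeded offset on every shape (correspondence by
  construction), then projected back to their surfaces. After every split
  a short uniform-spread phase (6 iterations) resolves the twins and a
  joint phase (sampling + ensemble) re-anchors correspondence. Running the
  joint phase at every level is essential: spread-only evolution lets
  specimens settle into different symmetry basins that no later phase can
  permute back.
* **Steps.** Projected gradient descent with per-particle σ²
  preconditioning, a trust region of 0.5σ per move, backtracking on the
  frozen-parameter objective (so accepted steps never increase Q), and
  Newton re-projection onto each surface after every step. The only
  randomness is the seeded split offsets, so runs are exactly
  reproducible, and all length-like controls are expressed relative to the
  ensemble bounding-box diagonal, making converged systems equivariant
  under global rescaling.
* **Initialization.** One particle per shape at the zero-band voxel
  nearest the foreground centroid, with near-ties (within one voxel)
  broken toward larger z, then y, then x. On symmetric shapes the nearest
  surface point is not unique, and noise-dependent tie-breaking would
  place specimen 1's first particle on a different face than specimen 2's
  — an error no amount of later optimization can repair.

## Signed distance fields

With `smoothing_sigma = 0`, φ is the exact Euclidean distance transform of
the voxel centers, composed inside/outside. This is exact but its zero
level set inherits the voxelization staircase and the value jumps by 2h
across the foreground/background seam. With the default
`smoothing_sigma` of one voxel the mask is antialiased by Gaussian
smoothing, subvoxel seed distances |ψ|/|∇ψ| are planted at sign-change
voxels of ψ = 0.5 − smoothed mask, and a fast-sweeping eikonal solve
re-distances the band near the surface; because first-order sweeps
accumulate error along converging characteristics, the far field is
blended back to the exact composed transform. On digitized balls at 8–24
voxels per radius this keeps |∇φ| within [0.85, 1.19] near the surface,
the center value within a fraction of 1.5h of −R, and marching-tetrahedra
surface area within 5% of the analytic value.

Meshes are extracted by marching tetrahedra on the Kuhn 6-tetrahedron cube
subdivision, which is translation-consistent across cube faces and
therefore watertight by construction (Euler characteristic 2 on balls).

## Group statistics

With group loadings A (n_a × m) and B (n_b × m) on the m retained modes,
the scatter matrices Σₐ, Σ_b (sums of outer products of within-group
deviations) give the Fisher discriminant w = (Σₐ + Σ_b)⁻¹(μₐ − μ_b) and

T² = [nₐ n_b (nₐ + n_b − 2) / (nₐ + n_b)] (μₐ − μ_b)ᵀ w,

the standard two-sample form, whose F transform
F = T²(N − m − 1)/[m(N − 2)] on (m, N − m − 1) degrees of freedom gives the
parametric p. A `prefactor = "printed"` option computes the constant
(nₐ + n_b − 2) instead; permutation p-values are provably (and, by test,
bit-exactly) invariant to this choice since a constant factor cancels in
rank comparisons.

The permutation test permutes group labels B times and reports
p = (1 + #{T²_perm ≥ T²_obs})/(1 + B); when choose(nₐ+n_b, nₐ) ≤ B the
enumeration is exhaustive and p is the exact fraction. Monte-Carlo paths
canonicalize the group order internally (smaller group first, exact ties
broken lexicographically) so swapping the groups leaves p bit-identical.

The Levene battery measures each observation's Euclidean distance from its
group center — mean, or coordinate-wise median for the robust
Brown–Forsythe-style variant — and compares deviations with a
pooled-variance two-sample t test; "randomized" variants replace the t
reference by the permutation null of the same statistic. The coordinate-wise
median (not the geometric median) is used as the multivariate median,
the simplest extension consistent with the univariate robust variant.

The discriminant is visualized by zero-padding w from m to the full mode
count r, mapping through the orthonormal basis (ŵ = E w̃), and reshaping to
k × 3 arrows anchored at the reference group's mean correspondences,
oriented reference → contrast. Arrow lengths are statistical quantities;
any display exaggeration is the plotting layer's concern.

**Per-comparison PCA.** The PCA and parallel analysis are fit on the union
of the two groups under comparison (not on all groups jointly), so each
pairwise comparison reports its own retained mode count, matching the
study design this package reproduces.

## The synthetic population

`population_spec()` describes a family of superellipsoid (p-norm, default
exponent 4) shapes: the boxy exponent gives flat faces and edge-like
features that exercise correspondence harder than ellipsoids. Within-group
variation multiplies the semi-axes by log-normal noise (positivity by
construction; default SD 0.03 on the log scale, the magnitude of
within-litter skeletal variation one would expect in an inbred line).
Group effects are C¹ radial displacements with compact angular support:
`"lateral_bump"` (outward, centered +y) and `"edge_inflection"` (inward,
centered +x, a synthetic stand-in for a bent posterior edge). Voxelization
samples the implicit inequality at voxel centers on an isotropic grid
sized to keep ≥ 2 voxels of background margin; shapes are star-convex, so
every volume is one 26-connected, closed-surface component. An optional
per-specimen random rotation (default off) exposes pose nuisance for
alignment experiments.

Defaults chosen once, and why:

* `base_axes = c(8, 5, 3)` world units at `voxel_spacing = 0.5` — a
  plate-like element ~16 × 10 × 6 voxels per semi-axis, the relative
  resolution regime of a small-bone microCT segmentation.
* "strong" effect amplitude = half the lateral semi-axis
  (`base_axes[2]/2`): a deformation a trained observer would see at a
  glance; the power/recovery acceptance checks use it, per the design goal
  that generator defaults serve test power rather than mimic any specific
  biology (no quantitative effect sizes exist to copy).
* Null populations are the same family with effect amplitude 0, which
  reproduces the no-effect family exactly (bit-identical volumes).

What a green test does and does not establish: the generator produces
smooth, star-convex, single-component shapes in a shared pose. It does not
emulate scanner noise, partial-volume effects, segmentation-rater
variability, multi-component or high-genus anatomy, or pose nuisance
(unless enabled). Statistical calibration and recovery results transfer to
real data only insofar as those complications are handled upstream.

## Alignment choices

The source analysis normalizes scale only (RMS point-to-centroid distance
= 1), treating size as a separate question; the removed per-specimen scale
factors are recorded for exactly that purpose. Rotational alignment is not
specified there; this package defaults to generalized Procrustes rotation
(no scaling, no reflection) before PCA, because synthetic populations with
pose nuisance would otherwise let orientation dominate the shape space.
`procrustes_rotate(enable = FALSE)` gives the literal scale-only reading.
Scale normalization happens after correspondence optimization, before
statistics.

## Numerical choices and degenerate inputs

* Parallel analysis: n_draws synthetic matrices of independent normals
  scaled to the data's per-column SDs; m = length of the leading run of
  data eigenvalues above the 95th percentile (default) of the matched null
  eigenvalue; deterministic given its seed. In the pipeline m is floored
  at 1 so downstream tests are always defined.
* Permutation p-values use the (1 + count)/(1 + B) convention (never
  exactly zero); permutations with singular scatter are re-drawn and
  counted.
* Coincident particles: the Parzen gradient is norm-capped, never NaN; a
  degenerate SDF gradient during projection triggers a deterministic axis
  nudge rather than silent divergence.
* All-zero Levene deviations yield p = 1 with a warning.
* Zero-scale (all points coincident) configurations are a normalization
  error.

## Known limitations

* **Localized deformations are partially absorbed tangentially.** Under a
  planted localized bump the per-particle radius responds linearly to the
  amplitude with near-zero residual, but with attenuated gain: the entropy
  objective allows particles to slide slightly along the surface,
  absorbing part of a *localized* deformation into tangential
  re-parameterization. Group separation and arrow localization are
  unaffected (both at ceiling in the acceptance checks), but per-particle
  displacement magnitudes under-estimate the planted radial displacement.
  Global smooth deformations (axis scalings) are tracked to within 6%
  residual variance.
* The optimizer assumes a shared pose or enabled Procrustes alignment; it
  has no rotation-invariant matching.
* First-order fast sweeping limits SDF accuracy near medial axes; the far
  field is blended to the exact composed transform, so only the
  mid-distance band (~4–8 voxels from the surface) carries a few percent
  distance error.
* Statistics are two-group only (pairwise comparisons, raw p-values), by
  design.
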