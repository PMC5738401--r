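# shapecorr

Statistical shape modeling of populations of segmented 3D structures, for
biologists and morphometricians who need to ask: *do these two groups of
specimens differ in shape, where, and in spread?* — without hand-placed
landmarks.

`shapecorr` converts binary segmentations into signed-distance implicit
surfaces, distributes k corresponding particles across every specimen by
minimizing the combined model entropy

> Q = H(Z) − Σₐ H(Pₐ),

(H(Z) = ½ Σⱼ log(λⱼ + α), the entropy of the ensemble of flattened
particle configurations; H(Pₐ), a per-shape Parzen entropy whose
maximization spreads particles uniformly), and then runs the classical
morphometric battery on the normalized configurations:

* PCA of the n × 3k shape matrix (dual-space solve), with the number of
  retained modes m chosen by Horn-style **parallel analysis**;
* two-group **Hotelling T²** on the m loadings,
  T² = nₐn_b(nₐ+n_b−2)/(nₐ+n_b) · (μₐ−μ_b)ᵀ(Σₐ+Σ_b)⁻¹(μₐ−μ_b),
  with the exact parametric F transform and a label-permutation null;
* a multivariate **Levene battery** (mean / median centers, parametric and
  permutation references) for dispersion differences;
* the **Fisher discriminant** w = (Σₐ+Σ_b)⁻¹(μₐ−μ_b), zero-padded and
  mapped through the orthonormal PCA basis back to shape space as one
  difference arrow per correspondence point.

A synthetic superellipsoid population generator with planted,
parameterized group effects (localized bumps, edge inflections) provides
ground truth for end-to-end validation; see the methods vignette
(`vignettes/shapecorr-methods.Rmd`) for the model, defaults and
limitations.

## Worked example

Generate a two-group population (10 wildtype-like, 10 with a strong
lateral bump planted on the +y flank), run the full pipeline at k = 64
correspondences, and inspect the comparison:

```r
library(shapecorr)

spec <- population_spec(
  n_per_group      = c(wt = 10, mut = 10),
  base_axes        = c(4, 2.5, 1.5),     # world units
  within_group_sd  = 0.05,               # log-scale axis noise
  effect_name      = "lateral_bump",
  effect_amplitude = c(0, 1.25),         # planted only in "mut"
  voxel_spacing    = 0.5,
  seed             = 1)

res <- run_pipeline(pipeline_config(
  spec = spec, k_target = 64, B_perms = 500, master_seed = 12,
  comparisons = list(c("wt", "mut"))))

print(res)
```

```
<pipeline_result> 20 specimens, 1 comparisons
<group_comparison> wt vs mut (n=10/10, m=2)
  T2 = 43.78, parametric p = 2.804e-05, permutation p = 0.001996 (B=500)
  Levene p: mean 0.158 / median 0.642 / rand mean 0.142 / rand median 0.629
```

Reading the output: parallel analysis retained m = 2 PCA modes; the mean
shapes differ strongly (T² = 43.8 on 2 modes; the permutation p is at its
floor 1/(B+1), i.e. no permutation reached the observed statistic), while
the Levene battery finds no dispersion difference — the groups differ in
*where* they are in shape space, not in how much they vary. The planted
effect is recovered spatially:

```r
gc   <- res$comparisons[[1]]$comparison
mw   <- group_mean_shape(res$comparisons[[1]]$sub, "wt")
top  <- order(rowSums(gc$arrows^2), decreasing = TRUE)[1:7]
mean(effect_support(mw, "lateral_bump", pi / 3)[top])
```

```
[1] 1
```

— 100% of the top-decile discriminant arrows fall inside the planted
bump's angular support. `export_visuals(res, "out/")` writes the group
mean shapes, per-mode walks at ±1, 2, 3 σ, and a VTK polydata with the
arrows for glyph rendering; `write_report(res, "report.json")` stores a
machine-readable report that is byte-identical across reruns with the same
master seed.

## Command line

```sh
Rscript inst/cli/shapecorr.R synth      --config spec.json     --out data/
Rscript inst/cli/shapecorr.R correspond --config corr.json     --out particles/
Rscript inst/cli/shapecorr.R run        --config pipeline.json --out results/
```

Configs are JSON mirrors of `population_spec()` / `pipeline_config()`
arguments.

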