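# mvpdR — multivariate pattern dependence for fMRI

Classical seed-based functional connectivity reduces each brain region to
its spatial-mean BOLD timecourse and correlates two regions' low-pass
filtered means. That measure is blind to everything a region encodes in
*patterns* of response that cancel across voxels. **Multivariate pattern
dependence (MVPD)** models each region's response as a trajectory in a
PCA-derived representational space and quantifies between-region
dependence by how well one region's trajectory linearly predicts the
other's in held-out runs.

For seed region `Y` and predictor region `X` with timepoints as rows,
each leave-one-run-out fold:

1. fits PCA bases on the concatenated training runs
   (`Y = U S Vᵀ`), retaining `k` components per region (BIC-selected or
   fixed `k ∈ {1,2,3}`);
2. fits `Ỹ = X̃ B + E` by OLS between the reduced timecourses;
3. predicts the held-out run, scoring each seed dimension by
   `r_j = corr(Ŷ_j, Ỹ_j)` and summarizing with
   `r̄ = Σ_j w_j r_j`, `w_j = S(j,j) / Σ_l S(l,l)`;
4. back-projects the prediction to voxel space and scores the
   cross-validated voxelwise variance explained
   `v(j) = 1 − SS(Y_j − Y̆_j)/SS(Y_j)`, averaged into `v̄` — the common
   target that makes MVPD and mean-based connectivity comparable.

The package also provides: matrix-level de-noising (128 s discrete-cosine
high-pass, CompCor components from a white-matter/CSF control region,
nuisance regression, censoring, univariate-signal removal), the standard
and leave-one-out univariate connectivity baselines, searchlight mapping
over a gray-matter mask (6 mm spheres; per-dimension maps, top-N voxel
selection, map-similarity matrices), one-sample sign-flip permutation
inference with max-statistic FWE control, a synthetic multi-run generator
with known ground truth, NIfTI I/O, and a small command-line wrapper
(`inst/cli/mvpd.R`, subcommands `subject`, `group`, `simulate`, `fc`).

## Worked example

Dependence carried purely by spatial patterns — the scenario mean-based
connectivity cannot see:

```r
library(mvpdR)

# two 80-voxel regions, 3 runs x 360 volumes, latently coupled, with the
# signal loadings constrained to zero spatial mean
ds <- generate_synthetic_dataset(synthetic_spec(pattern_only = TRUE,
                                                rng_seed = 1))

standard_fc(ds$seed, ds$predictor)
#> <fc_result> method 'standard_fc': r = -0.0062 over 3 runs

crossvalidated_mvpd(ds$seed, ds$predictor,
                    mvpd_config(component_mode = "fixed", k_fixed = 3))
#> <mvpd_result> method 'mvpd': r_bar = 0.9360, v_bar = 0.2717 over 3 folds

loo_univariate(ds$seed, ds$predictor)
#> <mvpd_result> method 'loo_univariate': r_bar = 0.0646, v_bar = -0.0000 over 3 folds
```

Standard FC sees essentially nothing (`r ≈ −0.006`) and the mean-based
leave-one-out baseline explains no held-out voxel variance, while MVPD
recovers the coupling (`r̄ = 0.94`) and explains 27 % of held-out voxel
variance. Per-dimension detail is in the result's `folds`: for fold 1 the
dimension correlations are `0.959 0.936 0.873` with spectrum weights
`0.481 0.326 0.193`.

Searchlight and group stages follow the same pattern
(`run_searchlight()`, `signflip_fwe_test()`); see the vignette in
`vignettes/mvpd-methods.Rmd` for the model, assumptions and design
choices.

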