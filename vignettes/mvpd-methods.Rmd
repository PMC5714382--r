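---
title: "Multivariate pattern dependence: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multivariate pattern dependence: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvpdR)
```

## The problem

Classical seed-based functional connectivity summarizes each brain region by
one number per timepoint — its spatial-mean BOLD response — and correlates
two regions' low-pass-filtered means. Anything a region encodes in
*patterns* of response that average out across voxels is invisible to that
measure. Multivariate pattern dependence (MVPD) instead treats each region's
response as a trajectory through a region-specific low-dimensional
*representational space*, and asks how well one region's trajectory
linearly predicts another's in runs that were held out of all model fitting.

## The model

Let $Y_i$ ($T_i \times n_Y$) and $X_i$ ($T_i \times n_X$) be the seed and
predictor timecourse matrices for run $i = 1, \dots, m$ (timepoints as
rows). Analysis is leave-one-run-out; for each fold the remaining runs are
concatenated into training data, and everything below is estimated on
training data only.

1. **Representational spaces.** PCA (SVD of the column-centered training
   matrix) yields loadings $V_Y$, $V_X$ and singular values $S_Y$, $S_X$.
   Data are projected onto the first $k_Y$ and $k_X$ components:
   $\tilde{Y} = (Y - \bar{y}) V_Y[, 1..k_Y]$, likewise for $X$.
2. **Dependence model.** Ordinary least squares fits
   $\tilde{Y}_{train} = \tilde{X}_{train} B + E$. With time as rows, $B$ is
   $k_X \times k_Y$. The solver is SVD-based minimum-norm least squares, so
   rank-deficient designs (possible in tiny spheres) are handled without
   special-casing.
3. **Prediction and scoring.** The left-out run is projected with the
   *training* means and loadings, predicted as
   $\hat{Y} = \tilde{X}_{test} B$, and scored per seed dimension $j$ by
   $r_j = \mathrm{corr}(\hat{Y}_j, \tilde{Y}_{test,j})$. The summary is the
   weighted mean $\bar{r}_i = \sum_j w_j r_j$ with
   $w_j = S_Y(j,j) / \sum_l S_Y(l,l)$, and $\bar{r}$ is the unweighted mean
   of $\bar{r}_i$ over folds.
4. **Voxelwise cross-validated $R^2$.** To compare MVPD with mean-based
   connectivity on a *common* target, predictions are carried back to voxel
   space, $\breve{Y} = \hat{Y} V_Y[, 1..k_Y]^\top + \bar{y}$, and each seed
   voxel is scored by $v(j) = 1 - SS(Y_j - \breve{Y}_j) / SS(Y_j)$ with raw
   sums of squares; $\bar{v}$ averages over voxels and folds. The
   leave-one-out univariate baseline predicts every voxel with the
   predicted spatial mean — the mean treated as a single dimension with
   equal loadings — so its $\bar{v}$ is directly comparable.

### Choices worth flagging

- **Weights use singular values, not their squares.** The defining formula
  weights by $S(j,j)$ while describing the weights as proportions of
  variance; variance proportions would use $S^2$. The package reproduces
  the formula as printed by default and exposes `weights = "variance"` for
  squared-singular-value weighting. At typical fMRI spectra the two
  orderings agree; only the contrast between dimensions changes.
- **Centering.** The SVD is taken of the column-centered training matrix,
  with the training mean also subtracted from test data and re-added after
  back-projection. Raw-SVD equations without a mean term are recovered with
  `center = FALSE`; centering is the default because the
  variance-explained reading of the spectrum requires it.
- **Orientation of the regression.** A printed form $\tilde{Y} = B
  \tilde{X}$ is dimensionally inconsistent with time-as-rows matrices; the
  only shape-consistent reading, $\tilde{Y} = \tilde{X} B$, is implemented.
- **Degenerate series.** A constant predicted or observed dimension has an
  undefined correlation; it is scored $r_j = 0$ with a warning, which keeps
  $\bar{r}$ defined and is conservative. Zero-variance voxels get
  $v(j) = 0$ with a warning. A region-mean timecourse whose variance is
  numerically zero *relative to the region's data* (exactly what remains
  after univariate-signal removal) is treated as constant, so mean-based
  connectivity on mean-removed data is exactly 0 by construction rather
  than noise-valued.

## Dimensionality selection

Two modes mirror the two analyses the method is used for:

- **BIC mode.** For each fold and region, $k$ minimizes the BIC of a
  probabilistic-PCA model: $k$ signal variances plus an isotropic residual,
  profile log-likelihood
  $-\tfrac{T}{2}[n \ln 2\pi + \sum_{j \le k} \ln \lambda_j + (n-k) \ln
  \sigma^2_k + n]$ with $\sigma^2_k$ the mean of the trailing eigenvalues,
  penalized by $p(k) = nk - k(k-1)/2 + k + 1$ parameters times $\ln T$.
  The search stops at $\min(k_{max}, n-1)$ so the residual variance stays
  estimable; ties in machine precision are broken toward smaller $k$. At
  high SNR with three planted dimensions this recovers $k = 3$ in ≥ 90 % of
  simulations (the suite checks 100 of them against an independently coded
  exhaustive-BIC oracle).
- **Fixed-$k$ mode** ($k \in \{1, 2, 3\}$) for the incremental-contribution
  analysis, and mandatorily for per-dimension searchlight maps: BIC would
  change $k$ from sphere to sphere, destroying the identity of "dimension
  $j$" across the brain. $k$ is a property of the seed and is held fixed.

Whether the two regions' $k$ are selected jointly is not fixed by the
method's definition; they are selected independently here.

## Preprocessing

All de-noising operates per run on timepoints × voxels matrices and never
crosses run boundaries (concatenation-edge artifacts would otherwise leak
across folds):

- High-pass: projection onto the complement of a discrete-cosine drift
  basis with periods ≥ 128 s (constant included) — the GLM-software
  convention, exactly idempotent, output exactly orthogonal to the basis.
- Low-pass (applied to region means only, for standard FC): zero-phase
  4th-order Butterworth at 0.1 Hz via forward–backward filtering. Only the
  cutoff is part of the method's definition; Butterworth forward–backward
  is the common functional-connectivity choice.
- CompCor: the first 5 principal-component timecourses of the centered
  white-matter + CSF control region, regressed out of gray matter along
  with optional global-signal and motion regressors. Regressor assembly
  order is explicit in the configuration because the method's definition
  does not fix it.
- Censoring: outlier flags are an *input* (0/1 vectors); outlier detection
  thresholds are experimenter-defined upstream and are not reimplemented.
- Univariate-signal removal subtracts the spatial mean at each timepoint,
  making every subsequent mean-based measure identically zero — the fully
  complementary regime in which only patterns can carry dependence.
- AR(1) prewhitening belongs to the upstream GLM pipeline and is out of
  scope here.

## Searchlight and group inference

Spheres of radius 6 mm (123 voxels on a 2 mm isotropic grid) are swept over
a gray-matter mask, each sphere serving as predictor for the fixed seed;
sphere computations are independent and order-invariant, and truncated
spheres at mask edges simply use the surviving voxels. Spheres overlapping
the seed are computed as-is by default (an `exclude_seed` flag exists
because self-prediction inflates dependence near the seed). The
gray-matter mask is built by Gaussian-smoothing tissue-probability maps
(FWHM → σ by $\sigma = \mathrm{FWHM} / 2\sqrt{2 \ln 2}$, truncated at 4σ),
averaging, and thresholding; the threshold is a required argument because
the mask's voxel count depends on it steeply and no canonical value exists.

Group inference is a one-sample sign-flip permutation test with
max-statistic family-wise error control: under the null each subject's map
is sign-symmetric, so all $2^N$ (or a seeded Monte-Carlo subset of) sign
assignments are rescored by the voxelwise one-sample $t$, and each voxel's
FWE-corrected p is the fraction of permutations whose *maximum* statistic
reaches its observed $t$. The identity assignment is always in the null, so
$p \ge 1/n_{perm}$. The test is one-sided (dependence > 0) by default,
matching connectivity-map conventions; variance smoothing (pseudo-$t$) is
deliberately omitted to keep the statistic assumption-light.

## The synthetic generator

Real scan data for this method are not redistributable, so validation is
synthetic with known ground truth. The generator emulates the study design
scale: 3 runs × 360 volumes at TR 2 s (5 runs in the shorter-run variant),
two regions of 80 voxels with 3 latent dimensions each. Predictor latents
are white noise convolved with a double-gamma haemodynamic kernel (giving
BOLD-plausible autocorrelation, which exercises the filters and the
effective-dof behavior of correlations realistically); seed latents are
$L_X B_{true}$ plus optional innovation noise; voxel data are latents times
random orthonormal loadings (scaled so per-voxel signal SD ≈ 1), plus an
optional shared spatial-mean timecourse common to both regions, plus iid
Gaussian noise (SD 1). `pattern_only = TRUE` projects the loadings to zero
column sums, producing dependence that is exactly invisible to mean-based
connectivity.

What it does *not* emulate: physiological (cardiac/respiratory) noise,
motion, spatial noise correlations, nonlinear coupling. Passing tests
therefore demonstrate correctness of the estimator under its own model
assumptions and the claimed contrasts between methods — not robustness to
every property of real scanner data.

Because PCA bases are identified only up to rotation, $B_{true}$ recovery
is always asserted on predictions (rotation-invariant), never on raw
coefficients.

## Problem sizes and numerical choices

The test and acceptance suites use deliberately small problems chosen to
keep the full suite under a minute of compute while leaving each effect
unambiguous: 3 runs × 100 volumes and 50-voxel regions for recovery checks;
the generator's full default scale (3 × 360) for the complementarity
contrast, because the width of the standard-FC null is governed by the
effective number of filtered timepoints and the |r| ≤ 0.1 bound is a
property of the full-length design; 500 simulated null datasets of 8
subjects × 40 voxels (exhaustive 256 sign flips) for the FWE calibration
check; and a 10 × 8 × 4 volume with a planted 27-voxel coupled block for
end-to-end searchlight localization, with the seed's own block excluded
from the analysis mask so no sphere self-predicts.

Other numerical conventions: loading-column signs are fixed by making each
column's largest-magnitude element positive (deterministic across LAPACK
implementations); mask voxels are ordered ascending-lexicographically by
(x, y, z); ties in top-N voxel selection are broken by that canonical
order; written statistic maps use NaN as background so "not computed" is
distinct from a true 0; sphere membership uses center-to-center distances
in world mm through the grid affine, so anisotropic voxels are supported.

## Known limitations

Only linear, simultaneous (non-lagged) dependence is modeled; ICA or
nonlinear embeddings, directed/lagged models, cluster-extent inference,
covariate designs and surface-based data are out of scope. Fold averaging
of $\bar{r}$ is unweighted, appropriate for equal-length runs; strongly
unequal runs would argue for length-weighting. The BIC parameter count
follows the package's stated convention; other pPCA parameter counts exist
and shift the penalty slightly without changing high-SNR behavior.

## A worked miniature

```{r example, eval = FALSE}
# pattern-only coupling: invisible to mean-based FC, visible to MVPD
ds <- generate_synthetic_dataset(synthetic_spec(pattern_only = TRUE,
                                                rng_seed = 1))
standard_fc(ds$seed, ds$predictor)$r          # ~ 0
crossvalidated_mvpd(ds$seed, ds$predictor,
                    mvpd_config(component_mode = "fixed", k_fixed = 3))
```
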