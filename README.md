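# mapdyn

Linking regional neurophysiological dynamics to cortical
micro-architecture: time-series phenotyping, spectral parameterization
with intrinsic timescales, PCA gradients, and partial least squares
brain-map association with spatial-autocorrelation-preserving inference
— validated end to end on synthetic data with planted structure.

## Who this is for

Researchers analyzing parcellated electrophysiological recordings
(MEG/EEG source time series) against regional brain maps (myelin, gene
expression, receptor density, metabolism, ...), and anyone who needs
tested, reusable R implementations of the statistical machinery this
literature relies on: spin permutation nulls, PLS-SVD with bootstrap
loading reliability, distance-dependent cross-validation, knee-mode
aperiodic spectral fits, and an atlas-expression workflow (probe
filtering, differential stability, robust-sigmoid normalization,
sample-to-region aggregation).

## The models at the core

**Spectral parameterization.** Welch PSDs (4 s Hann windows, 50%
overlap) are decomposed in log10-power space over 1-60 Hz into an
aperiodic component with a knee plus Gaussian oscillatory peaks:

    log10 P(f) = offset − log10(k + f^χ) + Σ A·exp(−(f−c)²/2w²)

The knee parameter yields the knee frequency and intrinsic timescale

    f_k = k^(1/χ),   τ = 1/(2π f_k)

(e.g. k = 2500, χ = 2 ⇒ f_k = 50 Hz, τ = 1/(100π) s).

**PLS brain-map association.** With region × feature matrix **X** and
region × map matrix **Y**, both z-scored column-wise:

    R = X′Y/(n−1) = U S V′

Effect sizes η_i = s_i²/Σ s_j²; brain scores XU and YV; loadings are
correlations between original columns and their side's scores.
Latent-variable significance uses spin permutations (uniform random
rotations applied to one hemisphere and mirrored to the other, values
reassigned to the closest rotated parcel), with add-one p-values;
loading reliability uses bootstrap CIs with Procrustes alignment;
out-of-sample generalization uses distance-dependent train/test splits
(75% nearest / 25% most distant regions from a random seed region).

**Feature catalogue.** 56 named features per region across seven
families (distribution, autocorrelation, fluctuation/DFA, spectral,
AR model fit, multiscale variance, sample entropy), each with a
brute-force reference implementation in the tests, plus outlier-robust
sigmoid normalization and a segment-length stability check.

## Worked example

Generate a 100-region synthetic dataset with one planted latent axis
linking dynamics to a 10-map "micro-architecture" set, then run the
full pipeline:

```r
library(mapdyn)

geom  <- generate_parcellation(100, seed = 1)
truth <- planted_truth(geom, n_maps = 10, seed = 1)
maps  <- generate_maps(geom, truth, noise_sd = 0.5, seed = 1)
ts    <- generate_timeseries(geom, truth, duration_s = 110, fs = 509, seed = 1)

fit <- fit_spectral_model(welch_psd(ts))
print(fit)
#> Spectral fit (knee mode, 1-60 Hz): 100/100 regions converged
#>   median chi 2.04, median knee freq 15.49 Hz, median tau 0.01028 s, median R2 0.998

fm  <- sigmoid_normalize(compute_feature_matrix(ts, feature_catalogue(),
                                                analysis_config()))
pca <- run_pca(fm)
print(pca)
#> PCA gradients: 100 regions x 56 features
#>   variance explained: PC1 71.6%, PC2 18.8%, PC3 2.0%, PC4 1.6%, PC5 1.3% ...

spins <- generate_spins(geom, 1000, seed = 1)
pls   <- fit_pls(fm, maps)
print(pls)
#> PLS mapping: 100 regions, 56 features x 10 maps
#>   LV1: singular value 16.057, effect size 99.4%, score r_s 0.98
#>   LV2: singular value 1.158, effect size 0.5%, score r_s 0.61
#>   LV3: singular value 0.239, effect size 0.0%, score r_s 0.36

pls_significance(fm, maps, spins, fit = pls)$p_spin[1]
#> [1] 0.000999001

cv <- distance_cv(fm, maps, geom, n_splits = 99, seed = 1)
median(cv$test_rs)
#> [1] 0.9335385

cor(pls$scores_Y[, 1], truth$gradient, method = "spearman")
#> [1] 0.98
```

Reading the output: the fitted aperiodic exponents and timescales track
the planted per-region values (median R² 0.998 in log space); the
feature matrix is dominated by one gradient (PC1 71.6%); PLS finds a
single dominant latent variable whose map scores recover the planted
spatial axis (r_s = 0.98), survive the spatial permutation test
(p_spin = 0.001 at 1000 spins) and generalize to held-out distant
regions (median test r_s = 0.93).

The expression stage runs analogously from
`generate_expression_bundle()` through `filter_probes_intensity()`,
`assign_samples()`, `differential_stability()`,
`build_expression_matrix()` and `cell_type_maps()`.

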