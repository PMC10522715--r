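---
title: "Mapping neurophysiological dynamics to cortical micro-architecture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping neurophysiological dynamics to cortical micro-architecture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Regional neurophysiological recordings (MEG/EEG source time series
parcellated to ~100 cortical regions) carry a rich dynamical signature:
band-limited oscillatory power, the shape and decay of the
autocorrelation function, fractal scaling, entropy, and the aperiodic
1/f-like background of the power spectrum. Cortical micro-architecture
(myelination, gene expression, receptor densities, metabolism, laminar
structure) varies smoothly along large-scale gradients. `mapdyn`
implements, as reusable and tested components, the statistical pipeline
that links the two: time-series phenotyping of regional signals,
spectral parameterization with intrinsic timescales, principal-component
gradients of the feature matrix, partial least squares (PLS) association
with a set of micro-architectural maps, spatial-autocorrelation
preserving permutation inference, bootstrap loading reliability,
distance-dependent cross-validation, and a toy-scale multi-donor
microarray expression-map stage.

All validation runs on synthetic data with *planted* structure: the
generators draw regional signals and map sets that share one latent
spatial axis, so every stage can be checked against a known ground
truth.

# Models and procedures

## Spectral parameterization and the intrinsic timescale

The one-sided power spectral density is estimated by Welch's method
(Hann-tapered 4 s windows, 50% overlap; density scaling such that the
integral over $[0, f_s/2]$ approximates the signal variance). In
log10-power space over 1-60 Hz the spectrum is decomposed into an
aperiodic component with a knee,

$$\log_{10} P(f) = \mathrm{offset} - \log_{10}\!\left(k + f^{\chi}\right),$$

plus up to 6 Gaussian oscillatory peaks with widths constrained to 1-6
Hz, a minimum height of 0.1 (log10-power) and a detection threshold of 2
residual standard deviations. The fitting procedure is: robust aperiodic
fit (a second pass excludes the most peak-contaminated quartile of
bins); iterative residual peak extraction (largest residual first, ties
to the lower frequency); aperiodic refit on the peak-removed spectrum;
joint bounded least-squares polish (Levenberg-Marquardt via minpack.lm).
Goodness of fit is the squared Pearson correlation between model and
data in log space. The knee parameter $k$ and exponent $\chi$ give the
knee frequency and intrinsic timescale

$$f_k = k^{1/\chi}, \qquad \tau = \frac{1}{2\pi f_k},$$

so, e.g., $k = 2500$, $\chi = 2$ imply $f_k = 50$ Hz and
$\tau = 1/(100\pi) \approx 3.18$ ms. Initialization uses the log-power
at the lowest fitted frequency, the endpoint slope for $\chi$, and a
knee placed at 10 Hz, with two fallback starts; non-converged regions
are flagged, never silently dropped. Gamma-range activity is summarized
by total Welch band power only — peak fitting above ~40 Hz is
unreliable, so the oscillation-score procedure covers delta (2-4),
theta (5-7), alpha (8-14) and beta (15-30 Hz) only. The oscillation
score multiplies the across-subject mean in-band peak amplitude
(normalized to the regional maximum) by the fraction of subjects with at
least one in-band peak.

## The feature catalogue

The phenotyping stage computes a fixed, documented catalogue of 56 named
features per region, spanning seven families: amplitude distribution
(moments, quantile spread), autocorrelation (biased-estimator ACF at
lags 2-40, first zero-crossing time, lag-1 autocorrelation of
rolling-window detrended residuals), fluctuation (DFA exponents of
orders 1 and 2 with fit $R^2$), spectral (six canonical band powers and
relative powers, spectral entropy, spectral centroid), model fit
(Yule-Walker AR(1)/AR(2) coefficients and innovation-variance ratio),
multiscale (block-mean variance ratios at scales 2-64), and entropy
(sample entropy, $m = 2$, $r = 0.2\,\mathrm{SD}$). This is deliberately
*not* a reimplementation of the massive (~7000-feature) phenotyping
libraries: the inference machinery downstream is the core of the
package, and the catalogue is pluggable. Every feature has a brute-force
reference implementation in the test suite.

Conventions worth noting:

* ACF uses the biased (divide-by-$n$) estimator for
  positive-semidefiniteness and stability at long lags; the AR features
  are solved in closed form from the same estimator.
* DFA uses 12 log-spaced scales from 16 samples to $n/4$ with order-1
  (and order-2) polynomial detrending of the integrated profile.
  Degenerate inputs are those whose profile the detrending annihilates:
  a constant series at any order, a linear ramp at order 2.
* Sample entropy is computed on the first 5000 samples of the segment;
  the $O(n^2)$ template count (compiled code) is otherwise the only
  stage whose cost would dominate the pipeline.
* Features are extracted from an 80 s segment after dropping the first
  30 s; a stability check (`segment_stability()`) correlates feature
  vectors across growing segment lengths and stabilizes around 30 s on
  stationary synthetic signals.
* A feature column is invalidated if it errors, is non-finite for any
  region, or is constant across regions — the whole column is dropped,
  matching the "remove erroring operations" policy.
* Normalization is the outlier-robust sigmoid
  $\tilde x = 1/(1 + \exp(-(x - \langle x\rangle)/(\mathrm{IQR}/1.35)))$
  (median center; the 1.35 factor makes the IQR approximate the SD under
  normality — the convention of the robust-sigmoid literature, which the
  source descriptions leave unspecified), followed by min-max rescaling
  to $[0, 1]$. Zero-IQR slices are flagged invalid. The transform is
  monotone, so ranks are preserved; it is not idempotent and is applied
  exactly once.

## Gradients and PLS

PCA is run on the column-centered normalized features (no second
standardization: the sigmoid already bounds scales; this choice is
explicit and auditable). Component signs are pegged so that each score
map correlates positively with its top-|weight| feature. Feature
loadings are Pearson correlations between each feature and the
component score map, with two-tailed spin p-values and FDR (BH) across
features.

PLS z-scores both matrices column-wise and decomposes the
cross-correlation matrix

$$\mathbf{R} = \mathbf{X}'\mathbf{Y}/(n-1) = \mathbf{U}\mathbf{S}\mathbf{V}',$$

so the entries of $\mathbf R$ are Pearson correlations (the $n-1$
normalization cancels everywhere downstream). Effect sizes are
$\eta_i = s_i^2 / \sum_j s_j^2$; brain scores are $\mathbf{XU}$ and
$\mathbf{YV}$; loadings are correlations between original columns and
their side's scores. Latent-variable significance permutes the rows of
$\mathbf Y$ (the spatially smooth map side; the choice of side is
documented and switchable by passing the sides swapped) by spin
assignments and compares singular values one-sidedly — singular values
are non-negative, so a two-sided test on them has no meaning. All
permutation p-values use the add-one convention
$p = (1 + \#\{s^{\mathrm{null}} \ge s\})/(n_{\mathrm{spin}} + 1)$ and
are never exactly zero.

Bootstrap reliability resamples regions with replacement (z-scoring
recomputed per resample), aligns each resampled solution to the original
by orthogonal Procrustes on $\mathbf V$ (absorbing sign flips and axis
rotations that would otherwise corrupt percentile pooling), and reports
95% percentile CIs per loading; a loading is reliable when its CI
excludes zero. Distance-dependent cross-validation draws seed regions
without replacement, trains on the 75% of regions nearest in chord
(3-D Euclidean) distance, z-scores the held-out quarter with training
statistics, projects it on the training singular vectors, and reports
Spearman correlations between LV1 feature and map scores for both
halves.

## Spatial nulls

Spin permutations draw uniform random rotations (normalized quaternion
sampling), rotate the left-hemisphere parcel coordinates, mirror the
same rotation across the sagittal plane for the right hemisphere, and
reassign each region the value of the nearest rotated same-hemisphere
region by great-circle distance. Nearest-parcel reassignment duplicates
sources — it is deliberately not a bijection, matching the
closest-parcel description of the procedure. Two consequences are worth
knowing: (1) source regions are not selected uniformly — rim parcels
absorb the targets that the rotated hemisphere cap leaves uncovered
(observed max/mean selection frequency ~4 at $R = 100$) — and (2) for
extremely smooth single-axis data the test is mildly anti-conservative
(~0.07-0.09 at nominal 0.05 in our simulations), consistent with what
is reported for parcel-level spins generally. Rejection rates on
independent smooth map pairs, and for PLS LV1 on independent smooth map
sets, are calibrated to [0.02, 0.10] in the test suite.

## Expression pipeline

The toy multi-donor microarray stage mirrors the standard
atlas-expression workflow: probes below background intensity in >= 50%
of samples (pooled across donors; the boundary case is discarded) are
removed; among a gene's surviving probes the one with the highest
differential stability
$\Delta_S(p) = \binom{N}{2}^{-1}\sum_{i<j}\rho[B_i(p), B_j(p)]$
(mean pairwise inter-donor Spearman correlation of regional profiles,
computed over regions shared by each donor pair) is kept, ties to the
first probe id. Samples are mirrored bilaterally (negated x, swapped
hemisphere), assigned to the nearest region center within an inclusive
radius (ties to the lower region index), and unassigned samples are
discarded. Per donor, each sample is sigmoid-normalized across genes,
then each gene across the donor's samples; samples in the same region
are averaged per donor and then across donors. Regions left uncovered
are filled per donor by inverse-distance weighting of the donor's three
nearest assigned samples and flagged as interpolated — a region-center
simplification of the voxel-level dense interpolation used with real
volumetric atlases. Cell-class maps are unweighted means over gene-set
columns.

# The synthetic-data generators

The generators define the study conditions; their defaults are fixed
once and are not tuned per experiment.

* **Parcellation**: $R/2$ quasi-uniform points on the hemisphere
  $x > 0$ (golden-angle lattice with a small seeded jitter), mirrored
  through $x \to -x$. Default $R = 100$.
* **Planted axis**: a kernel-smoothed Gaussian random field (kernel
  width 30°), z-scored. A smooth field of intermediate spatial scale is
  the right stand-in for an empirical cortical gradient; the simpler
  choice of a coordinate-axis projection is degenerate under rotation
  nulls (any rotation of a dipole is another dipole), which would make
  the planted association indistinguishable from chance by
  construction.
* **Maps**: `loading × gradient` plus kernel-smoothed noise
  (`exp(-θ²/2σ²)` over great-circle angles, default σ = 20°), scaled to
  `noise_sd` and z-scored per column. The planted study condition for
  end-to-end checks is `noise_sd = 0.5`, 10 maps × 40 feature-maps at
  $R = 100$.
* **Signals**: random-phase inverse-Fourier synthesis from the closed
  form PSD $10^{\mathrm{offset}}/(k + f^{\chi}) + \sum_i A_i
  \exp(-(f - c_i)^2/2w_i^2)$, so the generating spectrum is known
  exactly (an autoregressive simulator would only approximate arbitrary
  exponents). Dynamics parameters vary along the gradient: $\chi = 2 +
  0.35g$ (clipped to [0.5, 4]), $\log_{10} f_k = \log_{10} 15 + 0.15g$,
  offset $1 + 0.1g$, an alpha peak at $10 + 0.5g$ Hz whose amplitude
  grows with $g$, and a fixed beta peak. Defaults: 110 s at 509 Hz
  (30 s dropped, 80 s used downstream).
* **Forward model**: sensors on a 1.2-radius sphere, inverse-square
  gain falloff, seeded source depths, heterogeneous positive sensor
  noise; SNR $= 10\log_{10}\!\big(\frac{a^2}{N}\sum_k b_k^2 /
  s_k^2\big)$ with the default source amplitude $a = 10$ nAm.
* **Expression bundle**: per donor, samples at jittered region
  coordinates with the left hemisphere over-represented (to exercise
  mirroring); one good probe per gene tracking a smooth profile shared
  across donors plus donor noise, optional noisier probes, and
  per-probe-and-sample above-background flags. Gene profiles are made
  bilaterally symmetric — mirroring samples across hemispheres is only
  valid under approximate bilateral symmetry, so the generator encodes
  exactly that assumption.

Every generator draws from an offspring stream of the master seed
(a deterministic hash of the stage name), so regenerating one stage
never perturbs another, and the caller's RNG state is restored.

What the generators do *not* emulate: volume conduction and
cross-region leakage, non-stationarity and artifacts, realistic sensor
physics, cortical folding, probe cross-hybridization, and the full
scale of empirical feature libraries or map atlases. Passing tests
demonstrate that the statistical machinery recovers known planted
structure under these idealized conditions — not that any particular
empirical dataset would yield the same numbers.

# Numerical choices and degenerate inputs

* Permutation p-values: add-one formula, never exactly 0.
* Peak detection order: descending residual magnitude, ties broken
  toward the lower frequency, for deterministic output.
* SVD sign convention: the largest-|element| entry of each right
  singular vector is made positive; PCA components are pegged to their
  top-weight feature. Determinism of every stage given (data, config,
  seed) is asserted in tests.
* Constant columns: an error in PLS z-scoring (named in the message);
  excluded-and-flagged in loadings; degenerate bootstrap resamples are
  redrawn and counted; degenerate CV splits are flagged and excluded.
* Chord (3-D Euclidean) distance is used for CV splits; great-circle
  distance for spin reassignment. The two orderings agree on a sphere.
* Round-trip I/O: tab-delimited UTF-8, 15 significant digits, `NaN`
  literals preserved; round-trips agree to <= 1e-10.

# Known limitations

* The region-resampling bootstrap assumes exchangeable rows. For a
  spatially *smooth* null map the realized chance correlation with LV1
  is nonzero and the CI honestly brackets it away from zero; the spin
  test, not the bootstrap, is the guard against smooth-chance
  alignment. The bootstrap reliability check therefore uses a spatially
  unstructured noise map as its negative control.
* Parcel-level spins are mildly anti-conservative for single-dominant-
  axis, very smooth data, and the nearest-parcel reassignment is not
  source-uniform (rim pile-up). Both effects are inherent to the stated
  procedure and are characterized, not hidden, by the tests.
* The feature catalogue is representative, not exhaustive; results
  about "dominant axes of dynamics" depend on the feature census in any
  such analysis.

# Problem sizes used by the tests and the acceptance script

Chosen to exercise the study-scale conditions while keeping a complete
run lightweight: spectral recovery on 50 regions of 110 s at 509 Hz;
spin calibration on 200 smooth map pairs at 1000 spins; PLS type-I on
100 independent null datasets (5 × 3 maps) at 500 spins; end-to-end
planted recovery over 20 seeds (40 × 10 maps, `noise_sd` 0.5, 1000
spins, 99 CV splits); DFA on 100 white and 100 pink series of 60,000
samples; differential stability on 5-donor toys against a brute-force
oracle; bootstrap reliability over 20 seeds at 500 resamples.
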