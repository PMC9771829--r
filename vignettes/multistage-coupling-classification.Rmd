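---
title: "Multistage classification of frequency-resolved brain coupling"
author: "fcbag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage classification of frequency-resolved brain coupling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcbag)
```

## The problem

Whole-brain electrophysiological connectivity is enormous: with 457 cortical
sources there are 104,196 unique connections, measured at 23 carrier
frequencies for two distinct coupling modes (amplitude-envelope coupling and
phase coupling). Group differences in such a space defeat mass-univariate
testing — after multiple-comparison correction over 10^5 connections per
frequency, realistic effects at n = 17 + 17 subjects are invisible — and they
also defeat naive multivariate classification, because almost all dimensions
are uninformative. `fcbag` implements a multistage alternative:

1. **Spectral estimation.** Morlet wavelets on a quarter-octave grid
   (2.8–128 Hz), bandwidth 0.5 octaves (one spectral SD), coefficients
   sampled every half temporal SD.
2. **Coupling.** Two volume-conduction-insensitive metrics per source pair
   and frequency: the orthogonalized amplitude-envelope correlation and the
   weighted phase-lag index. The upper triangle of each coupling matrix,
   vectorized and z-scored within subject, is a *coupling profile*.
3. **Reduction.** PCA of the coupling profiles of an *independent reference
   cohort* (95 subjects). The top 30 components per mode and frequency span
   the feature space; study subjects are only ever projected into it, so
   between-group variance cannot leak into the basis, and a basis fit once is
   reusable.
4. **Selection.** Feature bagging: many small random feature subsets are
   drawn, each classified with cross-validated linear classification, and
   each feature is scored by the probability of appearing in the top quartile
   of subsets. Scores are tested against a pooled permutation null with FDR
   correction, plus a global count test.
5. **Confidence and accuracy.** Per-subject classification confidence as a
   difference of leave-one-out squared Mahalanobis distances; unbiased
   generalization accuracy by nested leave-one-out cross-validation of the
   entire pipeline with Gaussian fits to the signed boundary distances.

## The core statistic

For a bag $b$ of $n_{sub} = 10$ features, leave-one-out accuracy $a_b$ is
recorded. With threshold $\theta$ at the 75th percentile of
$\{a_b\}_{b=1}^{n_{draw}}$, the classification score of feature $f$ is

$$s_f = \frac{\#\{b : f \in b,\ a_b \ge \theta\}}{\#\{b : a_b \ge \theta\}}.$$

If no feature is informative every $s_f \approx n_{sub}/n_{features}$;
informative features rise above this floor. The identity
$\sum_f s_f = n_{sub}$ holds exactly and is asserted in code. Significance
comes from a pooled null: the whole procedure (fresh bags included) is
repeated under group-label permutations, and all permuted scores across
features form one component-independent null distribution; p-values use the
add-one estimator and are Benjamini–Hochberg corrected across features. The
number of significant features is itself tested against its permutation
distribution.

## Design choices worth knowing

**Classifier.** The default per-bag classifier is an L2-regularized
least-squares linear discriminant on ±1 labels (`lambda = 1`), for which
leave-one-out predictions have the exact closed form
$\hat y_{-i} = (\hat y_i - h_i y_i)/(1 - h_i)$ — one factorization per bag
instead of $n$ refits. With tens of millions of cross-validated fits per
analysis this is what makes permutation calibration routine; ridge-on-labels
is also the classical computational surrogate for a soft-margin linear SVM at
this sample size, and the procedure is demonstrably robust to the classifier
family (a squared-hinge max-margin solver, a nearest-centroid classifier and
a decision-stump voter are built in as `classifier = "svm"`, `"centroid"`,
`"stump"`). Features are standardized once, globally and label-free, rather
than within training folds: the standardization uses no group information, so
it cannot leak labels, and it keeps the closed-form leave-one-out exact.

**Tie handling.** With leave-one-out over 34 subjects, accuracies are
multiples of 1/34, so ties at the threshold are common; selection is
inclusive (accuracy ≥ the percentile value) and the selected fraction is
reported.

**Permutations.** Each permutation redraws its feature bags ("fresh draws"),
so bag-sampling noise is identical in observed and null scores. P-values use
the add-one (never-zero) convention. Each permutation's significant count is
evaluated against the same pooled null that includes it.

**Projection centering.** Component scores subtract the reference-cohort
mean profile before projection (standard PCA projection) by default;
`center = FALSE` gives the plain eigenvector product. The two differ by a
constant per component, so group contrasts, bagging accuracies and scores are
unchanged; centering only matters for absolute Mahalanobis positions.

**Z-scoring.** Profiles are z-scored within subject with the population-SD
convention (denominator $n$); the sample convention is available
(`sd_type = "sample"`).

**Sign asymmetry (univariate stage).** Connections are massively dependent,
so the binomial test of the sign distribution of significant connections is
evaluated at df = 40 effective trials — the typical rank of an MEG forward
model, i.e. the number of independently separable sources — by rescaling the
observed proportion to `round(prop * df)` successes out of `df`. Two-tailed
p-values use the exact minimum-likelihood convention.

**Mahalanobis confidence.** The printed squared form
$D = (f-\mu_g) C_g^{-1} (f-\mu_g)'$ is used without a square root; subject
$i$ is always excluded from its own group's mean and covariance. The feature
subset defaults to the significant components: a 17-subject group covariance
over all 1380 components is singular, whereas over a handful of selected
components it is usually well conditioned. When it is not, diagonal loading
toward the average variance is applied (initial weight 0.1, raised stepwise
with a warning).

**Nested LOO.** Leaving out one subject, feature selection (bagging +
permutation FDR) is redone from scratch on the remainder; folds that select
nothing fall back to the `bag_size` top-scoring features. The held-out
distance is divided by the SD of the in-sample distances (both groups
pooled), signed positive when classified as patient. Reduced per-fold scales
(`nested_n_draw`, `nested_n_perm`) keep the 34-fold refit tractable; the
estimator's calibration is checked on null cohorts, where its mean over
seeds sits near 0.5 (single-seed estimates at n = 34 scatter by ~0.08, so
calibration statements average over seeds).

## The synthetic cohort generator

No public recording accompanies the method, so the generator is a
first-class module that emulates the study conditions: 17 patients, 17
controls, a 95-subject reference cohort.

*Time-series path.* Per carrier frequency, sources are amplitude-modulated
sinusoids. Log-envelopes are correlated Ornstein–Uhlenbeck processes
(Gaussian copula, time constant 5 cycles, log-SD 0.5), which imposes the
envelope-correlation matrix; infeasible (non-PSD) matrices are rejected with
a diagnostic. Phase jitter is a slow OU process (2 cycles, SD 0.7 rad);
phase-coupled pairs share correlated jitter (0.8 by default) plus a static
lag, defaulting to π/4 because the wPLI is blind to zero-lag coupling; the
per-source offsets realizing the pairwise lags are fit by least squares.
`apply_mixing()` applies instantaneous linear mixing as a volume-conduction
surrogate. The desk-scale default is 30 sources, 6 octave-spaced carriers
(2^1.5 to 2^6.5 Hz, one per canonical band) and 60 s at 250 Hz — scaled down
from 457 sources x 23 frequencies so the full pipeline runs in minutes.

*Profile path.* For testing everything downstream of coupling estimation,
profiles are drawn directly: mean profile + low-rank subject variation along
8 orthonormal generative loading patterns + isotropic noise (SD 0.5).
Generative component-score SDs decay geometrically (8 x 0.82^j): adjacent
eigenvalue gaps (~33%) stay above their sampling fluctuation at
n_reference = 95, so the reference PCA identifies the generative basis and a
planted effect lands on the intended estimated component instead of being
diluted across neighbors. Planted effects shift the patient mean by
`effect_size` reference-SD units along chosen components; patient severity
scores are a noisy monotone function (SNR 1) of each patient's realized
shift, with one missing EDSS-like and four missing MSFC-like values
mirroring incomplete clinical scoring.

What the generator does *not* emulate: 1/f background spectra, realistic head
geometry or source leakage patterns, non-stationarity, artifacts. Passing
tests therefore demonstrate correctness and calibration of the statistics
under the generative model, not performance on real recordings.

## Numerical choices

- Wavelet kernels are truncated at 6 temporal SDs (truncation sidelobes stay
  below the Gaussian transfer function out to one octave); only time steps
  with full kernel support are emitted, so edges never bias envelopes.
- The wavelet bandwidth parameter `b` (octaves) is symmetric in log
  frequency: $\sigma_f = f(2^{b/2} - 2^{-b/2})/2$, i.e. $\sigma_f
  \approx 0.174 f$ at $b = 0.5$.
- Degenerate coupling pairs (zero-variance orthogonalized envelope; an
  imaginary cross-spectrum at rounding level of its magnitude) return 0 with
  a warning rather than NA, so downstream linear algebra never sees gaps.
- Mann-Whitney tests use exact p-values for group sizes up to 8 without
  ties, otherwise the tie-corrected, continuity-corrected normal
  approximation.
- The 98th-percentile normalization of component loadings uses the
  linear-interpolation percentile (R type 7).
- All randomness flows from explicit seeds; nested fold $f$ runs under
  `seed + f`, and pipeline stages derive their seeds from the master seed by
  fixed offsets, so stage toggles never shift another stage's stream.

## Desk-scale problem sizes

The packaged calibration studies use 30 sources (435 connections), 6
frequencies, 2 x 10^4 bags, 200 permutations and 20 cohort seeds for
calibration rates; nested cross-validation uses 2,000 bags and 50
permutations per fold, and the bag-size/threshold robustness analysis uses
2 x 10^5 draws per setting so that finite-bag score noise does not mask the
rank agreement. At these scales a full selection (observed + 200
permutations) takes ~20 s and a 34-fold nested accuracy estimate ~20 s on one
core. The full-scale settings (2 x 10^7 bags, 1000 permutations) remain
plain configuration values.

## A worked run

```{r, eval = FALSE}
cfg <- pipeline_config(
  sim = sim_config(planted_effect = planted_effect(), seed = 1),
  n_draw = 2e4, n_perm = 200, run_nested = TRUE, seed = 1)
run <- run_coupling_pipeline(cfg, out_dir = "results")
run$fit        # selection: scores, q-values, global p
run$accuracy   # nested-LOO sensitivity/specificity/accuracy
```

## Known limitations

- **Detection power for isolated components.** The classification score is
  bounded by `bag_size / n_features / selected_fraction` (~0.11 at desk
  scale): any sufficiently separable feature saturates this ceiling. Every
  permutation contributes one "chance champion" feature to the pooled null
  whose score also saturates, so a *single* planted component — however
  strong — must outscore nearly all 200 champions to survive FDR at rank
  one-or-two, and detection hinges on the sampling variability of its
  realized group separation at n = 17 + 17. Cohorts with many informative
  components are much easier: their BH ranks support each other (rank r
  only needs the `1 - 0.05 r / n_features` pooled quantile). At desk scale
  the package's calibration studies therefore show strong *ranking*
  recovery of planted components (they are almost always the top-scoring
  features) but only partial FDR-level recovery; the nested-LOO accuracy,
  which uses the top-scored features as fallback, is not affected.

- The reference-basis stage assumes the reference and study cohorts share a
  coupling geometry; systematic acquisition differences between cohorts
  enter the projected features.
- Classification confidence on the *selected* components is an in-sample
  quantity; only the nested-LOO estimate is unbiased for new subjects.
- The severity correlation is a plain product-moment correlation over
  patients (Spearman available); with 13–16 scored patients its power is
  modest.
- At frequencies above ~35 Hz, real MEG coupling increasingly reflects
  residual muscle activity; band summaries are therefore split at 35 Hz, but
  the synthetic generator has no muscle surrogate.
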