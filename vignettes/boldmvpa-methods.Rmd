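---
title: "Methods: voxel-wise rs-fMRI measures, hybrid feature selection, and ELM classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel-wise rs-fMRI measures, hybrid feature selection, and ELM classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state BOLD fMRI captures spontaneous low-frequency fluctuations of
brain activity. In neurodegenerative disease — Alzheimer's disease (AD) and
its prodromal stage, mild cognitive impairment (MCI) — these fluctuations
change in characteristic ways: regional temporal coherence weakens or
shifts, low-frequency amplitude changes, and connectivity of default-mode
hubs (posterior cingulate, precuneus, hippocampus) degrades. `boldmvpa`
implements a complete voxel-wise discrimination pipeline for two-group
cohorts: extract several whole-brain measure maps per subject, select
discriminative voxels on training data only, classify held-out subjects,
and quantify significance by label permutation. Because clinical cohorts
are access-restricted, the package ships a synthetic BOLD cohort generator
that plants the same three families of signal the measures target, so the
entire pipeline is exercised end to end by code alone.

## Measures

All measures are computed per subject inside a brain mask, after temporal
preprocessing (below).

**Regional homogeneity (ReHo).** For each voxel, Kendall's coefficient of
concordance between the voxel's time series and its neighbours (27-voxel
neighbourhood by default; 7 and 19 available). With $K$ series of length
$T$, ranks computed per series over time, and per-time-point rank sums
$R_i$,
$$W = \frac{12 \sum_i (R_i - \bar R)^2}{K^2 (T^3 - T)} \in [0, 1].$$
Mid-ranks are used on ties without a tie correction: on continuous BOLD
data exact ties have probability zero, so the correction would never
change a value while complicating the contract. Edge voxels use whatever
neighbours are in-mask, with $K$ reduced accordingly; a strict mode
assigns 0 where the neighbourhood is incomplete, matching toolchains that
require a full neighbourhood.

**ALFF and fALFF.** The one-sided amplitude spectrum $a(f)=\sqrt{P(f)}$ of
each *unfiltered* (detrended, residualised) series is computed by FFT.
ALFF is the mean of $a(f)$ over the 0.01–0.08 Hz band; fALFF is the band
amplitude sum divided by the full-band amplitude sum. The full band is
$(0, f_{Nyq}]$: at TR = 3 s the Nyquist frequency is 0.167 Hz, so a fixed
0.25 Hz cap would be physically unattainable; a cap can still be set via
`full_band_hz` for shorter-TR data.

**Degree centrality (DC).** Pearson correlation between every pair of
in-mask voxel series; each voxel's degree is the sum of correlations
exceeding `r_threshold` (0.25 by default). The threshold applies to the
signed correlation, so anticorrelations never contribute; a binary-degree
mode counts instead of sums. The map is z-scored over the mask. The
correlation matrix is computed in column blocks so memory stays bounded
at large masks.

**Seed-based functional connectivity.** The seed's mean series is
correlated with every voxel and Fisher-transformed, $z = \mathrm{atanh}(r)$,
with $r$ clipped to $\pm(1 - 10^{-7})$ so self-correlated voxels stay
finite. Seeds are given as explicit masks or as spheres around mm/voxel
coordinates (default radius 6 mm); no atlas is bundled, so atlas-defined
regions must be supplied as masks by the user.

**Concatenation.** Measures are concatenated subject-wise into a features
matrix with fixed column order — ReHo, fALFF, ALFF, DC, then seed
measures in supply order, each ordered by voxel linear index — with full
per-column provenance (measure name, 1-based voxel index). Voxel indices
are 1-based throughout, matching R's array semantics; mm coordinates go
through the NIfTI affine, which internally uses 0-based voxel offsets.

## Preprocessing

The package deliberately models only the *temporal* cleanup of
already-aligned volumes (slice timing, realignment, normalisation and
co-registration are out of scope; their outputs are the package's
inputs). Default order: discard initial volumes (configurable, default 0
for synthetic data), per-voxel linear detrend, ideal FFT band-pass
(0.01–0.08 Hz), then regression of user-supplied nuisance series (CSF,
white matter, motion parameters — never estimated in-package). The
band-pass zeroes FFT bins outside the band, so its action is exact at bin
frequencies and the output has exactly zero temporal mean; each stage is
individually idempotent. The composite chain is *not* exactly idempotent:
the trend projection and the band-pass do not commute, so a second full
pass changes data slightly — a property of any pipeline combining these
operations, worth knowing when comparing toolchains.

Spatial smoothing (separable Gaussian,
$\sigma = \mathrm{FWHM} / (2\sqrt{2\ln 2} \cdot \mathrm{voxel})$,
default 6-mm FWHM on 3-mm voxels, zero-padded convolution) is applied to
the finished measure maps, not to the series: measures like ReHo are
conventionally computed on unsmoothed data and smoothed afterwards, and
applying one rule to all measures keeps the contract simple. Zero padding
attenuates values within one kernel radius of the mask edge; maps are
restricted to the mask afterwards. Each measure map is then z-scored over
the mask per subject (`scale_maps`, default on) for cross-subject
comparability. Note one side effect: a strong localised group effect
shifts the map mean, so after z-scoring the *background* acquires a small
opposite-sign group difference; with liberal voxel thresholds this
broadens the univariate mask. Disable `scale_maps` when calibrated
voxelwise type-I rates matter more than cross-subject scale alignment.

## Feature selection (training data only)

Per outer fold, using training subjects only:

1. **Univariate t masks.** Pooled-variance two-sample t per voxel and
   measure; threshold $|t| \ge t_{crit}(\alpha, df)$ with exact Student
   quantiles at the fold's df (at df = 207 and $\alpha$ = 0.05/0.01/0.001
   these are 1.9715, 2.5998, 3.3381). Zero-variance voxels get $t = 0$,
   $p = 1$, flagged.
2. **Cluster-extent correction.** Connected components (26-connectivity
   default; 6/18 available) smaller than a minimum extent are removed.
   The extent either comes from configuration or from a Monte-Carlo
   simulation: Gaussian noise volumes smoothed to the analysis FWHM,
   re-standardised in-mask, thresholded two-tailed, maximum cluster size
   recorded per iteration (1000 by default), and the smallest size $s$
   with $P(\max \ge s) \le \alpha_{cluster}$ returned. Smoothness is
   parameterised by the applied FWHM rather than estimated from
   residuals. Each measure keeps its own surviving voxels; concatenation
   is their disjoint union.
3. **SVM-RFE** (optional). Iteratively train a linear SVM, score features
   by $w_j^2$, eliminate the weakest features, repeat; ranking is reverse
   elimination order. Elimination is one feature per iteration up to 500
   features and 10% of the remainder beyond that — the canonical
   single-feature variant is infeasible at voxel scale and chunking is
   the standard compromise. Weight ties are broken by eliminating the
   lower column index first, making runs bit-reproducible. The linear
   kernel is used for ranking even when classification is RBF: the
   squared-weight criterion is only well-defined for the linear machine.
   The retained count $k$ is chosen by inner-CV accuracy over a
   configurable grid (ties to the smallest $k$).
4. **LASSO** (optional). In-house cyclic coordinate descent on
   $$\min_{\gamma_0, \gamma} \frac{1}{2n}\sum_i (u_i - \gamma_0 -
   x_i^\top\gamma)^2 + \lambda \sum_j |\gamma_j|,$$
   warm-started along a decreasing $\lambda$ grid;
   $\lambda^*$ minimises the k-fold CV MSE and the nonzero-coefficient
   features at $\lambda^*$ are kept. The closed forms
   ($\lambda_{max} = \max_j |x_j^\top (u - \bar u)|/n$ kills every
   coefficient; a single standardised feature soft-thresholds) and an
   independent solver are used as test oracles.

Features are z-scored with training-fold statistics before RFE, LASSO and
every classifier — all three are scale-sensitive, and test rows reuse the
training statistics so no test information leaks.

## Classifiers

**ELM.** A single-hidden-layer network whose input weights and biases are
drawn Uniform(−1, 1) from a seed and never trained; with
$H = \mathrm{sigmoid}(XW^\top + b)$, the output weights solve
$H\beta = y$ ($y \in \{-1, +1\}$) by Moore–Penrose pseudoinverse — one
deterministic linear solve, no iteration. Prediction is
$\mathrm{sign}(H\beta)$ with the $\mathrm{sign}(0)$ tie mapped to $+1$.
The hidden-layer size is grid-searched over 1–400 by default, averaging
inner-CV validation accuracy over 100 random initialisations per
candidate to damp initialisation noise (both counts configurable; scaled
down in the test suite). No ridge term is added by default (an optional
$\varepsilon$ exists for ill-conditioned hidden layers). The standard
sigmoid $1/(1+e^{-z})$ is used; binary targets are coded $\pm 1$.

**SVM baselines.** Linear and RBF SVMs (via `e1071`/libsvm) with
exhaustive grid search over $C, \gamma \in \{10^{-3}, \dots, 10^{4}\}$
(eight decades each), inner-CV accuracy, ties to the smallest $C$ then
$\gamma$.

All inner grid searches use stratified 5-fold CV on training rows with
recorded seeds.

## Evaluation

Outer CV is leave-one-out or stratified k-fold (stratification prevents
class-empty folds at small n; the split seed is recorded). Per fold the
confusion counts give ACC, SEN, SPEC, BAC = (SEN+SPEC)/2, PPV and NPV as
percentages; zero-denominator metrics are returned as `NA` with a count
of exclusions, and fold metrics are aggregated as mean ± SD alongside
pooled-count metrics (the two differ when folds are unbalanced — both are
reported rather than choosing).

The permutation test holds the per-subject test predictions fixed and
permutes the true labels $P$ times (default 1000);
$p = (1 + \#\{\mathrm{null} \ge \mathrm{observed}\})/(1 + P)$, so the
attainable floor is $1/(P+1)$. This tests the labelling against the fixed
predictions — it does not rerun the pipeline per permutation, so it is
liberal relative to a full rerun; the design follows the evaluation
convention the pipeline mirrors, and a stricter rerun variant can be
composed from the exported stage functions if needed.

## Synthetic cohorts

Voxel noise is stationary Gaussian AR(1) (default $\phi = 0.3$, marginal
SD 1): the simplest temporal null with a closed-form spectrum, enough to
give the band-limited analyses something realistic to reject. Three
additive effect kinds plant group structure, each scaled by a per-group
amplitude pair (the group difference lives entirely in the amplitudes):

- *coherence* — one shared band-limited latent series added to every
  voxel of a region: raises within-region concordance (ReHo) and band
  power; pairwise correlation approaches $a^2/(a^2+\sigma^2)$.
- *amplitude* — an independent band-limited latent per voxel: raises
  ALFF/fALFF without inter-voxel coherence.
- *coupling* — the same latent added to a region and a partner region:
  raises seed-FC and degree centrality in both.

Latents are built directly in the frequency domain (complex Gaussian
coefficients on in-band FFT bins only, conjugate-symmetrised, scaled to
exactly unit variance), so out-of-band spectral mass is zero by
construction. Everything is reproducible bitwise from one seed via named
substreams (per-subject generation, fold splits, ELM initialisations,
permutations, cluster simulations all derive from the master seed).

The generator does **not** emulate haemodynamic response shapes, head
motion, physiological noise, scanner drift or multi-site effects. Passing
tests therefore demonstrate that the pipeline's statistics, selection and
classification machinery are correct and leak-free — not that the
pipeline is robust to real-world artefacts.

The reference study conditions (`demo_cohort_spec()`) are 20 + 20
subjects, a 24³ grid of 3-mm voxels (ellipsoidal brain mask, ~4200
voxels), 120 volumes at TR = 3 s, and three planted spheres of 2.5-voxel
radius with group-0/group-1 amplitudes (0.5, 2.0) for coherence and
amplitude and (0.375, 1.5) for coupling — strong, clearly separable
effects chosen to exercise recovery, not to mimic clinical effect sizes,
for which no reliable voxel-level ground truth exists. The test suite
uses scaled-down variants (16³ × 64, 6 + 6; 12³ × 48, 4 + 4) so the whole
suite and the acceptance script run in minutes on one CPU.

## Numerical choices and edge cases

- Ideal FFT filtering and frequency-domain latent construction make
  spectral tests exact at bin frequencies; off-bin sinusoids leak, as
  they must.
- Correlations of constant series are set to 0 with a warning (DC) or
  error (a constant seed mean).
- Fisher z clipping at $\pm(1-10^{-7})$ caps $z$ at ≈ 8.41.
- All tie-breaks are deterministic and documented: RFE elimination by
  column index, grid searches to the smallest parameter, ELM
  $\mathrm{sign}(0) \to +1$.
- `alphasim`-style thresholds error when $\alpha_{cluster} < 1/n_{iter}$
  rather than returning an unresolvable extent.
- An empty univariate mask (nothing survives in any measure) is an error
  advising a larger $\alpha$, not a silent empty feature matrix; an empty
  LASSO selection falls back to the single strongest-path feature.

## Known limitations

- The permutation test inherits the fixed-prediction design's liberal
  bias (above).
- Zero-padded smoothing biases measure values near mask edges.
- The univariate stage tests each voxel marginally; with per-subject map
  scaling enabled, localised effects induce small compensatory background
  differences (see Preprocessing).
- The ELM pseudoinverse solve is exact but can be ill-conditioned for
  very large hidden layers on few subjects; the optional ridge term
  exists for that case.
- Only binary discrimination is supported; three-group designs are run
  as pairwise problems.
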