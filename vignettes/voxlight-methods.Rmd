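---
title: "Searchlight decoding and permutation inference: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Searchlight decoding and permutation inference: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

voxlight implements, end to end, the two standard analysis tracks of a
voice-localizer block experiment — a per-block GLM feeding (a) a univariate
vocal-minus-non-vocal contrast and (b) searchlight SVM decoding — together
with nonparametric second-level inference, driven by a synthetic cohort
generator. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic experiments do and do not show.

## The generative model

Each simulated subject is a 4D series on a common grid (default
16 × 16 × 12 voxels of 3 × 3 × 3.3 mm for desk-scale work; 70 × 70 × 32
mirrors a whole-cortex EPI matrix) over 310 volumes at TR 2 s. The signal
model is

    y_v(t) = baseline + drift_v(t) + sum_b X_b(t) * amp_b(v) + noise_v(t)

where `X_b` is block *b*'s regressor (boxcar convolved with the HRF) and,
inside a planted region,

    amp_b(v) = a(cond_b, group) + pattern_scale(group) * pat(v) * code(cond_b)

with `code(vocal) = +1`, `code(non-vocal) = −1`. The signed pattern `pat`
is balanced ±1 (a single 0 filler if the region has an odd voxel count), so
its spatial mean is exactly zero: the pattern adds decodable structure with
no univariate contrast in expectation. Noise is white Gaussian (an AR(1)
option exists, default 0 — nothing in the emulated protocol constrains
temporal autocorrelation); drift is a low-order cosine basis, default
amplitude 0. Everything is seeded: identical inputs and seed give
bit-identical data, and cohort subject seeds derive deterministically from
one global seed.

**Units.** `baseline = 100` plays the role of a grand-mean-scaled signal,
so amplitudes are percent-signal-change-like: `noise_sd = 1` is 1% noise
per volume, and a vocal response of 0.15–1 units spans weak to strong
block responses. With the default design, per-block beta noise is ≈ 0.54
per unit of time-series noise (measured; it depends only on the design
matrix).

**Shared vs subject-specific patterns.** `pattern_mode = "shared"` uses
one pattern for every subject; `"subject"` draws an independent pattern
per subject. The distinction is scientifically load-bearing. A pattern
shared across subjects is a fixed voxelwise effect: group differences in
its scale survive averaging across subjects and are therefore detected by
a voxelwise univariate two-sample test — only the *regional average* is
blind to it. Subject-specific patterns leave within-subject decodability
untouched (the classifier only needs block-to-block reliability inside a
subject) while averaging out of the univariate contrast across subjects.
The group-dissociation configuration (`dissociation_truth()`) therefore
uses `"subject"`; this is also the more realistic reading of fine-grained
pattern idiosyncrasy across brains. `"shared"` remains the constructor
default and is useful for single-subject tests.

**Rest placement and block order.** The paradigm (40 × 10 s) occupies
400 s of the 620 s run; the protocol does not pin down where the rest
lies or the block order. The package places a configurable lead-in
(default 10 s) before the first block, leaves the remaining rest at the
end, and draws a seeded random order with equal condition counts — a
random order avoids confounding condition with drift.

## GLM and regressors

The design matrix has one column per block: the block's boxcar on a 0.1 s
grid, convolved with the canonical double-gamma HRF (delays 6 s / 16 s,
dispersions 1, undershoot ratio 1/6, 32 s support) and sampled at the
volume times. Two normalisations coexist deliberately:

- `hrf_kernel()` returns the kernel at **unit peak** — the natural shape
  for inspection and for tests that locate the ≈ 5 s peak.
- `build_design_matrix()` convolves with the kernel scaled to **unit
  integral** (the standard regression convention): a sustained response of
  amplitude `a` then yields a regressor plateau near 1 and betas near `a`.
  The convolution is a Riemann sum, so results are invariant to the fine
  step. The `identity` HRF is treated as the Dirac identity: the regressor
  is the sampled boxcar itself.

The regressor convention matters beyond aesthetics: it sets the scale of
the beta exemplars the classifier sees (next section).

Fitting is ordinary least squares per voxel, shared by both tracks
("one 40-column fit feeds both"): betas are the classification exemplars
and the contrast `mean(vocal) − mean(non-vocal)` is the univariate
statistic. No prewhitening, motion or physiological regressors are
modelled (none are simulated); cosine drift columns are available and
default to 0 for synthetic data. Rank-deficient designs and models with
`n_regressors ≥ n_volumes` are rejected, naming the offending columns.

The emulated protocol smooths the *data* before the univariate GLM.
Smoothing is spatial and the GLM is temporal and voxelwise, so
smoothing-then-GLM equals GLM-then-smoothing exactly (both are linear);
the pipeline smooths the contrast image, which keeps a single GLM per
subject.

## Searchlight decoding

The searchlight uses a closed ball on voxel-centre distances: all integer
offsets with `sqrt((i·dx)² + (j·dy)² + (k·dz)²) ≤ radius`. At 6 mm radius
that is 33 offsets at isotropic 3 mm spacing and 31 at 3 × 3 × 3.3 mm. A
sphere enters the analysis when at least `min_gm_fraction` (default 0.5,
compared with ≥) of its *in-grid* voxels are gray matter — using the
in-grid count as denominator keeps edge-of-volume spheres alive and only
penalises gray-matter-poor ones. Features are the sphere's in-gray-matter
voxels by default (`feature_space = "in_grid"` is available, since the
emulated protocol does not say which was used).

The classifier is a linear hinge-loss SVM, C = 1, no feature scaling,
intercept fitted — the common reading of a "default linear SVM". It is
trained in the dual by coordinate descent (a liblinear-style solver written
for the searchlight's inner loop; the intercept is an augmented regularised
constant feature). Determinism is guaranteed: sweep order comes from a
fixed xorshift generator, folds warm-start from the full-data solution
(the fold optimum is unique, so this only saves sweeps), and a decision
value of exactly 0 predicts the positive class. The test suite
cross-checks predictions and LOO accuracies against libsvm (e1071) on
separable and structured problems.

Leave-one-out accuracy over the 40 betas is stored at the sphere's centre;
chance (0.5) is subtracted and the map smoothed with 6 mm FWHM using
in-mask renormalisation (dividing by the smoothed mask), so values are not
attenuated at the validity-mask boundary. Spatial normalisation to a
template is the identity here — synthetic subjects share one grid by
construction.

### Two properties of LOO + SVM worth knowing

- **Feature scale interacts with C.** With `C·‖x‖²` far below 1 the
  soft-margin SVM degenerates toward a majority vote; under LOO the
  held-out exemplar's class is always the training minority, so null
  accuracy collapses toward 0 (an extreme case: constant features give
  exactly 0). At the package's beta scale (noise ≈ 0.54 per unit
  time-series noise, ~20–30 features) decoding operates in the healthy
  regime.
- **LOO is pessimistically biased under the null.** Even in the healthy
  regime, the 19-vs-20 training imbalance pulls predictions toward the
  (wrong) majority: measured null accuracy is ≈ 0.48–0.49, one to two
  accuracy points below the theoretical 0.5, and the effect is carried
  almost entirely by the intercept (without it, measured ≈ 0.50). This is
  a property of leave-one-out itself, not of the solver; group inference
  is unaffected because it tests maps against their own permutation null,
  but point comparisons of raw accuracy to 0.5 inherit the bias.

## Second-level inference

One-sample tests sign-flip whole subject maps; two-sample tests permute
group labels with the pooled-variance t. The identity permutation is
always in the null, so p-values are bounded below by `1/N`. With
`exhaustive_if_feasible` (default), all `2^n` flips are enumerated for
n ≤ 14 subjects and all `choose(n, nA)` assignments up to 20,000 for the
two-sample test — the desk-scale cohorts (8 + 8) are exhaustive in both
tracks, which makes p-values exact and runs reproducible without a seed; a
seed is mandatory for Monte-Carlo runs. FWE correction uses the maximum
statistic over the mask; uncorrected p comes from each voxel's own
permutation distribution (a parametric option is deliberately not offered
— one self-contained mechanism serves both tracks, and random-field
corrections are out of scope). Degenerate voxels follow a documented
convention: zero variance with zero mean gives t = 0, p = 1; zero variance
with non-zero mean gives an infinite statistic, which the counting rules
handle correctly (e.g. five identical positive maps give exactly p = 1/32).

Between-group tests (both directions, run as one-tailed tests with the
groups swapped) are restricted to the conjunction mask: voxels with
uncorrected p strictly below 0.01 in both groups' one-sample decoding
tests. The same mask restricts the univariate between-group tests.
Clusters are connected components of the significant set (default
18-connectivity, configurable 6/18/26; peak ties break to the first voxel
in scan order), reported with peak location, size, and Cohen's d (pooled
SD) at the peak.

## The dissociation configuration

`dissociation_truth()` plants two bilateral 6 mm regions with identical
univariate amplitude (vocal 0.15, non-vocal 0, noise SD 1) in both groups
and subject-specific patterns with `pattern_scale` 0.23 (F) vs 0.05 (M).
These values were fixed once by power reasoning at the measured beta noise
(0.538): over a ~20-voxel sphere they target multivariate class
separabilities of roughly 4 (F) and 1.5 (M) noise units, i.e. decoding
near ceiling for F (~0.97 observed at region centres) and modest but
above-chance for M (~0.70) — both groups clear the conjunction threshold
while only the F > M accuracy difference survives FWE correction, and the
univariate contrast, equal in expectation across groups, stays silent.

## Problem sizes

The package's own test and acceptance runs use: the 16 × 16 × 12 grid with
8 + 8 subjects for the headline experiment (~1.5 min); 100 null cohorts on
a 10 × 10 × 8 grid with a 12-block design for FWE calibration (~1 min);
10³-grid brute-force equivalence for the searchlight; 200 replicates for
GLM bias; 6 null subjects for decoding calibration. These sizes make every
claim recomputable on one CPU in minutes while keeping the tests'
Monte-Carlo errors meaningful.

## What passing tests do and do not show

The generator emulates the paradigm's timing, geometry and the
amplitude/pattern dissociation mechanism. It does not emulate: spatial
noise correlations or physiological noise structure, motion and its
interaction with the signal, between-subject anatomical variability (all
subjects share one grid and mask — spatial normalisation is the
identity), scanner drift beyond a cosine basis, or stimulus acoustics.
Consequently, passing the calibration and dissociation tests shows the
*machinery* is correct and the inference calibrated under exchangeable
noise; it does not certify sensitivity or specificity on real BOLD data,
where smoothness, artefacts and registration error change the operating
characteristics. Cluster sizes, peak statistics and mask sizes from real
cohorts depend on those factors and on sample size, and are expected to
differ from the synthetic values.

## Known limitations

- Voxel-level maximum-statistic FWE only; no cluster-extent or TFCE
  inference, no covariates, no variance smoothing.
- The two-sample permutation test assumes exchangeability under the null;
  with strongly unequal group variances *and* unequal group sizes it is
  only approximate (the package's designs use equal sizes).
- Raw LOO accuracy is compared to the theoretical chance level only
  descriptively; inferential statements always go through the permutation
  null (see the LOO bias note above).
- The searchlight reports the sphere-centre accuracy map only; no
  information-mapping variants (e.g. weight maps) are provided.
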