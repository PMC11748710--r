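---
title: "octgrade: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{octgrade: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octgrade)
```

This vignette documents the science and the engineering decisions behind
`octgrade`: what each stage computes, why the defaults are what they are,
how the synthetic data generator relates to real AS-OCT images, and where
the method's limits lie. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The grading problem

Nuclear cataract severity is graded `normal < mild < severe` from
anterior-segment OCT. Raw images of different grades look similar, but the
distribution of pixel intensity inside the segmented lens nucleus separates
them: opacity raises and spreads the intensity mass. `octgrade` therefore
works entirely on (a) the intensity histogram of the masked nucleus and
(b) simple intensity statistics of the masked pixels. The segmentation mask
is an input; producing it is deliberately out of scope.

## The nucleus histogram

`build_histogram()` discretizes the masked pixel values into `N =
ceil((hi - lo) / w)` bins of width `w` with left boundaries `L_i`,
producing proportions `X_i`. Three conventions are worth making explicit,
because histogram statistics are sensitive to all of them:

* **Bin edges.** Bins are half-open `[L_i, L_i + w)` with the final bin
  closed at `hi`, so the upper boundary value is counted exactly once and
  the bins tile the range without overlap. With the default 5–150 / width-5
  setting this gives `N = 29` bins at boundaries 5, 10, …, 145.
* **Out-of-range pixels** are excluded from both the numerator and the
  denominator of `X_i`. The 5–150 default exists precisely to remove the
  large near-zero background mass and the sparse high tail; excluding that
  mass from the denominator is the only choice under which restricting the
  range actually sharpens the class differences rather than merely
  rescaling all proportions. The alternative (`denominator = "all"`) is a
  config switch, under which `ΣX_i < 1` and percentile crossings are taken
  relative to the binned mass so they remain well defined.
* **Units.** Moment-type features operate on bin *indices* `i` exactly as
  the defining formulas are written; boundary-type features (minimum,
  maximum, interquartile, range, quartile dispersion) operate on the left
  boundaries `L_i` in intensity units. The catalog intentionally mixes the
  two unit systems; the ridge stage standardizes features, so the mixed
  scales do not leak into the classifier.

The alternative settings exercised by the ablation command — full range
0–255 and bin width 10 — are the comparison conditions for studying how
range and resolution choices propagate into recognition performance.

## The 27-feature catalog

`histogram_features()` computes 23 statistics of `X`: mean
`μ = Σ i X_i`, variance, skewness and *excess* kurtosis (a two-point
equal-mass histogram has kurtosis exactly −2, a useful check), mean/median
absolute deviations, a 10–90 percentile-restricted absolute deviation,
coefficient of variation `σ/μ`, entropy in bits, uniformity `Σ X_i²`,
percentile indices (smallest index whose cumulative proportion reaches the
target), the mode index, occupied-bin boundary extrema, interquartile and
range differences, the quartile coefficient of dispersion, and the extrema
and arg-extrema of the forward-difference gradient `g_i = X_{i+1} − X_i`.
`intensity_features()` adds the four clinical statistics of the raw masked
pixels: mean, median, standard deviation, maximum.

Decisions where the definitions left latitude:

* **Occupied-bin semantics.** The minimum/maximum boundary features are
  restricted to bins with `X_i > 0`. On full-range histograms the lowest
  bin is essentially always occupied, which is why the minimum feature is
  degenerate ("zero by nature") in that setting — the occupied-bin reading
  is the only one under which that observation makes sense.
* **Truncated deviation.** The 10–90 restricted absolute deviation sums the
  literal truncated mass without renormalizing; a renormalized variant is
  available via `ihr_renormalize = TRUE`.
* **Mode as an index.** The mode feature returns the *index* of the largest
  proportion, not the proportion itself, keeping its units consistent with
  the other location features.
* **Ties and degeneracy.** All arg-extrema and percentile crossings resolve
  to the smallest index. A single-occupied-bin histogram would give 0/0 for
  skewness and kurtosis; both are set to 0 with a warning, and likewise the
  quartile dispersion when its denominator is 0, so downstream tables stay
  finite. The intensity SD uses the population denominator `n`
  (config-switchable); on histograms built from proportions the population
  convention is the self-consistent one.

Every histogram statistic is validated against a brute-force oracle that
re-derives the same quantities from per-pixel bin assignments by linear
scan, independent of the vectorized binning code.

## Shapley importance with retraining

Feature importance uses the classical Shapley value over the feature set
`T`, with the *model retrained from scratch* on every feature subset `S`,
and the value function `f_S^c(y)` = the retrained model's predicted softmax
probability of class `c` for sample `y`. The result is a samples × features
× classes array: per-class importances are mean `|φ|` within the class
dimension, and the overall importance is the mean over samples and classes.
Probability (rather than the hard label) keeps `φ` continuous; the
empty-set model predicts the training class frequencies, the standard
baseline.

Exact enumeration costs `2^|T|` retrainings and is capped at 12 features;
beyond that, `mode = "sampled"` averages marginal contributions along
random feature orderings — an unbiased estimator of the same weighted sum —
using antithetic pairs (each sampled ordering together with its reverse) to
reduce variance. Submodels are cached by feature subset, so with few
features the sampled mode converges to exact enumeration at essentially the
cost of the distinct subsets encountered. The sampling seed is a required
part of the configuration; identical seeds give identical estimates.

The exact mode is tested against the Shapley axioms (efficiency per sample
and class to 1e−8, symmetry of duplicated columns, zero attribution for
features that never change a prediction) and the sampled mode against the
exact values.

## Redundancy filtering and selection

Pearson correlations are computed feature-vs-ordinal-severity and pairwise
between features; constant features take correlation 0 with a `constant`
flag rather than NA, so degenerate features propagate zeros. The selection
rule codifies a two-stage judgment: drop features whose overall Shapley
value falls below `shap_floor` (default 0.015 — on an importance scale
where the leading features sit around 0.5–1.7, values below ~0.015 are
negligible), then resolve redundant pairs (explicitly listed, or
`|PCC| ≥ 0.95`) by dropping the lower-importance member. Exact importance
ties are resolved by keeping the index-valued (location) member of the
pair, else alphabetically. Applied to the bundled clinical importance table
with the three stated redundant pairs, the rule retains 22 of 27 features;
both the floor and the threshold are ordinary parameters, not hard-coded
outcomes.

## The ridge ensemble

Recognition uses one ridge regression per class in one-vs-all 0/1 coding,
solved in closed form from the normal equations
`(XᵀX + λI) ŵ = XᵀY` (a symmetric linear solve; no explicit inversion),
with the intercept carried as a final all-ones design column. Per-class
scores are combined by max-shifted softmax and decided by argmax, ties to
the lowest severity code.

* **Intercept penalization.** The objective as written penalizes the full
  weight vector including the intercept, and that is the default;
  `penalize_intercept = FALSE` gives the conventional variant. With
  standardized features and moderate λ the two rarely disagree.
* **λ = 1 by default.** The study this design follows does not state its
  penalty; λ = 1 on standardized features is the neutral middle of the
  usual grid and is exposed everywhere (function argument, config key, CLI
  flag). λ = 0 is allowed when the design is nonsingular.
* **Standardization on by default.** Ridge shrinkage is scale-sensitive and
  the catalog deliberately mixes bin indices, intensity units and
  proportions; z-scoring with training statistics (stored in the model) is
  the safe default. Constant columns are centered and left at scale 1.

A structural note: with a *single* feature, the three one-vs-all scores are
three lines in that feature, and the middle class can win only where its
line is uppermost — often nowhere. Single-feature accuracies therefore
saturate well below 1 even for strongly class-correlated features; this is
a property of linear one-vs-all scoring, visible in the per-feature
accuracy column of any importance report.

## Evaluation metrics

Accuracy, precision, sensitivity, specificity and F1 are computed per class
from one-vs-rest counts and macro-averaged (unweighted mean over classes);
macro was chosen because reporting specificity at all implies the balanced
per-class treatment, and a micro view is available as the plain agreement
rate (`overall_accuracy`), which is also the quantity used for held-out
accuracy checks. Zero-denominator cells report 0 and set a flag rather than
NaN.

## The synthetic generator

`generate_image()` draws nucleus pixels from a three-component mixture:

| component | default | role |
|---|---|---|
| background spike, uniform on 0–4 | weight 0.20 (all classes) | the near-zero mass that dominates full-range histograms |
| truncated normal on [0, 255] | mean 30/55/85, sd 8/12/18 for normal/mild/severe | the opacity body; shifts and widens with severity |
| uniform tail on 110–180 | weight 0.00/0.05/0.15 | the heavy high-intensity tail of advanced opacity |

Pixels are rounded, clipped to 8 bits, and placed inside an elliptical
nucleus mask (default 64×64 image, semi-axes 20×26 ≈ 1,600 nucleus
pixels); outside pixels are 0. The class means/SDs/tail weights are the
package's fixed simulation conditions; the background weight and the tail
support were chosen once as plausible for nucleus intensity mixtures and
are not tuned. Per-image seeds derive as `seed + index`, so any subset of a
dataset is reproducible independently, and the whole dataset is a pure
function of its `sim_config()`. The sampler is validated against the
closed-form truncated-mixture mean.

What the generator does *not* emulate: OCT speckle statistics, anatomical
layering, asymmetric opacity distributions, segmentation error, class
imbalance, or inter-device variation. Consequently the default profiles are
*linearly separable by construction* — a held-out accuracy of 1.0 on them
validates the machinery, not clinical performance — and the collapsed
profiles (`collapsed_profiles()`), where all classes share one mixture,
bound the opposite extreme at chance level (≈ 1/3). Results on this
generator say nothing quantitative about clinical AS-OCT data.

## Problem sizes and numerical tolerances

The test suite and the acceptance script use: 200 images/class for the
separable recognition check and 500–1,000/class for the chance-level check;
exact-vs-sampled Shapley comparisons on 5–8 features with up to 2,000
permutations; 20 random ridge problems against a BFGS minimizer of the
penalized loss at 1e−6; oracle agreement for histogram statistics at 1e−10
over ~100 random pixel lists; softmax normalization and histogram mass at
1e−12. These sizes were chosen so the full validation runs comfortably on a
laptop while keeping every stochastic check far from its decision boundary.

## Known limitations

* The mask is trusted as given; segmentation errors propagate directly into
  every feature.
* Only 8-bit grayscale inputs are accepted; other bit depths are rejected
  rather than rescaled, by design.
* The EMRR is linear; severity signals that are non-monotone in every
  feature would require interactions or a nonlinear model.
* Sampled Shapley values on the full 27-feature catalog inherit Monte-Carlo
  error; the permutation count trades accuracy for time and should be
  raised for publication-grade importance tables.
* The selection rule reproduces a specific published judgment when given
  that study's importance values; on other data the same thresholds may
  select very different subsets — on the bundled synthetic cohort, whose
  features are extremely collinear, it prunes far more aggressively.
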