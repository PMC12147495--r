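---
title: "Predicting the variability of repeatedly measured responses with sub-dataset ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting the variability of repeatedly measured responses with sub-dataset ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonevar)
```

## The problem

Bone formation rate — the percentage of new bone formed after implanting an
artificial calcium-phosphate material (hydroxyapatite, β-TCP and related
ceramics) in an animal — is the key performance measure of a bone
substitute, and it varies substantially between implantations of the *same*
material. For material design two things matter: a high *mean* rate and a
*stable* rate, i.e. small animal-to-animal variability. Ordinary regression
workflows collapse the repeated measurements of each material to their
average and can therefore only predict the mean.

`bonevar` implements a framework that predicts a *distribution* per
material rather than a point:

1. **Sub-datasets.** From a panel of materials, each with a fixed feature
   vector $x_i$ and $k_i \ge 1$ repeated measurements
   $\{y_{i1}, \dots, y_{ik_i}\}$, draw $N$ sub-datasets. Each sub-dataset
   keeps every $x_i$ and draws exactly one $y_{ij}$ per material, uniformly
   at random. Materials with one measurement contribute the same value to
   every sub-dataset.
2. **One model per sub-dataset.** On each sub-dataset the best regression
   method (and hyperparameters) is selected from a zoo by inner
   cross-validation and assessed by double (nested) cross-validation, with
   5 inner and 10 outer folds by default. The out-of-fold estimates are
   retained, so each material accumulates $N$ predictions — an empirical
   predictive distribution whose spread reflects how variable the training
   responses are in the material's neighbourhood of feature space.
3. **Distribution scoring.** Measured and predicted values per material are
   summarised as Gaussians, and their distance is measured by the
   Jensen–Shannon divergence
   $$D_{\mathrm{JS}}(p, q) = \tfrac12\, D_{\mathrm{KL}}\!\left(p \,\Big\|\, \tfrac{p+q}{2}\right) + \tfrac12\, D_{\mathrm{KL}}\!\left(q \,\Big\|\, \tfrac{p+q}{2}\right),
   \qquad D_{\mathrm{KL}}(p \| q) = \int p(x) \log\frac{p(x)}{q(x)}\,dx,$$
   which is symmetric, non-negative, and bounded by $\log 2$ in natural
   log. The aggregate score of a feature combination is the arithmetic mean
   of per-material $D_{\mathrm{JS}}$, reported alongside the coefficient of
   determination $r^2$ of the per-material means. $r^2$ judges the means
   only; $D_{\mathrm{JS}}$ judges means and spreads jointly, which is what
   makes it informative about variability prediction.

## Gaussian summaries and the SD-substitution rule

Both sides of the divergence are fitted normals. The predicted side always
has $N$ estimates (100 by default), so mean and sample SD (denominator
$n-1$) are used directly; an SD that is numerically zero is floored at a
configurable epsilon and flagged. The measured side is sparse: materials
with one or two measurements cannot provide a usable SD. Following the
substitution rule, such materials receive the *mean of the sample SDs of
the materials with three or more measurements*
(`compute_fallback_sd()`), and the summary is flagged `sd_substituted`.
The substitution is never applied to the predicted side.

Two aggregation choices are deliberately simple and stated as assumptions:
the run-level $D_{\mathrm{JS}}$ is the unweighted mean over materials, and
divergences default to nats (`base = "bits"` switches to base 2; the bound
becomes 1).

## Numerical evaluation of the divergences

$D_{\mathrm{JS}}$ between two Gaussians has no closed form, so both
divergences are computed by trapezoidal quadrature on a uniform grid
spanning $[\min\mu - 10\,\sigma_{\max},\ \max\mu + 10\,\sigma_{\max}]$ with
20,001 points (`divergence_grid()`). Integrands are assembled from
*log*-densities (`dnorm(log = TRUE)`, with the mixture via log-sum-exp), so
far tails never underflow and the quadrature matches the closed-form
Gaussian KL to well below $10^{-6}$ across $\sigma \in [0.1, 10]$; points
where the reference density vanishes to double precision contribute zero by
the usual convention, and small negative results are clipped to zero.
Doubling the grid changes $D_{\mathrm{JS}}$ by less than $10^{-7}$.

## Model selection inside the resampling loop

The zoo (`model_zoo()`) covers ordinary least squares, ridge, lasso,
elastic net, linear and RBF support-vector regression, Gaussian process
regression, a decision tree, a random forest, and gradient-boosted trees,
each with a small conventional grid (regularisation strengths on log grids,
SVR cost/width on powers of two, tree depths 3/5/unbounded, 200 trees). Two
design points deserve explanation:

* **Selection is nested.** The best method is chosen *inside each outer
  training fold* by inner CV, never on rows the outer fold will test —
  selecting once per sub-dataset on all rows would leak the held-out
  responses into the choice. The price is `outer_folds` selections per
  sub-dataset.
* **The selection score** is the $r^2$ of the pooled inner out-of-fold
  predictions. Averaging per-fold $r^2$ values is the obvious alternative,
  but with ~7 rows per inner fold a single fold's denominator can be
  near-degenerate; pooling ranks candidates identically in the typical case
  and is robust in the small-sample one.

Features are standardised with training-fold statistics only (zero-variance
columns are centred and left unscaled); the linear and kernel methods
require it and the tree methods are indifferent. Ridge is solved exactly
via SVD of the standardised design — one decomposition serves the whole
lambda grid and $p > n$ is handled naturally — while lasso and elastic net
use coordinate descent (glmnet). All stochastic learners receive seeds
derived deterministically from the run's root seed, so a run is
reproducible bit for bit; fold shuffles are independent across
sub-datasets.

The out-of-fold estimates themselves are the ensemble's predictions
(rather than predictions of models refitted on all rows), so the reported
distributions are honestly out of sample.

## Feature blocks

Base features (synthesis conditions, animal-experiment conditions, material
properties) are always included. Three optional blocks mirror the
instrument data available for bone substitutes, switched by the eight
combinations A–H (`method_combo()`; A = none, H = all):

* **FT-IR and XRD band intensities** (`select_band_intensities()`): the
  mean intensity within a ± window of each configured band position
  (window 0 = nearest grid point). Characteristic wavenumbers and
  diffraction angles of the phases present (e.g. hydroxyapatite and β-TCP)
  are *configuration*: sensible positions are instrument- and
  material-specific, so the package fixes none.
* **LBP histograms** (`compute_lbp_codes()`, `lbp_histogram()`): each
  interior pixel of a grayscale SEM-like image is coded by binarising the
  eight neighbour-minus-centre differences (≥ 0 → 1, read clockwise from
  the top-left neighbour as MSB) and the 256-bin code histogram is the
  feature block. Ties map to 1, which matches the canonical LBP definition
  and makes constant images well defined (code 255); borders are not
  padded. Codes are invariant to brightness offsets and to any strictly
  monotone intensity transform.
* **Imputation** (`impute_missing()`): materials lacking an image get their
  LBP cells filled by iterative Gaussian-mixture conditional means —
  initialise at column means, fit a small full-covariance mixture (EM with
  ridge-regularised covariances, seeded k-means initialisation), replace
  each missing cell by its conditional mean given the row's observed cells,
  and repeat to convergence. This is a deliberately simple scheme intended
  to keep rows usable, not a state-of-the-art imputer.

## The synthetic generator

No public panel of bone-substitute materials with repeated implantation
results exists, so `generate_synthetic_dataset()` emulates the *structure*
such data is assumed to have, with every default chosen once as a realistic
study condition: 38 materials; a measurement-count histogram with 17
single-measurement materials and the remainder at 2–6 (counts assigned to
materials at random); per-material true SDs spanning 2–12 % — the kind of
spread implantation experiments show; and a latent two-phase composition
$c \in [0,1]$ that drives two of the five base features (noisily), the
spectral peak amplitudes (first signature $\propto c$ at six FT-IR/five XRD
positions, second $\propto 1-c$), the texture coarseness of 64×64
filtered-noise images, and the true mean response
$20 + 50c - 15c^2$ percent (truncated to $[0, 100]$).

The default links the true SD monotonically to the composition
(`sd_link = "composition"`, with a 15 % uniform jitter). This is a
deliberate design choice: a material's own out-of-fold estimate never sees
its own responses, so the ensemble can only recover variability that is
*encoded in the features*. An SD drawn independently of everything
(`sd_link = "independent"` remains available) is unlearnable by
construction and is the right null case, not the right default. Note what
this implies about the tests: passing the variance-recovery check shows the
pipeline recovers *learnable* heteroscedasticity; it cannot show anything
about real data whose variability is unrelated to the measured descriptors.

Other honesty notes on the generator: spectra are sums of Gaussian peaks
plus white noise — no baselines, no peak shifts; images are smoothed noise
with composition-dependent grain, which LBP can distinguish but which looks
nothing like real SEM morphology; and measurements are exactly Gaussian, so
the normality assumption of the evaluation metric holds by construction.
`generate_null_dataset()` keeps all features but draws means and SDs
independently of them.

## Problem sizes used in the shipped checks

The test suite exercises the study-scale configuration — 38 materials, 100
sub-datasets, 5/10 folds — once, with a reduced two-method zoo
(ridge + random forest), and verifies: 1,000 fitted models and 100
estimates per material; Spearman correlation of at least 0.4 between the
ensemble spread and the true SDs; an oracle predictor (sampling from the
measured-fit Gaussians) scoring aggregate $D_{\mathrm{JS}} < 0.05$; and,
across ten seeded replicates at 10 sub-datasets each, the feature-only
combination A ranking worse on aggregate $D_{\mathrm{JS}}$ than each of the
spectra-bearing combinations B, C and E in at least eight replicates.
Smaller unit fixtures (14 materials, 3–6 sub-datasets) cover the
structural properties. `scripts/acceptance.R` re-runs the study-scale
ensemble from scratch and writes the resulting quantities as JSON.

## Known limitations

* Everything is evaluated under the Gaussian summary; multimodal or skewed
  predictive distributions are collapsed to (mean, SD) before scoring.
* The aggregate $D_{\mathrm{JS}}$ weights all materials equally, including
  those whose measured SD was substituted — for such materials the
  "measured" distribution is partly an artefact of the substitution rule.
* With few sub-datasets the predicted SD is itself noisy
  ($\chi^2_{N-1}$-scaled); at $N = 10$ rankings between close feature
  combinations can flip between seeds, which is why the shipped comparison
  uses ten replicates.
* The imputer assumes the feature table is approximately a Gaussian
  mixture; LBP histograms are compositional and only roughly so.
* PLS and LightGBM, sometimes used in this setting, are not in the zoo;
  ridge/elastic net and xgboost cover the same linear/boosted-tree ground.
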