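---
title: "Channel-augmented classical least squares for Raman calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel-augmented classical least squares for Raman calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(augCLS)
```

## The model and why it breaks

Classical least squares (CLS) calibration treats an observed spectrum as a
Beer–Lambert mixture: for L calibration samples over P wavenumber channels,

$$ A = C K + E, $$

with $A$ (L × P) the spectra, $C$ (L × M) the known component quantities, $K$
(M × P) the pure-component spectra, and $E$ noise. Fitting solves the
least-squares problem for $K$ given $C$ (`fitCLS()`), and prediction inverts
the fitted $K$ for a new spectrum (`predictCLS()`): both are rank-revealing
SVD solves rather than the textbook normal equations
$\hat K = (C^\top C)^{-1} C^\top A$ and
$\tilde C = A \tilde K^\top (\tilde K \tilde K^\top)^{-1}$, which are
numerically fragile for the long, smooth, nearly collinear matrices typical
of vibrational spectra. Spectra and concentrations are mean-centered around
the calibration set by default (`meanCenter()`), and predictions are mapped
back to original units.

The model's Achilles heel is its information requirement: *every* component
that contributes spectral variance must appear in $C$. A species nobody
measured, a drifting baseline, or a detector nonlinearity is projected onto
the components that are present and corrupts both $\hat K$ and the
predictions. The package calls the model with only the target analyte's
column `fitCLS1()` and the model with all known analytes `fitCLS2()`; the gap
between them on the same data measures the price of component information
loss.

## The augmentation defense

`fitACLS()` appends spectral channels to $C$ as pseudo-components:

1. **Channel screening** (`channelR2()`): the squared Pearson correlation of
   every channel's intensity with the target concentration. Channels with
   $R^2$ below a threshold (default 0.2) are driven mostly by what the model
   is missing, so their intensity columns are usable proxies for the missing
   component quantities.
2. **Region separation** (`rankCandidates()`): candidates are sorted by
   ascending $R^2$ and greedily thinned so that retained channels lie at
   least `minSpacing` (default 100 1/cm) apart. Neighbouring channels of a
   smooth spectrum are mutually correlated and would be redundant.
3. **Sizing by cross-validation** (`looRmsecvCurve()`): for every
   augmentation size m = 0..mMax the exhaustive leave-one-out RMSECV of the
   target is computed on the calibration set, refitting (and re-centering)
   per left-out sample.
4. **Elbow selection** (`chooseAugmentationSize()`): the chosen m maximizes
   the vertical drop of the curve below the chord joining its first and last
   points — a Kneedle-style elbow. Ties break toward the smaller size. If the
   curve value at the elbow is *worse* than at m = 0 (a low-m region where
   appended channels inject noise without absorbing structure), the choice
   falls back to 0 with a warning. An explicit `m` (for example a visually
   read elbow) bypasses the rule.

By default the base component matrix holds **all** known analyte columns
(`baseComponents = "all"`): the channels stand in for the *unknown*
remainder only. You never discard concentration information you actually
have; with `baseComponents = "target"` the channels must additionally proxy
the other known species, which is the setting of interest when only the
target's reference values exist but needs many more channels and a longer
RMSECV scan.

### Why prediction uses a minimum-norm solve

A channel appended to $C$ that happens to be orthogonal to every real
component column gets a numerically zero row in $\hat K$, making
$\tilde K \tilde K^\top$ exactly singular — yet the data contain everything
needed to predict the target. `predictCLS()` therefore returns the
minimum-norm least-squares solution (warning on rank deficiency, erroring
only when $K$ is numerically zero). This choice makes "harmless
augmentation" an invariant: appending concentration-orthogonal columns to a
noiseless, fully modeled calibration changes the target prediction by
nothing beyond floating-point noise.

A related subtlety: *omitting* a component whose concentration column is
orthogonal to the target's leaves the target's row of $\hat K$ unchanged,
but the prediction is only unchanged if the omitted *pure spectra* are also
orthogonal to the target's — the prediction step projects the full spectrum,
not just the target's share. The test suite asserts exactly this version.

## Baselines

* **CRACLS** (`fitCRACLS()`): starts from the all-analyte fit and
  iteratively appends the vector of calibration residuals (predicted minus
  reference target concentrations) as a pseudo-component. The residuals
  carry the part of the unmodeled variance that projects onto the target.
  Iteration stops on convergence, a rank-deficient append, an overfit guard,
  or `maxIter`; a step that worsens the calibration fit is rolled back, so
  the returned model is never worse than its starting point. With nothing
  unmodeled it reproduces the all-analyte CLS exactly.
* **PCR / PLS** (`fitPCR()`, `fitPLS()`): inverse models regressing the
  target on latent variables — principal-component scores for PCR, NIPALS
  covariance-maximizing latent variables with deflation for PLS (univariate
  target). One decomposition yields coefficient vectors for every component
  count. When `nComponents` is NULL the count is the smallest whose
  leave-one-out RMSECV lies within 2% of the curve minimum
  (`pickComponentCount()`), a parsimony rule that avoids chasing noise-level
  improvements. At full rank both collapse to ordinary least squares, which
  the tests verify against `lm.fit` and the PLS implementation against
  mixOmics.

## Validation protocol

`venetianBlinds()` assigns sample i to fold (i − 1) mod nFolds in
acquisition order; for smoothly varying batch processes this keeps
concentration coverage similar across folds. `compareModels()` fits every
method on the calibration fold, predicts the rest, and reports validation
R², RMSEP, calibration RMSECV, and — after sorting methods from worst to
best RMSEP — the one-way fixed-effects ANOVA p value (`anovaAbsErrors()`) of
each method's absolute errors against its predecessor. For two groups the F
statistic is exactly the squared pooled t statistic; identical groups return
F = 0, p = 1 rather than NaN.

## The synthetic generator, its realism and its limits

`benchmarkScenario()` registers four seeded study designs built on a
reaction-monitoring story: batches of a sequential first-order reaction
A → B → C (reactant / intermediate / product, labelled PA, ST, EB) observed
on a 230–3500 1/cm grid at 2 1/cm (1636 channels), 7 batches / 110 samples.
Concentrations follow the closed-form kinetics on an uneven time grid
$t_i = t_{max}((i-1)/(n-1))^{2.2}$ (dense early sampling, as a decelerating
reaction is monitored); per-batch lognormal jitter perturbs the rate
constants *and* the initial charge. The charge jitter matters beyond
realism: with a perfectly identical charge, mass conservation makes the
three analyte columns sum to a constant, so the centered component matrix is
exactly collinear and the all-analyte model unfittable. Perturbations are
applied in a fixed order — extra spectral components, per-sample quadratic
baseline drift, per-sample wavelength shift (sub-channel interpolation),
quadratic intensity nonlinearity $x \mapsto x - \beta x^2$, i.i.d. Gaussian
noise — and noise never touches the concentrations, which play the role of
trusted off-line reference measurements.

One generator lesson is worth recording because it shapes the scenarios: an
interferent's *concentration profile* decides whether it hurts. A profile
lying in (or near) the span of the analyte kinetic profiles — e.g. a
bell-shaped profile that resembles the intermediate, or a monotone ramp that
resembles cumulative conversion — is absorbed by the analyte columns at the
fitting stage and barely corrupts predictions, no matter how large its
spectrum. The registered scenarios therefore give interferents oscillating
profiles, which cannot be written as combinations of the smooth
monotone/unimodal kinetics and inject genuinely new concentration-space
variance. Consequently:

* `"paperlike"` — one mild oscillating spectral interferent, a weak
  intensity nonlinearity, and noise: the target-only model degrades by an
  order of magnitude against the all-analyte model, and augmentation
  recovers essentially all of it.
* `"clean"` — all perturbations off; exactness checks.
* `"two_interferents"` — two strong oscillating interferents with different
  cycle counts; the RMSECV curve needs at least two appended channels and
  drops several-fold at the elbow.
* `"demo"` — a small, fast variant for examples.

Limits worth stating plainly: peaks are ideal Gaussian/Lorentzian shapes
with no temperature or matrix effects; noise is homoscedastic; batches are
independent (no drift across batches); and the scenario constants were fixed
once, at the default seed, during design. The qualitative orderings
(target-only worst, augmentation ≈ inverse models, all-analyte exact when
nothing is unmodeled) are stable across seeds, but individual ratios move
with the seed, as they would across real measurement campaigns.

## A worked run

```{r example, eval = FALSE}
re <- generateDataset(benchmarkScenario("paperlike"))
split <- venetianBlinds(ncol(re))
cal <- re[, split == 0]

fit <- fitACLS(cal, "PA")
fit
plot(seq_along(rmsecvCurve(fit)) - 1L, rmsecvCurve(fit), type = "b",
     xlab = "appended channels m", ylab = "LOO RMSECV")

compareModels(re, "PA",
              c("cls1", "cls2", "cracls", "pcr", "pls", "acls"))
```

The comparison table reproduces the canonical pattern: the target-only model
sorts worst by a wide, statistically significant margin; the augmented model
sits with the inverse models at the noise floor; and the all-analyte model,
which in this synthetic world really does know every species, marks what is
achievable. On real data "all species" is exactly the information one
doesn't have — which is the point of augmenting.
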