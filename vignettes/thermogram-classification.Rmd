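---
title: "Classifying biofluid DSC thermograms with temperature-pair models"
author: "thermoTLB authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying biofluid DSC thermograms with temperature-pair models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoTLB)
```

## The measurement and the model

A biofluid DSC thermogram is the excess heat capacity $C_P(T)$ of a fluid
sample scanned over roughly 40–95 °C: an envelope of overlapping
denaturation transitions of the dissolved proteome. Disease shifts the
composition of the fluid, and with it the position and relative weight of
those transitions. The classification problem is to map one curve to a
binary diagnostic label using cohorts of only tens of samples.

Two properties of the data drive the design. First, absolute amplitude is
not trustworthy: it depends on total solute concentration, dilution and
instrument gain. Second, $n \ll p$ if the curve is used naively
(hundreds of grid values per sample). The pipeline addresses both with a
rank-based, heavily reduced representation:

$$\mathrm{score}(x) \;=\; \beta_0 + \sum_{k=1}^{K} \beta_k\,
  \mathbf{1}\!\left[x(T_{i_k}) > x(T_{j_k})\right],$$

where $x$ is the area-normalized curve and the pairs
$(T_{i_k}, T_{j_k})$ are chosen by the top-scoring-pairs (TSP) statistic.
A sample is called positive (higher-risk class) when its score is
strictly positive, negative otherwise — a score of exactly 0 deliberately
falls to the lower-risk call so that boundary cases do not create false
positives by fiat.

The assumptions are modest: class information must be visible in the
*ordering* of the normalized curve at a few integer-degree temperatures;
monotone per-sample distortions (scaling, moderate gain differences) are
tolerated by construction; smooth baseline differences are removed before
ordering is measured.

## Preprocessing

Each raw curve passes through four deterministic steps
(`prepareFeatures()`):

1. **Baseline correction** (`baselineCorrect()`): a straight line through
   the mean $(T, C_P)$ of a pre-transition window (default 40–45 °C) and a
   post-transition window (default 90–95 °C) is subtracted. The windows
   should bracket the transition region and contain only baseline signal.
   A linear chord is the minimal model that is exactly testable — a curve
   that *is* linear corrects to identically zero; whether instrument
   software applies additional curvature correction varies by lab, and no
   curvature model is attempted here.
2. **Interpolation** (`interpolateGrid()`): piecewise-linear resampling
   onto the uniform grid $40, 40.25, \dots, 95$ °C. Linear interpolation
   is monotone, parameter-free, and verifiable against a two-point
   oracle. Grid temperatures are generated by index arithmetic
   ($T_m = T_{\min} + m\,\Delta T$), never by accumulating the step, so
   the last point is exactly 95.
3. **Area normalization** (`areaNormalize()`): division by the
   trapezoidal integral over the full retained 40–95 °C span, *before*
   truncation to the feature window, so the features are tail-aware
   fractions of the whole denaturation signal. A non-positive area marks
   a failed thermogram and is an error, not a silent pass-through.
4. **Per-degree extraction** (`extractFeatures()`): the normalized curve
   is point-sampled at the 31 integer temperatures 55–85 °C. Point
   sampling (rather than per-degree averaging) is exactly reproducible
   and keeps the feature definition trivial to state. Both endpoints are
   included. The window is wider than the 60–80 °C sometimes used for
   serum because less cooperative fluids start unfolding earlier and
   finish later.

All grid parameters live in `GridSpec()` (units: °C) and flow through
`runConfig()`. Scale invariance — `prepareFeatures(c * x)` equal to
`prepareFeatures(x)` for any $c > 0$ — is enforced by tests to $10^{-9}$.

## Pair selection and the penalized fit

All $\binom{31}{2} = 465$ unordered temperature pairs are scored
(`ktspSelect()`); the grid is small enough that no pre-filtering is
justified. The primary score of a pair is the absolute difference of the
within-class frequencies of the ordering event, with strict inequality:
exact ties count as 0 on both sides, a convention that matters for
synthetic data where identical floats can occur. Each pair is stored in
the canonical direction (ordering event more frequent in the positive
class). Ties in the primary score are ordered by the absolute
between-class difference of the mean within-sample rank difference, then
lexicographically — the full ordering is deterministic. By default the
top `kMax = 10` temperature-disjoint pairs (standard kTSP semantics) are
passed on; disjointness is configurable because tied scientific usage
varies.

The indicators then enter an L1-penalized logistic regression
(`fitTSPModel()`, solved by glmnet's coordinate descent on the
unstandardized binary matrix):

$$\min_{\beta_0, \beta}\; \frac{1}{n}\sum_s \log\!\left(1 +
  e^{-y_s(\beta_0 + x_s^\top \beta)}\right) + \lambda \lVert \beta
  \rVert_1 .$$

The λ path holds 100 log-spaced values from $\lambda_{\max}$ (smallest λ
with an all-zero solution) down to $10^{-3}\lambda_{\max}$. Coefficients
are reported as the penalized solution itself — no post-selection refit —
and pairs shrunk exactly to zero are dropped, so the final model size
(often 1–3 pairs) emerges from shrinkage, not from `kMax`. Tests verify
the solution against a coarse-to-fine grid search of the objective (final
lattice step $10^{-3}$, agreement to $5 \times 10^{-3}$).

**Choosing λ.** `fitTSPModel()` defaults to stratified
$k = \min(10, \text{smallest class size})$-fold cross-validated deviance
with seeded fold assignment. The *pipeline* (`runConfig()`) defaults to
leave-one-out instead: at the cohort sizes this package targets (roughly
20–40 training samples), 10-fold CV puts 2–3 samples in each fold and the
deviance curve is dominated by fold noise; leave-one-out is the standard
small-sample choice, and it makes the entire training run deterministic
(no random fold assignment). Minimum-deviance selection is the default
rule; the 1-SE rule is available via `lambdaRule = "1se"`. Because pair
selection and λ selection see the same training data, some selection
optimism is unavoidable — training metrics are optimistic, and the
held-out (non-confirmed) samples are the honest yardstick.

Numerical details: glmnet runs with `thresh = 1e-9` on CV paths and
`1e-12` for fixed-λ fits; residual coefficients below $10^{-8}$ are
treated as exact zeros; on separable data the unpenalized end of the path
may not converge, in which case glmnet's truncated path is used and λ is
chosen among the returned knots. Constant indicator columns are dropped
with a warning; if nothing remains, the model is the intercept-only fit
at the class log-odds.

## Presets and evaluation

Two training presets mirror the two clinical questions the pipeline was
built around. `preset = "itlb1"` (non-mucinous vs mucinous) trains on
samples whose diagnosis is confirmed and keeps the high-probability
remainder as a validation set (`trainValidateSplit()`); `preset =
"itlb2"` (benign vs malignant mucinous) trains on every labeled sample,
the only defensible option when one class has fewer than ten members.

Evaluation (`confusionMetrics()`, `rocAUC()`, `wilcoxonRankSum()`)
follows diagnostic-test conventions. Ratios with a zero denominator are
reported as `NA`, never 0. Display values are rounded to whole percent;
internal values keep full precision. The AUC is the Mann–Whitney
normalization with ties counted ½, verified against brute-force
concordance counting; its 95% CI is a class-stratified percentile
bootstrap (2000 replicates, seeded) — assumption-light at $n \approx 20$
and naturally degenerate at (1, 1) for perfectly separated scores. No
analytic (DeLong-type) variance is attempted, and no claim is made that
the bootstrap reproduces any particular published interval. The Wilcoxon
comparison uses exact enumeration when the smaller group has ≤ 12
observations and no ties, otherwise the normal approximation with
tie-corrected variance and *no* continuity correction, so that identical
groups yield $p = 1$ exactly.

## What the synthetic generator does and does not emulate

`generateCohort()` builds each curve as a sum of Gaussian peaks plus a
linear baseline and white noise:

$$C_P(T) = \sum_m A_m f_m \exp\!\left(-\frac{(T - (T_{m} +
  \varepsilon_m))^2}{2\sigma_m^2}\right) + s\,(T - 40) + \eta(T),$$

with per-sample peak-position jitter $\varepsilon_m \sim N(0,
\sigma_{jit}^2)$, truncated-positive amplitude factors $f_m \sim N(1,
cv^2)$, and $\eta \sim N(0, \sigma_{noise}^2)$ i.i.d. per grid point. The
raw sampling step is 0.1 °C — deliberately different from the 0.25 °C
analysis grid so interpolation is always exercised.

Gaussians are a simplification: true excess-heat-capacity transitions are
asymmetric (two-state van't Hoff shapes skew toward lower temperatures)
and transitions interact. Gaussians were chosen because the pipeline is
rank-based and shape-agnostic while their means, areas and mixture maxima
stay analytically tractable for oracle tests. The generator also ignores
instrument artifacts (scan-rate dependence, feedback mode, re-scan
irreproducibility) and any correlation structure in the noise. Passing
tests on synthetic cohorts therefore demonstrate that the *algorithmic
chain* is correct and calibrated — not that the classifier performs at
any particular level on real cyst-fluid thermograms.

Default conditions (fixed once, used by tests and the acceptance script):
20 samples per class; 63% of each class flagged confirmed, matching the
typical share of pathologically confirmed diagnoses in cyst cohorts;
amplitude ~1 a.u. with noise SD 0.02 (a realistic signal-to-noise for
modern capillary DSC), position jitter 0.5 °C, baseline slope 0.002
a.u./°C. Three named recipes cover the study conditions: `"null"`
(identical classes — the no-signal control), `"shifted-peak"` (a single
transition moved 68 → 72 °C — the recovery benchmark), and `"envelope"`
(three transitions at 62/70/77 °C with class-dependent amplitude
redistribution — the realistic multi-transition shape).

## Calibration properties

Three properties are enforced by the test suite at fixed problem sizes,
chosen to finish in minutes on one CPU:

- **Null calibration**: across 25 seeded `"null"` cohorts, the held-out
  AUC lies in $[0.3, 0.7]$ for at least 80% of seeds. At a 7-vs-7
  validation split the null AUC of *any* non-degenerate score has SD
  ≈ 0.16, so this bound effectively requires the fitted models to
  collapse toward intercept-only under no signal — which is what the
  leave-one-out λ choice delivers.
- **Signal recovery**: on `"shifted-peak"` cohorts, training AUC ≥ 0.95
  and, in ≥ 90% of 50 seeds, the pair with the largest absolute
  coefficient straddles the shifted midpoint (one temperature on each
  side of 70 °C).
- **Dose response**: mean held-out AUC over 10 seeds is non-decreasing in
  the transition shift over $\{0, 1, 2, 4\}$ °C (measured at jitter
  1.5 °C and noise 0.05 so that intermediate shifts are neither trivial
  nor hopeless).

## Known limitations

- The linear-chord baseline cannot represent curved instrument baselines;
  strongly curved drift will leak into the features.
- Point sampling at integer degrees is sensitive to very narrow
  transitions (width ≪ 1 °C), which real biofluid envelopes do not show.
- With tens of samples, training metrics are optimistic (selection +
  shrinkage on the same data); only held-out or external validation
  numbers should be quoted.
- The bootstrap CI undercovers slightly at extreme AUCs short of 1; no
  correction (BCa or otherwise) is applied.
- CSV is the only interchange format; proprietary instrument exports must
  be converted upstream.
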