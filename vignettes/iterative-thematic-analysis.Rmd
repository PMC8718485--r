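---
title: "Iterative thematic analysis: model, design choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iterative thematic analysis: model, design choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(themelasso)
```

## The problem and the procedure

Large health surveys carry thousands of candidate correlates for a rare
binary outcome (here: any marital sexual violence in the past year,
weighted prevalence around 5.7%). A single sparse fit answers *which
columns* predict the outcome, but analysts usually want *which topics*
do — and the strongest topic tends to absorb all the model's attention,
masking weaker ones. Iterative thematic analysis addresses this by
alternating machine selection with human topic coding:

1. **Lasso pre-filter.** A survey-weighted L1-penalized logistic
   regression on the active features (training split only), with the
   penalty chosen by stratified 5-fold cross-validation maximizing the
   weighted validation AUC. Zero-coefficient features are dropped.
2. **Ridge ranking.** A survey-weighted L2 fit on the lasso support,
   again CV-tuned. Features are ranked by absolute coefficient;
   absolute value keeps protective (negative) associations in play.
3. **Evaluation.** Weighted AUC and balanced error rate
   (BER = 1 − (sensitivity + specificity)/2) on the held-out 20% test
   split. The classification threshold minimizes weighted BER on the
   *training* scores and is then frozen, so the test BER is leak-free.
4. **Knee-point selection.** The ranked coefficient curve is smoothed
   and the rank of maximal curvature
   $\kappa(r) = |f''(r)| / (1 + f'(r)^2)^{3/2}$ marks the knee;
   features at ranks $1..\text{knee}$ (inclusive) are selected.
5. **Theme coding and exclusion.** Selected variables are coded into
   themes (by humans via a resumable worksheet, or by the generator's
   ground truth in validation). A theme qualifies when it has at least
   2 selected members and at least 5% of the selected variables. The
   theme of the highest-ranked selected variable (walking down to the
   first variable with a qualified theme) is *dominant* and is
   excluded: every variable all of whose themes are now excluded
   leaves the active set; variables with a surviving membership stay.
   Newly surfacing variables whose themes were all excluded earlier
   are filtered out before the next round.
6. **Stopping.** The loop ends when the test AUC drops below 0.75,
   when no new theme has qualified for three consecutive rounds, when
   a round surfaces no previously unseen variable, or at a
   `max_rounds` guard (default 25).

The second strategy replaces steps 2–4 with a four-hidden-layer
feed-forward classifier on the lasso support; inputs are ranked by
*first-layer importance* — the sum of absolute weights connecting each
input to the first hidden layer — and the knee of that curve yields
the selection.

## Statistical model

Both penalized fits minimize the summed weighted negative Bernoulli
log-likelihood plus a penalty, with an unpenalized intercept:

$$\min_{\beta_0, \theta} \; \sum_i w_i \left[ -y_i \eta_i +
\log(1 + e^{\eta_i}) \right] + \lambda P(\theta), \qquad
\eta_i = \beta_0 + x_i^\top \theta,$$

with $P(\theta) = \lVert\theta\rVert_1$ (lasso) or
$\lVert\theta\rVert_2^2$ (ridge). $\lambda$ is reported on this
*summed-loss* scale (not the mean-loss scale some solvers use), so the
analytic critical penalty for the lasso is
$\lambda_{\max} = \max_j |\sum_i w_i x_{ij} (y_i - \bar y_w)|$; at or
above it the fitted solution is exactly the null model, which the
implementation returns in closed form. Survey weights enter the
likelihood, the CV selection metric, *and* the reported AUC/BER —
reporting nationally representative errors with unweighted metrics
would be inconsistent (unweighted variants are emitted alongside for
debugging). Integer weights are exactly equivalent to row replication,
which the test suite asserts to 1e-6 (fits) and 1e-12 (metrics).

## Tunable parameters

| Parameter | Default | Why |
|---|---|---|
| `train_fraction` | 0.8 | 80/20 stratified split, fixed once and reused by every round so AUC traces are comparable across iterations. |
| `k_folds` | 5 | Stratified by outcome; stratification protects folds at 5.7% prevalence. |
| `nlambda`, `lambda_min_ratio` | 50, 1e-4 | Log-spaced grid from $\lambda_{\max}$ down. CV ties break toward the stronger penalty. |
| `auc_floor` | 0.75 | Stopping rule (a). The 0.74/0.75 boundary is exercised in tests. |
| `theme_min_frac`, `min_theme_members` | 0.05, 2 | Qualification uses `ceiling(0.05 × |selected|)` with the ≥2 floor. |
| `support_tol` | 1e-10 | Coefficients below this count as zero when reading the lasso support. |
| `nn_config()` | (64, 32, 16, 8), ReLU | Only the layer *count* is fixed by design; widths, activation, epochs, batch size and optimizer settings are configuration. |

## Numerical and design choices

**Knee detection.** Discrete second differences of a raw ranked
coefficient vector are noise-dominated, so the curve is smoothed with
a cubic smoothing spline before curvature is evaluated. Two choices
matter and are deliberate:

* *Scale normalization.* Raw curvature is not invariant to the overall
  coefficient scale (multiplying all values by $c$ changes where
  $|f''|/(1+f'^2)^{3/2}$ peaks). Values are therefore rescaled to
  $[0,1]$ before fitting; knee ranks are then provably unchanged under
  positive rescaling.
* *Bandwidth.* The spline's smoothing is chosen by GCV but its
  effective degrees of freedom are capped at 6. A ranked, monotone
  coefficient curve has a single macroscopic bend; uncapped GCV
  interpolates noise-free curves and undersmooths empirical ones,
  letting rank-scale wiggles create spurious curvature maxima well
  inside the signal region. The cap was fixed by benchmarking against
  synthetic curves with known elbow locations and is validated against
  a discrete-curvature oracle (agreement within ±1 rank in ≥95/100
  random convex curves).

Ties in curvature go to the smallest rank; the knee rank itself is
included in the selection (the boundary is ambiguous in prose, so
inclusivity is fixed by convention). Curves shorter than 5, flat
curves, and exactly linear curves (maximal curvature below 1e-12 on
the normalized scale) have no knee; the engine records the error and
stops if it cannot select.

**Empty lasso support.** If CV prefers a penalty that zeroes
everything, the round's model is the intercept-only classifier:
constant scores, weighted AUC exactly 0.5. The normal stopping check
then applies — on signal-free data the loop therefore stops through
the AUC floor, which is the behavior the null-data validation asserts;
the empty support is additionally flagged in the round record.

**Dominant-theme rule.** The dominant theme is the theme of the
highest-ranked selected variable, walking down to the first variable
that belongs to any *qualified* theme. If that variable belongs to
several qualified themes, the tie breaks to the theme with more
selected members, then lexicographically. With a dual-membership
variable on top and equal member counts this can legitimately exclude
the lexicographically smaller theme first.

**Open choices resolved.** Where the procedure's description leaves
freedom, this implementation: re-tunes $\lambda$ by CV in every round
for both models (recorded per round); keeps one fixed train/test split
across rounds; resets the "no new themes" counter whenever a round
qualifies a previously unseen theme label; and adds the `max_rounds`
guard. All of these are surfaced in `ita_control()` output embedded in
every report.

**Neural-network training.** No multi-layer network package is
available in this stack, so the classifier is a direct implementation:
minibatch gradient descent with classical momentum (0.9) on the
weighted cross-entropy, early stopping on a stratified held-out fifth
of the training rows by weighted AUC, with the best-epoch weights
restored. Two choices serve the interpretability of first-layer
importance specifically: the optimizer is *non-adaptive* (an adaptive,
per-coordinate-normalized optimizer moves uninformative inputs'
weights as fast as informative ones, destroying the gradient-magnitude
signal that makes $\sum_u |W_1[j,u]|$ meaningful), and the first layer
is initialized near zero (SD 0.05) so its trained weight mass is
learned structure rather than He-initialization noise. Deeper layers
use He initialization. The importance aggregation over hidden units is
the sum of absolute weights (`"sum-abs-first-layer"`); an L2-norm
alternative is selectable for sensitivity analysis.

## What the synthetic generator emulates — and what it does not

`generate_population()` emulates the *shape* of a demographic-survey
violence module: tens of thousands of respondents; a mix of
continuous, binary and 5-level categorical variables one-hot-expanding
to roughly 500 columns; heterogeneous lognormal(0, 0.3) sampling
weights renormalized to mean 1; redundant representations (binned
categorical copies of continuous variables, which redundancy removal
must eliminate); three outcome item indicators whose any-vs-none
aggregate is the outcome; and a rare outcome whose expected weighted
prevalence is calibrated to 0.057 by root-finding the intercept.
Theme structure is planted through a Gaussian copula: members of a
theme share latent equicorrelation (0.3–0.35), binary variables
threshold the latent Gaussian, and each member contributes a signed
log-odds effect. The default three themes have well-separated mean
absolute effects (≈0.78, 0.50, 0.29), each containing a protective
effect, with one variable (`cont_09`) holding a dual membership to
exercise the retention rules.

It does **not** emulate: real skip patterns and structured
missingness, informative weighting (weights are independent of the
outcome), non-linear or interaction effects, inter-theme correlation,
or the semantics of human theme coding. Passing recovery tests
therefore shows the *pipeline* recovers planted structure under clean
conditions — not that any given survey's themes are equally
recoverable, and not that the human-coding step is reliable (coder
agreement is measured, not modeled).

## Validation experiments and problem sizes

The package validates itself at these scales (chosen as the study
conditions of the recovery experiments):

* **Recovery:** 20 seeds at n = 20 000, ~500 encoded features, three
  planted themes, prevalence 0.057. Asserted: the strongest theme is
  the round-1 dominant exclusion in ≥90% of seeds; the exclusion
  sequence follows the planted magnitude order in ≥80%; median
  round-1 above-knee recall of strong (|log-odds| ≥ 0.5) variables
  ≥0.8. These runs use a 30-value penalty grid down to
  $10^{-3}\lambda_{\max}$ — a resolution study for this problem size;
  the package-wide default grid is finer (50 values to $10^{-4}$).
* **Null behavior:** 20 signal-free seeds at the same scale must stop
  in round 1 through the AUC floor in ≥95%.
* **Neural variant:** on the recovery data, planted inputs must beat
  null inputs in first-layer importance (one-sided rank-sum p < 0.01)
  in ≥80% of seeds, and the selection must always be a rank prefix.
* **Solver oracles:** glmnet-backed fits are compared against an
  independently written FISTA proximal-gradient solver (≤1e-5 per
  coefficient) and a hand-rolled Newton MLE at λ = 0; the weighted AUC
  against O(n²) pair enumeration; the knee detector against discrete
  curvature.
* **Determinism:** identical config, seed and theme map reproduce
  byte-identical JSON reports; interrupted-and-resumed coding runs
  equal uninterrupted ones because every stochastic step derives its
  seed from the master seed and round number.

`scripts/acceptance.R` reruns the main computation end-to-end
(10 seeds per multi-seed experiment) and writes the headline numbers
as JSON.

## Known limitations

* Theme coding quality is an input, not an output: with a poor theme
  map the loop still runs but its exclusions are only as meaningful as
  the coding. `coder_agreement()` quantifies consistency between two
  coders; nothing reconciles them automatically.
* The knee is a single global bend by design; coefficient curves with
  two genuine plateaus will be cut at the stronger bend only.
* CV re-tuning per round means reported λ values are comparable across
  rounds only through the recorded total weight.
* The NN variant's importance is first-layer-only by definition;
  it will credit an input used exclusively through deep interactions
  less than a gradient-based attribution would.
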