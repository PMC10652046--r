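---
title: "Modelling a 2^5 inhibitor screen: linear, interaction and Bayesian-regularised network fits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a 2^5 inhibitor screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factorscreen)
```

## The experimental design and its encoding

The screen perturbs five signalling pathways in cultured pluripotent cells
with one small-molecule inhibitor each — U (U0126, Mek1), S (SU5402, Fgfr),
L (LY294002, Pi3k), R (rapamycin, mTor), P (PF-4708671, S6k) — in every
presence/absence combination: a two-level factorial with $2^5 = 32$
conditions. Emergent properties (cell number, proliferation, apoptosis) are
measured at days 2, 4 and 6; colony morphology is scored once, at day 6, on
a 0/1/2 scale per colony. Gene expression (a seven-gene panel) is profiled
at day 6 as log2 fold changes against the untreated reference after
normalisation to *Actb*.

Each condition is encoded as a one-hot vector: inhibitor column $x_j = 1$
when inhibitor $j$ is present. For responses pooled across days, day
indicators are appended. Three day indicators plus an intercept are
collinear, so the default policy keeps the intercept and drops the day-6
indicator (day 6 is the baseline); the all-indicator, no-intercept
parameterisation is available where the marginal day means are wanted
directly. This choice affects the parameterisation only, not fitted values
or model comparisons.

Conditions containing both L and R lose viability after day 2; their day-4
and day-6 rows are excluded from modelling (`apply_viability_mask()`),
leaving 24 modelled conditions on those days while all 32 contribute at
day 2. Replicates (3 by default) are averaged before modelling.

## Normalisation and transforms

* **Morphology**: per image, colony scores are summed and divided by the
  colony count; the condition score is the mean over images, bounded in
  $[0, 2]$.
* **qPCR**: efficiency-corrected $\Delta\Delta C_t$,
  $\log_2\mathrm{FC} = -\Delta\Delta C_t \cdot \log_2 E$, with $E = 2$ by
  default (classic assumption of perfect doubling); measured efficiencies in
  $(1, 2]$ are accepted.
* **Immunoblots**: band minus size-matched background, divided by the
  background-corrected loading control (beta-tubulin), expressed as log2
  fold change over the 0 h / untreated baseline ratio. A band darker than
  its background is clamped to $10^{-6} \times$ loading and flagged rather
  than returned negative.
* **Variance stabilisation**: apoptosis and morphology are log transformed,
  proliferation is raised to the sixth power, cell number is modelled
  untransformed. Because a fully naive condition scores exactly 0 for
  morphology, its log uses an offset, $\log(x + 0.1)$; the offset is a
  parameter and is recorded in the analysis report. Logs are natural: the
  base only rescales coefficients, leaving $R^2$, F-tests and significance
  unchanged. Normality is checked with Shapiro–Wilk (Royston's
  approximation, $3 \le n \le 5000$) before and after each transform, and
  again on model residuals; a failing residual check is reported as a
  warning, not an error, since the fit remains interpretable.
* **Octile binning** (`octile_bin()`) is an alternative rank-based
  normalisation into 8 equal-frequency bins for strongly non-normal
  responses. Ties take average ranks and are floored into bins — a
  deterministic rule chosen because equal values must land in the same bin.

## The model trio

**Main-effects MLR.** Ordinary least squares of the (transformed) response
on the inhibitor and day indicators. Coefficients carry the per-inhibitor
effect on the modelling scale; standard errors come from
$\hat\sigma^2 (X^\top X)^{-1}$.

**Two-way interaction MLR.** All $\binom{5}{2} = 10$ pairwise products of
inhibitor indicators are added and fitted jointly. A pair's interaction
term measures departure from additivity:

* not significant at $\alpha$ (default 0.05) → **additive**;
* significant, coefficient with the *same* sign as the summed main effects
  → **synergistic** (the combination overshoots the additive prediction in
  the direction the inhibitors already push);
* significant, *opposite* sign → **antagonistic** (the combination falls
  short of additivity).

The rule is stated in the output (coefficient, p-value, summed mains) so
every call is auditable. In the degenerate case of exactly zero summed main
effects the call follows the interaction coefficient's own sign. Raw
per-term significance is reported by default, matching the screen's
convention of reading individual terms at $P < 0.05$; Holm correction can
be applied downstream from the returned p-values. Note that under 0/1
indicator coding the product columns are not orthogonal to the main-effect
columns even in the balanced full factorial, so main-effect estimates
legitimately shift when interactions are added; they are invariant exactly
when the underlying response is additive.

After viability masking, day-6-only responses (morphology, genes) retain no
condition containing both L and R, so the L:R product column is identically
zero there. The fit drops such columns and lists them as *non-estimable*
rather than failing or silently reporting a meaningless coefficient.

**Nested F-test.** The interaction model is compared with the main-effects
model by
$F = \frac{(\mathrm{RSS}_r - \mathrm{RSS}_f) / (p_f - p_r)}
          {\mathrm{RSS}_f / (n - p_f)}$,
referred to $F(p_f - p_r,\, n - p_f)$: a small p-value says the ten extra
parameters buy a real reduction in residual variance.

**Bayesian-regularised network (BRANNGP).** A three-layer feed-forward
network — linear inputs, two sigmoidal (tanh) hidden units, linear output —
trained to the maximum of the marginal likelihood (evidence) under a single
Gaussian prior over all weights and biases. The objective is
$M(w) = \beta E_D + \alpha E_W$ with $E_D = \tfrac12\sum_i (t_i - y_i)^2$
and $E_W = \tfrac12\sum_j w_j^2$, minimised by Levenberg–Marquardt at fixed
$(\alpha, \beta)$; the outer loop re-estimates
$\gamma = k - \alpha\,\mathrm{tr}(H^{-1})$ with $H = \beta J^\top J +
\alpha I$, then $\alpha \leftarrow \gamma / 2E_W$ and
$\beta \leftarrow (n - \gamma)/2E_D$, iterating until the log-evidence
$-\alpha E_W - \beta E_D - \tfrac12\ln|H| + \tfrac{k}{2}\ln\alpha +
\tfrac{n}{2}\ln\beta - \tfrac{n}{2}\ln 2\pi$
is stationary. Because complexity is set by evidence maximisation, no
validation split is needed — important with at most 80 averaged rows.
$\gamma \in [0, k]$ is the effective number of well-determined weights and
replaces the raw parameter count in adjusted $R^2$
($1 - (1 - R^2)(n-1)/(n-1-\gamma)$), which is what makes network and linear
fits comparable on one scale.

Numerical choices: predictor columns are centred/scaled and the response is
standardised internally (predictions are un-standardised); weights are
initialised $\mathcal N(0, 1/\sqrt{\mathrm{fan\,in}})$ with
$\alpha_0 = 0.01$, $\beta_0 = 1$ on the standardised scale; $\ln|H|$ and
$\mathrm{tr}(H^{-1})$ use a Cholesky factorisation with a scaled
$10^{-9}$ jitter if $H$ is near-singular; biases are penalised in $E_W$
(simplest consistent prior; the effect is negligible after
standardisation); training keeps the best of 10 random restarts by final
log-evidence and is bit-for-bit reproducible given the seed. A restart
whose loss turns non-finite is discarded; training fails only if every
restart does. A single global $\alpha$ is the default — a Gaussian prior is
not sparsity-inducing, and the evidence framework's shrinkage is the
complexity control; no explicit pruning is applied.

Two degenerate configurations exist purely as cross-checks: a
linear-activation hidden layer (the network then spans exactly the OLS fit)
and `n_hidden = 0` with fixed $(\alpha, \beta)$ (the posterior mode is
ridge regression with penalty $\alpha/\beta$). The test suite holds the
trainer to both closed forms.

## Exploratory structure

The paired day-6 condition matrix (four properties + seven genes per viable
condition) feeds three unsupervised views:

* **Correlation matrix**: Pearson $r$ with p-values from the Spearman rank
  test — an unusual pairing, implemented literally because it is the
  screen's stated convention; Pearson-test p-values are one option away.
  Variables are ordered by average-linkage hierarchical clustering on
  $1 - r$ (the linkage is recorded in the output; the screen does not state
  one, and average linkage is the common default for correlation
  heatmaps). Constant variables give `NA`, never a fabricated 0.
* **PCA** on the z-scored matrix via SVD, deterministic up to sign, which
  is fixed by making each component's largest-magnitude loading positive.
* **k-means** with the silhouette score choosing $k$: the screen's
  "25 iterations" is read as the reference implementation's 25 random
  starts (best-of by within-cluster sum of squares), with Lloyd iterations
  run to convergence within each start; rows with missing variables are
  dropped with a logged count.

## The synthetic generator: what it emulates, and what it does not

The generator plants a known truth: per-property baselines, main effects
and day effects on the *modelling* scale, typed pairwise interactions,
Gaussian noise of stated SD, and a marginal law mapping the modelling scale
to the observed scale — `lognormal` for apoptosis and morphology (so the
log transforms are exactly the normalising ones) and a bounded-fraction law
for proliferation (so $x^6$ is). Lethal conditions generate no rows after
day 2, so generated data pass the viability mask unchanged. Gene panels add
correlated Gaussian noise with a target correlation matrix (Rex1–Oct4 0.8,
Dnmt3b–Fgf5 0.5 in the canned fixture) imposed through an eigen
factorisation. RNG sub-streams are derived per (property, condition, day),
so increasing the replicate count extends rows without perturbing existing
ones.

The canned fixture's planted interaction coefficients are set to about 3.6
standard errors of the corresponding term in the replicate-averaged, masked
design — per-term power ≈ 0.95 at 3 replicates, chosen once from the
design's closed-form SEs so that planted calls are recovered reliably
(≥ 90% across regenerations) while null pairs stay additive at the nominal
rate. Defaults: 3 replicates, noise SDs 0.08 (cell number, fold units),
0.03 (proliferation, transformed scale), 0.15 (apoptosis and morphology,
log scale), 0.4 (genes, log2 units).

What passing tests on this generator do **not** show about real screens:
real measurement error is not exactly Gaussian on the transformed scale,
real interactions are not confined to two-way products, plate/batch
structure and pipetting drift are absent, and gene–phenotype coupling here
is noise correlation plus shared mean structure rather than regulatory
dynamics. The generator validates the *machinery* — estimation, testing,
classification, clustering — not biological conclusions.

## Problem sizes and runtime choices

The packaged studies use sizes at which the statistical properties are
stable and a full run stays interactive: 500 simulated screens for the
type-I-error study (10 pairs each, exact binomial reference), 200 fixture
regenerations for interaction-call recovery, 100 runs for the
network-vs-linear comparison on nonlinear responses, and 50 random 80/20
splits for the stability profile. The acceptance script recomputes all of
these from scratch in about a minute.

## Known limitations

* With ~30 averaged observations, evidence maximisation occasionally
  retains structure in pure noise (a restart with $\gamma$ well above 0 can
  win the evidence comparison); across repeated draws the typical outcome
  is $\gamma \approx 0$ and an adjusted $R^2_\gamma$ near zero, and the
  tests assert exactly that distributional behaviour.
* Feature importances of the network are local (they depend on where the
  response surface is probed) and are not extracted.
* No three-way or higher interactions; no robust or weighted regression.
* The qPCR path implements the efficiency-corrected
  $\Delta\Delta C_t$ computation only; proprietary tool internals beyond
  that computation are out of scope.
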