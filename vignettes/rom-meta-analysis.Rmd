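---
title: "Ratio-of-means meta-analysis of a diagnostic biomarker: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratio-of-means meta-analysis of a diagnostic biomarker: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rommeta)
```

# The problem

Serum thyroid-stimulating hormone (TSH) — and positive biomarkers like it —
is measured on different assay platforms in different clinical studies, so
absolute differences in means are not comparable across studies. The
**ratio of means (RoM)**, the case-group mean divided by the control-group
mean, cancels assay scale: a study reporting in mU/L on one platform and a
study on another both contribute a dimensionless fold-change. `rommeta`
implements the complete quantitative-synthesis pipeline around that
measure for case/control comparisons of a positive continuous biomarker
(the motivating application is TSH in thyroid-cancer cases versus benign
thyroid-nodule controls): random-effects pooling, heterogeneity
exploration, small-study-effect diagnostics, category-count odds ratios,
and a cut-off-stratified diagnostic-accuracy arm.

# Effect measures

For a study with case mean $\bar x_1$ (SD $s_1$, $n_1$ subjects) and
control mean $\bar x_0$ (SD $s_0$, $n_0$), the analysis works on the log
scale:

$$y = \ln\frac{\bar x_1}{\bar x_0},\qquad
  v = \frac{s_1^2}{n_1 \bar x_1^2} + \frac{s_0^2}{n_0 \bar x_0^2}$$

with $v$ the first-order delta-method variance. All pooling arithmetic
stays on the log scale; exponentiation happens only at the reporting
boundary, which is why confidence intervals on the ratio scale are
asymmetric. Positivity of every mean and SD is enforced at the data
boundary — the ratio measure is undefined otherwise.

Studies reporting a median with range are converted by the standard
median/range rules: mean $(a + 2m + b)/4$; SD
$\sqrt{((a-2m+b)^2/4 + (b-a)^2)/12}$ for $n \le 15$, $(b-a)/4$ for
$15 < n \le 70$, $(b-a)/6$ for $n > 70$. The source of the rules does not
say whether the band boundaries are inclusive; this package closes each
band on the left ($n = 15$ uses the small-sample formula, $n = 70$ the
middle one) and treats a degenerate range ($a = b$) as an error, since it
would imply a zero SD. Only the full-range conversion is implemented;
interquartile-range summaries are out of scope.

Category counts (subjects tabulated into biomarker ranges) collapse to
2×2 tables over half-open $[{\rm low}, {\rm high})$ ranges whose endpoints
must align with the study's own bin edges, and feed a log odds ratio
$y = \ln(ad/bc)$, $v = 1/a + 1/b + 1/c + 1/d$, with a continuity
correction of $0.5$ added to every cell *only* when some cell is zero —
not unconditionally, so fully populated tables are untouched.

# Pooling and heterogeneity

Fixed-effect weights are $w_i = 1/v_i$; Cochran's
$Q = \sum w_i (y_i - \bar y_F)^2$ on $k - 1$ df and
$I^2 = \max(0, (Q - df)/Q)$ summarise heterogeneity. The random-effects
model is DerSimonian–Laird:

$$\hat\tau^2 = \max\!\left(0,\ \frac{Q - (k-1)}{\sum w_i - \sum w_i^2 / \sum w_i}\right),
\qquad w_i^* = \frac{1}{v_i + \hat\tau^2}.$$

Truncation at zero is explicit, so $Q \le k-1$ makes the random-effects
result coincide with the fixed-effect one exactly — asserted in the test
suite. Confidence intervals use the normal quantile (no Knapp–Hartung
adjustment), matching the z-based P values the pipeline reports
throughout. $P(Q)$ comes from the $\chi^2_{k-1}$ distribution. A single
study is returned as itself with $\tau^2 = 0$.

Subgroup analysis pools each level of a stratification factor
independently; records with a missing level form an explicit `"unknown"`
stratum so no study silently disappears. Two pooled results are contrasted
with a two-sample z-test on the log scale,
$z = (y_a - y_b)/\sqrt{se_a^2 + se_b^2}$. A between-group Q-test is a
known alternative; the z contrast was chosen because the pipeline's
two-level clinical comparisons (tumour size, stage, node status) are
pairwise by construction, and for two groups the two are equivalent
($Q_{between} = z^2$). Leave-one-out sensitivity analysis re-pools after
each omission and requires $k \ge 3$ so that every re-pool still has two
studies.

# Meta-regression

Effect modifiers are screened with a random-effects meta-regression
$y_i = x_i'\beta + u_i + \epsilon_i$, $u_i \sim N(0, \tau^2)$,
$\epsilon_i \sim N(0, v_i)$, with $\tau^2$ estimated by **REML** — note
this deliberately differs from the DL moment estimator used for pooling,
so an intercept-only meta-regression will not numerically equal the DL
pooled estimate. The restricted likelihood is maximised by a bounded
one-dimensional search on $\tau^2$ (tolerance $10^{-8}$), with an explicit
check of the $\tau^2 = 0$ boundary because a bounded interior search can
miss it. Tests verify the profile maximum against a dense independent
grid ($\tau^2 \in [0, 5]$, step $10^{-3}$) and the weighted-least-squares
step against direct matrix algebra.

Covariate coding: `size_class` is coded as an ordered index
(small/moderate/large = 0/1/2) — a scalar coding that yields one
coefficient per factor, which is how sample-size effects are conventionally
reported; other categorical covariates get treatment contrasts against the
alphabetically first level. The coding actually used is returned in
`covariate_coding`. Moderators are tested singly by default (joint models
behind `joint = TRUE`), because screening candidates one at a time is the
standard heterogeneity-exploration design and keeps $k \ge p + 2$
satisfiable in small corpora. Raw sample size can be supplied as a numeric
covariate where the class index is too coarse.

# Small-study effects and heterogeneity diagnostics

The **Egger test** regresses the standardized effect $y_i/se_i$ on
precision $1/se_i$ by ordinary least squares and t-tests the intercept on
$k-2$ df. This parameterization is algebraically identical to the weighted
regression of $y_i$ on $se_i$; the equivalence is asserted against an
independent implementation in the tests. The **Begg–Mazumdar test**
correlates the standardized deviates $(y_i - \bar y_F)/\sqrt{v_i - 1/\sum w}$
with the variances using Kendall's tau (tie-corrected denominator). Its
p-value is exact — full enumeration over permutations — for $k \le 8$, and
a tie- and continuity-corrected normal approximation beyond, where
enumeration stops being worthwhile.

Funnel coordinates carry pseudo-confidence guide lines
$\bar y \pm z_{1-\alpha/2} se$ from $se = 0$ to the largest observed
standard error. The Galbraith (radial) plot fits the no-intercept weighted
line $\hat b = \sum x_i z_i / \sum x_i^2$ — identically the fixed-effect
estimate — and flags studies whose residual exceeds 2 in absolute value,
the conventional band; the inequality is strict, so a residual of exactly
2 is not flagged. Under strong heterogeneity most studies can exceed the
band: the flag marks heterogeneity contributors, not data errors.

# Diagnostic-accuracy arm

Studies reporting 2×2 counts (TP/FP/FN/TN) at a biomarker cut-off are
grouped into named cut-off bands (< 0.5, 0.5–1.5, 1.5–2.5, > 3.5 mU/L).
Cut-offs in the gap (2.5, 3.5] belong to no named band and are rejected
with a warning rather than silently assigned. Sensitivity and specificity
are pooled on the **logit** scale with the same DL engine and
back-transformed; whether to pool on the raw or logit scale is a genuine
choice — logit was selected for its unbounded support and
variance-stabilising behaviour near 0 and 1, and is a potential source of
numeric discrepancy with raw-scale implementations. Likelihood ratios
(PLR $= sens/(1-spec)$, NLR $= (1-sens)/spec$) are pooled on the log scale
with delta-method variances. The clinical-utility quadrant uses strict
thresholds: a clinically useful test needs PLR $> 10$ *and* NLR $< 0.1$.

The summary ROC is the Moses–Littenberg construction: per study
$D = \mathrm{logit}(TPR) - \mathrm{logit}(FPR)$ (the log diagnostic odds
ratio) and $S = \mathrm{logit}(TPR) + \mathrm{logit}(FPR)$ (a threshold
proxy); the line $D = a + bS$ is fitted unweighted (the classical default;
inverse-variance weighting of $D$ is available behind `weighted = TRUE`),
giving the curve

$$TPR(FPR) = \mathrm{expit}\!\left(\frac{a + (1+b)\,\mathrm{logit}(FPR)}{1-b}\right),$$

which runs from $(0,0)$ to $(1,1)$ whenever $|b| < 1$. The area (AUSROC)
is computed by adaptive quadrature over the *full* FPR domain $(0,1)$ —
one area per band, with restriction to the observed FPR range available as
an option. When $|\hat b| \ge 1$ the back-transform is non-monotone: the
coefficients are reported and the area is marked undefined rather than
integrating a meaningless curve. The AUSROC confidence interval is a
seeded nonparametric bootstrap over studies (percentile method, 2000
resamples by default), since no analytic CI exists for this construction.
Zero cells receive the 0.5 correction per study before both pooling and
the SROC fit. The bivariate random-effects (Reitsma/HSROC) model is a
deliberate non-goal; Moses–Littenberg is the construction implemented.

# The synthetic-data generator

`simulate_rom_studies()` draws, per study, a true log ratio
$\theta_i = \mu + \tau u_i$, a control-arm mean from a lognormal
distribution across studies, and individual biomarker values from a
lognormal (optionally gamma) distribution within arms — lognormal because
TSH-like biomarkers are strictly positive and right-skewed. Observed
means and SDs are *sample* statistics of the drawn values, not plugged-in
truths, so the delta-method variance faces genuine sampling noise; and
category counts are tabulations of the same draws, so the ratio-of-means
arm and the odds-ratio arm of a simulated corpus are internally consistent
by construction. The `small_study_effect` knob inflates each study's
observed case mean by $\exp(s \cdot \widehat{se}_i)$ — bias proportional
to imprecision, the signature the Egger test is built to detect; it acts
on the summary statistics only, not on the tabulated counts.

Generator defaults describe the emulated literature: $k = 56$ studies,
true ratio 1.44, $\tau = 0.3$ (substantial heterogeneity, $I^2$ well above
90% — characteristic of assay-heterogeneous biomarker corpora), control
means centred at 1.5 mU/L with 35% spread, within-study CV 0.8, case
counts 30–800 and control counts 50–2000 so the small/moderate/large
bands are all populated. `simulate_diagnostic_studies()` draws study-level
(logit sens, logit spec) from a bivariate normal — default means at
sens 0.75/spec 0.80, SD 0.4, correlation −0.3 to mimic threshold
trade-off — and binomial cell counts.

What the generator does *not* emulate: reporting heterogeneity (it never
emits median/range summaries), correlated covariates, non-lognormal
contamination, or selective publication beyond the single
`small_study_effect` mechanism. Passing recovery tests on these
simulations therefore validates the estimators under the model's own
assumptions; it does not certify behaviour on real literatures that
violate them.

All randomness flows from the single `seed` in the config; the same seed
reproduces tables byte-for-byte, and emitted CSVs record the seed in a
header comment.

# Validation design and problem sizes

The test suite checks every estimator against an independent oracle on
toy inputs — direct-summation pooling, closed-form normal equations for
Egger, full permutation enumeration for Begg, a dense $\tau^2$ grid for
REML, adaptive quadrature for the AUSROC — at tolerance $10^{-10}$ where
the arithmetic is exact, and against `metafor` as an external
cross-check. Simulation-based checks use: $k = 200$ studies for
ratio-and-$\tau^2$ recovery (within 2 pooled SEs and 30% relative error
respectively); 2000 replicates at $k = 30$, $\tau = 0$, arm sizes 50–300
for the Egger type-I rate (expected in $[0.03, 0.08]$ — the homogeneous
null, since heterogeneity is known to distort the test's size); and
$k = 100$ diagnostic studies for accuracy recovery and the chance-line
area. These sizes give the checks Monte-Carlo resolution well below the
tolerances they assert.

# Worked example

```{r example}
sim <- simulate_rom_studies(rom_sim_config(k = 30, seed = 11))
est <- log_rom(sim$studies)
pool_dl(est)
egger_test(est)
by_eth <- subgroup_pool(sim$studies, "ethnicity")
sapply(by_eth, function(r) round(r$est_pooled, 3))
```

# Known limitations

* The DL $\tau^2$ estimator is moment-based; REML appears only in
  meta-regression (by design, not omission).
* Moses–Littenberg regression is known to be biased at extreme
  sensitivities/specificities and ignores within-study correlation; it is
  retained as the implemented construction, with the bivariate model noted
  as an extension.
* The Egger test's size is only near-nominal under homogeneity; with
  $\tau^2 > 0$ its rejection rate under the null inflates, as the
  diagnostics literature documents.
* Subgroup contrasts are unadjusted pairwise z-tests; no multiplicity
  correction is applied across the factor levels or factors.
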