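---
title: "Trait-based meta-analysis of linear-infrastructure effects: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-based meta-analysis of linear-infrastructure effects: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iezmeta)
```

## The problem

Roads, power lines and other linear infrastructure alter wildlife abundance
well beyond their physical footprint. Field studies report paired abundance
records — a site near the infrastructure and a more distant control — for
particular species, distances and habitats. Synthesizing hundreds of such
comparisons across mammals, birds, reptiles and amphibians requires (i) an
effect size that survives the pathologies of abundance data (zero counts,
missing variances, shared controls), (ii) a multilevel meta-regression that
respects the nested source/study/species structure and known sampling
covariance, and (iii) a derived quantity practitioners can use: the
infrastructure-effect zone (IEZ), the distance at which the modelled
response returns to zero.

`iezmeta` implements this workflow end to end, together with a
synthetic-data generator with known truth so that every stage is testable
without the original field database.

## Effect sizes

For a comparison with disturbed-site sample mean $\bar A_d$ (SD $SD_d$,
sample size $n_d$) and control $\bar A_c$ ($SD_c$, $n_c$), the effect size
is the log response ratio with a second-order small-sample (delta)
correction:

$$\mathrm{LRR}^{\Delta} = \log\frac{\tilde A_d}{\tilde A_c}
 + \frac{1}{2}\left[\frac{SD_d^2}{n_d \tilde A_d^2}
 - \frac{SD_c^2}{n_c \tilde A_c^2}\right],$$

with sampling variance

$$\mathrm{VAR}(\mathrm{LRR}^{\Delta}) =
 \frac{SD_d^2}{n_d \tilde A_d^2} + \frac{SD_c^2}{n_c \tilde A_c^2}
 + \frac{1}{2}\left[\frac{SD_d^4}{n_d^2 \tilde A_d^4}
 + \frac{SD_c^4}{n_c^2 \tilde A_c^4}\right].$$

Zero sample means (roughly a fifth to a quarter of field comparisons) make
the raw ratio undefined, so means enter as truncated means
$\tilde A = \bar A$ if $\bar A > 0$, else $1/(2 n D)$, where $D$ is the
reporting-scale constant (e.g. trap nights). Both the ratio and the
correction terms use $\tilde A$; the substitution only matters where
$\bar A = 0$, where the printed form of the estimator is unusable anyway.

Comparisons at different distances within the same study and species divide
by the *same* control observation. The induced sampling covariance is the
control's first-order variance contribution $SD_c^2/(n_c \tilde A_c^2)$,
assembled into a full variance–covariance matrix. Sharing is identified by
equality of the control columns within study and species, which is exactly
what "one control observation" means in the flat one-row-per-comparison
schema. The second-order delta term of the shared control is *not* added to
the covariance: the covariance construction for shared-control designs is a
first-order result, and including fourth-moment terms off-diagonal without
the matching cross-moments can break positive semidefiniteness. The
diagonal keeps the full second-order variance.

Missing (or reported-zero) SDs are imputed before effect sizes are
computed. The default assumes Poisson-like dispersion, $SD = \sqrt{\tilde
A}$; two alternatives support robustness checks: the Bracken ratio method
(scale each incomplete mean by the pooled SD-to-mean ratio of complete
cases) and hot-deck nearest-neighbour draws from the `k = 5` complete cases
closest in truncated mean, restricted to the same taxon so abundance
metrics stay comparable (ties broken by record order; the value of `k` and
the pool restriction are this package's choices, as is treating a reported
zero SD as missing). Hot-deck imputation is repeated (default 100 completed
data sets) and downstream model estimates are summarized by their median
and 2.5/97.5 percentiles across completed sets — a comparison of
per-imputation estimates rather than Rubin pooling, matching how such
robustness checks are usually reported in this literature. Because the
control observation is shared, its SD is drawn once per control group, not
once per row; per-row draws would make the covariance matrix inconsistent
(and indefinite).

A small-sample-mean screen is available for sensitivity analyses: an arm
passes Geary's rule when $(\tilde A/SD)\cdot 4n^{3/2}/(1+4n) \ge 3$, and a
comparison is retained when both arms pass.

## The multilevel model

Effect sizes are modelled as

$$y \sim \mathcal N(X\beta,\; M), \qquad
  M = V + \sum_{k=1}^{5} \sigma_k^2 Z_k Z_k^\top,$$

where $V$ is the known sampling variance–covariance matrix and the five
components are observation, clade (order for mammals and birds, family for
reptiles and amphibians — there are too few herptile orders for a usable
grouping, and body mass varies widely within them), species nested in
clade, data source, and study nested in source.

Moderators enter $X$ with treatment contrasts (habitat reference `closed`,
infrastructure reference `non_traffic`; power lines are a separate level
for birds only, reflecting collision mortality, and fold into non-traffic
for other taxa). Continuous moderators are deliberately uncentered:
distance as $\log_{10}$ metres, body mass as $\log_{10}$ grams, diet as raw
percent. Uncentered coding makes the intercept the prediction "at 1 m" for
a non-carnivorous, 1 g, closed-habitat, non-traffic reference — which is
how the published coefficient tables are arithmetic-checked and how the
bundled reference models reproduce the printed percentages. Distances below
1 m (field data do contain 0 m records) are clamped to 1 m so the transform
is 0 at the edge; an additive offset (`log10(d + 1)`) would shift every
prediction and break the "at 1 m = intercept" identity.

### Estimation

Variance components maximize the restricted log-likelihood

$$\ell_R(\sigma^2) = -\tfrac12\left[(n-p)\log 2\pi + \log|M|
 + \log|X^\top M^{-1} X| + r^\top M^{-1} r\right]$$

by bounded quasi-Newton (`L-BFGS-B`) on $\log\sigma_k^2$ with analytic
gradients and three starts: near-zero ($10^{-4}$), a method-of-moments
heuristic from the $Q_E$ excess, and `var(y)`. Components at the boundary
are common in these data and a single start can stall on a ridge (nested
factors are partially confounded), hence the multi-start. The best start
wins; relative convergence tolerance is about $10^{-8}$
(`factr = 1e7`). Fixed effects are generalized least squares at the
estimates, $\hat\beta = (X^\top M^{-1}X)^{-1}X^\top M^{-1}y$, with Wald
(normal) 95% intervals — the published tables print symmetric intervals and
no small-sample adjustment, so none is applied. Sampling variances below
$10^{-8}$ (possible only for degenerate inputs) are floored with a warning.

In cross-checks against `metafor::rma.mv` the engine agrees exactly on
identifiable structures (coefficients, components and restricted
log-likelihood up to the constant $\tfrac12\log|X^\top X|$ convention), and
on harder instances its multi-start optimum is at least as good.

### Fit statistics and tests

* **$Q_E$** — residual heterogeneity: $(y - X\hat\beta_V)^\top V^{-1}(y -
  X\hat\beta_V)$ at the fixed-effects (V-weighted) solution, chi-square
  with $n - p$ df. The fixed-effects form is used (rather than evaluating
  at the multilevel fit) so that the statistic has its exact reference
  distribution under homogeneity.
* **$Q_M$** — Wald chi-square on a coefficient subset. Term-level tests
  drop a main effect's interactions (refitting the reduced model) before
  testing the main effect; distance interactions are tested jointly with
  their quadratic companions.
* **AICc** — $-2\ell_F + 2k + 2k(k+1)/(n-k-1)$ with the *full*
  (unrestricted) likelihood evaluated at the REML estimates and $k$
  counting fixed effects **plus** free variance components. Counting the
  variance parameters is the defensible reading of a full-likelihood
  information criterion for mixed models; whether a given reference
  implementation counts them is rarely stated, and the choice only shifts
  every candidate's AICc by a constant when the random structure is held
  fixed — which it is, so selection is unaffected.
* **$R^2$** — marginal and conditional, with the typical sampling variance
  $s^2 = (n-1)\sum w_i / ((\sum w_i)^2 - \sum w_i^2)$, $w_i = 1/V_{ii}$
  (the Higgins–Thompson form; the exact "typical variance" used by any
  given published analysis is usually unstated, and alternatives move
  $R^2$ by little).
* **Profile likelihood** — each component is profiled on a grid with the
  others re-optimized; a component is identifiable when the profile has a
  unique interior maximum and drops by at least 1.92 units (the
  $\chi^2_1/2$ cutoff) on each side the grid covers. Duplicated grouping
  factors produce the expected flat/ridged profile and are flagged.
* **Egger test** — classic funnel-asymmetry regression on the
  meta-analytic residuals: standardized residuals $(y_i -
  x_i^\top\hat\beta)/\sqrt{V_{ii}}$ regressed on precision
  $1/\sqrt{V_{ii}}$ by OLS, intercept t-test. Standardizing makes the
  errors homoscedastic; regressing raw residuals on precision is
  conservative and nearly blind to small-study censoring, which the
  calibration tests demonstrate.

Model selection fits every candidate moderator structure by REML with the
same data and random effects and ranks by AICc (ties within $10^{-6}$ go to
fewer parameters; non-converged candidates are dropped with a warning).
Comparing fixed-effects structures under REML draws a textbook caveat; it
is retained deliberately because the full-likelihood AICc is what the
workflow this package reimplements prescribes, and a maximum-likelihood
switch is not offered to avoid presenting two selection paths as
equivalent. Candidate enumeration respects marginality: interactions
require their main effects, `distance2` requires `distance`, and
`distance2:Z` requires `distance:Z`.

## Infrastructure-effect zones

For fixed moderators, the fitted surface is at most quadratic in $x =
\log_{10}$ distance, so the IEZ — the smallest distance in $[1\,\mathrm m,
d_{\max}]$ at which the prediction crosses zero — comes from closed-form
roots (verified in tests against a dense 10,000-point sign scan). The sign
of the prediction at 1 m is reported alongside (`+` means higher abundance
near the infrastructure, within the zone). The zone is *undefined* when the
prediction never crosses zero within `d_max`, e.g. a response that does not
recover with distance (the non-carnivorous-bird case in closed habitat);
tangency without a sign change does not count as a crossing. `d_max`
defaults to 100 km — far beyond any observed distance (max 4.5 km), so the
default never truncates a biologically meaningful zone. If the prediction
is exactly zero at 1 m the zone is 1 m with the sign taken from the slope.

Confidence bounds are the first crossings of the pointwise 95% CI envelope:
the envelope side that crosses earlier gives the lower bound (0 when that
side already brackets zero at 1 m) and the other side the upper bound
(unbounded, reported as `Inf`, when it never crosses). The envelope method
reproduces the one-sided/unbounded interval patterns seen in published IEZ
tables; it is this package's choice, since IEZ interval methods are
essentially never spelled out.

Two caveats on the bundled reference coefficients (`reference_models()`):
they are printed to two decimals with no covariance, so reference-model CI
envelopes use a diagonal covariance (point IEZs and percentages are
unaffected); and the two-decimal amphibian quadratic has no real root, so
the amphibian reference zone (about 27 m at full precision) is undefined
here — a rounding artifact the package reports honestly rather than
papering over.

## The synthetic-data generator

`simulate_dataset()` emulates the structure of the field database: sources
containing 1–3 studies, studies containing 1–4 species from a clade pool,
2–5 disturbed distances per study–species drawn log-uniformly on
$[1, 4500]$ m (rounded to the metre, so true 0–1 m records appear as edge
distances), one shared control observation per study–species, lognormal
control abundances, and traits (log-uniform body mass over the taxon's
observed range; diet zero-inflated with a Beta tail). Each record's true
response is its design row times `true_beta` plus the five Gaussian random
effects. Observed arm means are Normal around the true mean with SD
$CV \cdot \mathrm{mean}/\sqrt n$, censored at zero — censoring is what
produces genuine zero means; sample SDs follow the scaled chi-square law;
SDs are withheld at a configured rate. A count-based mode was considered
and rejected: the field data span densities, rates and indices, not just
counts, and the censored-Normal model matches that heterogeneity of metrics
with one mechanism.

The per-arm zero probability is $\Phi(-\sqrt n / CV)$, independent of the
mean level, so the generator calibrates the mean coefficient of variation
by solving for the target zero rate over the replicate-count and CV
distributions (`zero_rate_target`). The taxon presets mirror the published
strata — record counts (mammals 863, birds 2471, reptiles 362, amphibians
216 at `scale = 1`), zero-mean rates (20/19/20/26%), SD-missingness
(22/63/26/54%), observed body-mass ranges, the reference coefficients as
truth, and no open-habitat amphibian records.

What the generator does *not* emulate: genuine count processes (zeros enter
by censoring, not discreteness), spatial autocorrelation within studies,
publication bias (added explicitly in the Egger power check), digitization
error, and correlation between traits and sampling design. Passing
recovery tests therefore demonstrates the estimator handles the declared
hierarchy, covariance and missingness — not every pathology of real field
data.

## Problem sizes used by the checks

The packaged checks run at sizes chosen to make Monte-Carlo error small
relative to the tolerances while staying desk-scale: null calibration of
$Q_E$, $Q_M$ and the Egger intercept uses 1000 replicates at $n = 30$
(acceptance band 0.03–0.08 at $\alpha = 0.05$); Egger power uses 200
replicates with absolute-threshold censoring; parameter recovery uses 200
replicates of roughly 350–400 effect sizes with coefficients on the scale
of the published mammal model and moderate heterogeneity
($\sigma^2$ = 0.3/0.05/0.3/0.2/0.05). The recovery configuration uses
complete SDs and a near-zero truncation rate so that it measures the
estimator rather than Poisson-imputation misspecification; with the
presets' missingness the observation-level component absorbs imputation
error by design, which the robustness stage (not the recovery test) is the
place to see. The analysis drivers under `analysis/` default to 30% of the
full database scale; `taxon_preset(tx, scale = 1)` reproduces full-scale
strata.

## Known limitations

* Reference-model CI envelopes use a diagonal coefficient covariance
  (printed tables carry no covariances); point estimates are unaffected.
* Wald intervals and tests, no Knapp–Hartung small-sample adjustment and
  no cluster bootstrap or robust (sandwich) variances.
* Whether Geary's screen should use imputed SDs for originally-missing
  values is ambiguous in the literature; `geary_subset()` screens whatever
  SDs the records carry at call time, so callers choose by ordering the
  imputation step before or after.
* No phylogenetic correlation beyond the clade/species hierarchy, and no
  spline distance responses — the quadratic-in-log10 family is a modelling
  commitment inherited from the workflow this package reimplements.
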