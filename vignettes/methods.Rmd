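---
title: "Synthetic-control evaluation of staggered primary-care interventions: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic-control evaluation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scmeval)
```

## Scope

`scmeval` estimates the causal effect of an organisational intervention
(the motivating case is vertical integration of GP practices with an acute
hospital) on three monthly unplanned-care outcomes — ED attendances,
unplanned admissions and unplanned readmissions, all as rates per 100
registered patients per month — using one synthetic control per treated
practice, placebo-based inference, inverse-variance pooling across
practices, and reference-cost arithmetic. This vignette documents the
models, the defaults and why they were chosen, the numerical choices, and
the limitations.

## The synthetic control model

For treated practice $j$ joining at month $T_j$, the counterfactual is a
convex combination of donor practices. With $X_1$ the treated predictor
vector and $X_0$ the matching donor matrix, the donor weights solve the
inner problem

$$\min_{W \ge 0,\ \sum W = 1}\ (X_1 - X_0 W)^\top \mathrm{diag}(V)\,(X_1 - X_0 W),$$

an exact convex quadratic programme solved by the dual active-set method
(`quadprog`), with a relative ridge of $10^{-8}$ on the Hessian diagonal so
the programme stays positive definite when donors outnumber predictor rows.

The predictor block stacks (a) the pre-period means of the covariates
(staffing counts, list size, demographic bands, deprivation, prevalence
markers, emergency length of stay) over (b) the full monthly pre-period
paths of all three outcomes, so one fit serves all outcomes jointly. Each
predictor row is divided by its donor-pool standard deviation by default
(`standardize = TRUE`); without this, rows measured in large units (list
size) dominate the quadratic form for scale reasons alone. Rows with zero
donor variance carry no matching information and are dropped with a
warning; an outcome whose entire pre-period path has no donor variance is
an error, since the fit criterion would be vacuous.

The diagonal predictor-importance weights $V$ are chosen by an outer search
minimising the pre-period outcome mean squared prediction error (MSPE) of
$W(V)$ — the conventional dependent-variable criterion, computed on the raw
(unstandardized) outcome paths. The outer search evaluates:

* the **equal-V** solution (always a candidate, so the fitted objective is
  never worse than that baseline);
* the **outcome-only-V** solution, with weight proportional to the squared
  row scaling on the outcome rows and zero on covariates. By construction
  this makes the inner QP minimise the raw outcome MSPE directly, so the
  nested optimum is never worse than a pure outcome-path fit. This
  candidate is what makes the outer search reliable: derivative-free search
  alone can stall in the flat softmax landscape, and dependent-variable-only
  matching is a standard, well-understood variant of the method;
* Nelder–Mead refinements in softmax coordinates from the equal-V start,
  the outcome-only start and `multistarts` random starts drawn with fixed
  internal seeds (so a fit is a pure function of its inputs).

Ties are resolved by lowest objective, then lexicographically smallest $W$.
`optimize_v = FALSE` skips the Nelder–Mead stage and keeps the better of
the two analytic candidates; the large simulation studies below use this
mode, trading a slightly worse pre-period fit for a ~30-fold speedup that
does not change the difference-in-differences logic.

### Pre/post windows and staggered adoption

Each treated practice gets its own windows: pre-period from the first panel
month to $T_j - 1$, post-period from $T_j$ to the last panel month, or to
the month before an exit month when the practice leaves the programme
early. No common event-time alignment is imposed.

### Donor pools

Donors are practices outside the intervention schedule whose registered
list size, in the month before the treated practice joins, lies within
±20% (inclusive) of the treated practice's. The comparison month follows
the convention of describing practices in the month before joining; the
tolerance is configurable. Treated practices are never donors for each
other — their post-periods are contaminated by construction. A geographic
restriction of a real study is represented by an optional categorical
`group_col` filter, since simulated practices have no geography. Every
inclusion and exclusion decision is logged per candidate.

## Effects and placebo inference

The per-practice effect is a difference in differences,

$$\delta_j = \left[\bar Y^{\text{post}}_j - \bar Y^{\text{pre}}_j\right] -
  \left[\bar Y^{\text{post}}_{SC(j)} - \bar Y^{\text{pre}}_{SC(j)}\right],$$

per 100 patients per month. Inference treats each donor in turn as a
pseudo-treated unit (its pool being the remaining donors, same windows and
spec); the sample SD of the placebo $\delta$'s is the standard error, with
a normal-reference CI ($\pm 1.96\,se$) and two-sided p-value
$2(1-\Phi(|\delta|/se))$. The normal approximation, rather than a
rank-based permutation p-value, is used because downstream pooling needs
standard errors, which only the placebo-SD route supplies. Placebo fits
that fail are dropped and logged; fewer than 10 usable placebos is an
error, since an SD from fewer gives unusably unstable inference. An
optional `mspe_ratio_cap` excludes placebos whose pre-period fit is worse
than a multiple of the treated fit's; it is off by default, since there is
no principled universal threshold.

## Pooling

Per outcome, practices are combined by inverse variance: $w_i = 1/se_i^2$,
$\hat\delta = \sum w_i \delta_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$.
Heterogeneity is summarised by Cochran's
$Q = \sum w_i(\delta_i - \hat\delta)^2$ on $k-1$ degrees of freedom,
$I^2 = \max(0, (Q - df)/Q) \cdot 100$, and DerSimonian–Laird
$\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))$ — the standard
companion of inverse-variance pooling. The $I^2$ CI uses Higgins and
Thompson's test-based method on $\ln H$; for $k = 2$ with $Q \le k$ the
$\ln H$ standard error is undefined and the CI is reported as the full
[0, 100] range. The model choice follows the $Q$ test at $\alpha = 0.05$:
fixed effects when not significant, otherwise random effects with weights
$1/(se_i^2 + \tau^2)$. At $\tau^2 = 0$ the random-effects result collapses
onto the fixed-effects one exactly (a test asserts this limit). REML or
Paule–Mandel $\tau^2$ and Hartung–Knapp adjustment are out of scope.

## Cost model

Avoided events: monthly events $= \mathrm{round}(|\delta| / 100 \times
\text{population})$, annual $= 12 \times$ the **rounded** monthly count.
Rounding monthly first keeps the published style of monthly and annual
figures mutually consistent (74/month × 12 = 888/year; annualising before
rounding would give 890). Rounding is half-away-from-zero at both the event
and whole-currency level, the commercial convention, rather than R's
half-to-even. The per-admission unit cost is the per-episode reference cost
times the national FCE/FAE episode ratio (a reference cost is per finished
consultant episode, while an admission can span several episodes), rounded
to whole currency. Savings $=$ annual events $\times$ unit cost, with a
sensitivity range from the same arithmetic at the CI bounds. Admission and
readmission savings are never summed: whether avoided readmissions are a
subset of avoided admissions cannot be verified, so adding them risks
double counting. Only the admissions effect is costed by default.

## The synthetic panel generator

Real extracts of this kind (hospital activity linked to practice registers)
are not public, so the package generates panels with exactly the structure
the estimator assumes — an interactive fixed-effects model, which is the
data-generating process the synthetic control method is designed for:

$$y_{iot} = \max\!\left(0,\ \alpha_{io} + s_o(t) + \gamma_i f(t) c_o +
  \delta_o \mathbb{1}[t \ge T_i] + \varepsilon_{iot}\right)$$

* $\alpha_{io}$: practice intercepts, driven by one latent severity score
  per practice shared across outcomes, so the three rates co-move and the
  deprivation-like covariates (IMD, BME %, prevalence markers) correlate
  positively with outcome levels;
* $s_o(t)$: a common annual sine cycle with amplitude 5% of the outcome
  mean;
* $f(t)$: a shared smooth trend (standardized moving average of a random
  walk) with practice loadings $\gamma_i \sim N(1, 0.1)$ and outcome scale
  $c_o = 0.05 \times$ mean;
* $\varepsilon$: Gaussian noise, clipped at zero. Clipping (rather than
  truncated-normal draws) keeps the model simple and exactly testable; a
  configuration whose noise would clip more than 10% of draws is rejected
  as an unusable calibration. An optional count mode redraws monthly events
  as Poisson at the practice list size for integer-granular rates.

**Calibration.** Defaults describe a diverse set of urban English
practices: outcome means (2.70, 0.87, 0.12) per 100 patients per month
with between-practice intercept SDs (0.55, 0.22, 0.045); 48 monthly
observations; ten treated practices joining at months
{15, 15, 15, 22, 25, 28, 30, 32, 35, 40}, mirroring a staggered roll-out
over roughly two years starting a year into the panel; injectable default
treatment effects (0, −0.11, −0.021); emergency length of stay around 5
days. List sizes default to 5000–7000: real practices span a wider range,
but with only 40 donor candidates (rather than the several hundred a
national extract provides) a wider spread would leave some treated
practices with too few donors inside the ±20% band for placebo inference.
The noise SDs (0.18, 0.06, 0.025) put within-practice monthly variation at
roughly 5–10% of the mean. No public dataset pins down the trend or noise
process of the real series, so these are calibration knobs held fixed
across all tests, not facts.

**What the generator does not emulate:** patient-level event processes
within months, list-size drift, policy shocks hitting subsets of practices,
geographic referral structure, or covariate measurement error. Passing
tests therefore show that the pipeline recovers effects from data with the
assumed factor structure — not that the assumptions hold in any real
extract.

## Simulation studies and problem sizes

The test suite runs three simulation studies, sized to be informative while
keeping the whole suite in a few minutes:

* **Parameter recovery:** 20 replicates of the demo conditions (10
  treated, 40 donors, 48 months, injected admissions effect −0.11, fast
  fit mode). The pooled estimate's mean must sit within 0.03 of the truth.
* **Type-I calibration:** 200 single-practice null panels (30 donors, 36
  months); the per-practice placebo test at $\alpha = 0.05$ should reject
  at roughly its nominal rate.
* **Q calibration:** 500 homogeneous meta-analyses of $k = 10$ correctly
  specified estimates; $Q$ should average its degrees of freedom.

## Known limitations

* **Cross-practice dependence.** Treated practices draw their synthetic
  controls from overlapping donor pools and share common time shocks, so
  their effect estimates are positively correlated. Inverse-variance
  pooling assumes independence; its pooled standard error is therefore
  anti-conservative under shared pools, and the recovery study in the test
  suite shows the pooled 95% CI covering the truth less often than
  nominal even though the per-practice standard errors are well
  calibrated. Correlation-adjusted pooling is deliberately out of scope;
  users should read the pooled CI as a lower bound on uncertainty when
  pools overlap heavily.
* **Normal-approximation p-values** inherit the usual small-pool caveats;
  with 10–30 placebos the test runs slightly hot (the type-I study sits at
  the upper edge of its band).
* **Weight non-identification.** When outcomes are driven by a
  low-dimensional factor, many donor-weight vectors give equally perfect
  pre-period fits; weights are then reported as fitted but should not be
  over-interpreted individually (effects, which average over the fit, are
  stable).
* The cost model is deterministic arithmetic on a pooled point estimate
  and its CI; it is a sensitivity range, not a probabilistic analysis.

## Reproducibility

Every source of randomness derives from explicit seeds: the generator from
`sim_config(seed =)`, the outer-search multistarts from fixed internal
constants, and a pipeline run from its single top-level seed (stage seeds
are derived and recorded in the report's seed registry). Rerunning
`run_pipeline()` with the same configuration reproduces the JSON report
byte for byte.
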