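---
title: "Gender gaps in health expectancy: estimation and decomposition"
author: "hegap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gender gaps in health expectancy: estimation and decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hegap)
```

## The problem

Women outlive men in nearly every population, yet tend to report more
disability and chronic illness at older ages — the health–survival paradox.
Gender gaps in *healthy* life expectancy (the expected remaining years lived
free of a condition) are widely used to summarise this, but a single gap
number mixes two very different forces: sex differences in death rates and
sex differences in the age-specific prevalence of poor health. Two
populations can show the same small gap for opposite reasons — one because
women's survival advantage is almost exactly cancelled by a large disability
disadvantage, another because both forces are genuinely small. This package
estimates the gap and, crucially, splits it into an additive mortality
component and a health component, so the cancellation is visible instead of
hidden.

## The estimator

### Sullivan health expectancy

Inputs are an abridged period life table by sex (5-year age groups with an
open terminal group) and an age-group prevalence schedule by sex. With
life-table person-years $L_x$, survivors $l_{x_0}$ at the start age $x_0$,
and the proportion unhealthy $\pi_x$ in each group, healthy life expectancy
is

$$\mathrm{HLE}(x_0) \;=\; \frac{1}{l_{x_0}} \sum_{x \ge x_0} L_x\,(1 - \pi_x),$$

the Sullivan (1971) estimator. Under the *disability* definition
(any reported difficulty with the five activities of daily living: bathing,
dressing, eating, transferring in/out of bed, toileting) this is
disability-free life expectancy, DFLE; under the *chronic* definition (a
physician diagnosis of at least one of arthritis, cancer, diabetes, heart
condition, lung disease, stroke) it is chronic-disease-free life
expectancy, CFLE. The gender gap is $\Delta = \mathrm{HLE}_{women} -
\mathrm{HLE}_{men}$, computed at age 60 by default: that is where gender
disparities in health widen and where ageing surveys have dense coverage.

Prevalence comes from survey microdata as the weighted proportion
unhealthy among classified respondents in each age group,
$\hat\pi_x = \sum_i w_i\,1[\mathrm{unhealthy}_i] / \sum_i w_i$. A
respondent is unhealthy if *any* relevant item is a yes, healthy if *all*
are no. A single yes classifies the respondent even when other items are
unanswered (the yes dominates: the "any difficulty" aggregate is already
determined); respondents with no yes and at least one unanswered item are
indeterminate and dropped. The proportion is invariant to rescaling the
weights, so weights need no normalisation; non-positive weights are
rejected outright rather than repaired.

### Variance

Published life tables are treated as fixed — their sampling error is
negligible next to the survey's — so the variance propagates prevalence
sampling only:

$$\widehat{\mathrm{Var}} \;=\; \frac{1}{l_{x_0}^2} \sum_x L_x^2\,
\frac{\hat\pi_x (1-\hat\pi_x)}{n_x},$$

with $n_x$ the unweighted respondent count, and normal-approximation 95%
intervals. This is the conventional Sullivan variance; it ignores the
design effect of clustered, stratified samples, so a user-supplied
design-effect multiplier (`deff`) is available to inflate it. The gap's
standard error assumes independent samples by sex,
$\sqrt{v_w + v_m}$. A bootstrap over the group-level prevalence draws
reproduces the formula on a toy table (tested to 15% at 10,000
replicates).

### Decomposition

The gap is decomposed over the full parameter vector
$\theta = (m_{x}, \pi_{x})$ of one sex — death rates first (the mortality
block), prevalences second (the health block) — with the continuous-change
method of Horiuchi, Wilmoth and Pletcher (2008). Along the straight-line
path $\theta(t) = \theta_{men} + t(\theta_{women} - \theta_{men})$,
sampled at the midpoints of `n_steps` equal intervals, the contribution of
parameter $i$ accumulates the central difference
$f(\theta(t) + \tfrac{\delta_i}{2} e_i) - f(\theta(t) -
\tfrac{\delta_i}{2} e_i)$ with $\delta_i = \Delta\theta_i /
n_{steps}$, where $f$ rebuilds the life table from the $m_x$ block and
returns the Sullivan HLE. Block sums give the mortality and health
components; their total equals the directly computed gap up to a residual
that is *reported, never redistributed*.

Numerical behaviour of that scheme: the residual is second order,
shrinking roughly 4-fold per doubling of `n_steps`. At the default
`n_steps = 20` the residual on realistic schedules is of order
$10^{-5}$–$10^{-4}$ years — far below the 0.01-year precision at which
health expectancies are reported, which is why 20 is the default; a few
hundred steps drive it below $10^{-6}$ years when near-exact additivity is
wanted. Rates enter on their raw scale (the method's standard
formulation); `log_mx = TRUE` switches to a straight line in $\log m_x$
as a sensitivity check. A prevalence path can never leave $[0,1]$ between
valid endpoints, so an out-of-range evaluation aborts — it can only be a
coding error.

An independent **stepwise-replacement oracle** (`decompose_stepwise()`)
replaces parameters one at a time and averages over all replacement
orders; it is exactly additive by construction and anchors the tests: on
small objectives the two methods agree to well under 1% of the largest
contribution, including the classical two-parameter product example
$f = \theta_1\theta_2$, $(1,2) \to (3,4)$, whose contributions are
exactly $(6, 4)$. All orderings are enumerated up to 8 parameters; beyond
that a sampled set of orderings with a declared seed is required.

## Life-table construction

Abridged tables are built from central death rates with the standard
conversions: closed groups use
$q_x = n m_x / (1 + (n - a_x) m_x)$ and
$L_x = n\,l_{x+n} + a_x d_x$; the open group uses $q_x = 1$ and
$L_x = l_x / m_x$ (constant hazard). Choices:

* $a_x = n/2$ in closed groups. The analysis starts at 60, so no infant
  correction is needed, and sources rarely publish their $a_x$.
* Terminal group 85+ by default (configurable), matching the top-coding of
  ageing surveys. At very high death rates ($m_x a_x > 1$) the mid-interval
  $a_x$ makes $q_x$ exceed 1; this is reported as an error (incompatible
  $m_x$/$a_x$) rather than silently clamped — with a 85+ terminal group it
  does not occur for human mortality.
* Radix 100,000; every reported quantity is radix-invariant.
* CSV files may carry either $m_x$ or $q_x$ (exactly one). Closed-group
  rates are back-solved as $m_x = q_x / (n - (n - a_x) q_x)$; the open
  group's rate is unrecoverable from $q_x = 1$, so the $q_x$ schema
  requires an $a_x$ column and uses $m_x = 1/a_x$ there (the open-group
  $a_x$ *is* the mean years lived, $1/m_x$, under the constant-hazard
  closure).

Against a single-year-of-age table built from the same hazard with exact
interval integrals, the 5-year construction reproduces $e_{60}$ to well
under 0.1 years, with error falling monotonically as groups narrow.

## What the synthetic generator emulates

Access to the harmonised ageing surveys that motivate this package is
registration-restricted, so validation runs on synthetic data whose
population quantities are known in closed form:

* **Mortality**: Gompertz hazards $\mu(a) = \alpha e^{\beta a}$ per sex —
  the canonical adult-mortality model. Group rates are the hazard at the
  group midpoint (open group: its start + 5 years). Survival from age 60
  has a closed form, so total and healthy life expectancy can be computed
  by fine quadrature (0.01-year trapezoid grid to age 130) independently
  of the life-table machinery.
* **Health**: logistic-in-age prevalence
  $\pi(a) = \mathrm{logit}^{-1}(\gamma_0 + \gamma_1 (a - 60))$ per sex and
  definition, reproducing the strong age gradient of disability and
  chronic disease.
* **Ages** follow the stationary population implied by the life table
  (group counts proportional to $L_x$), uniform integer ages within the
  group, so group sizes thin out realistically at high ages.
* **Items**: the any-condition status is drawn first
  (Bernoulli($\pi_x$)), then one uniformly chosen item is set positive for
  the unhealthy; the analysis consumes only the aggregate, and this makes
  the generated group prevalence match $\pi_x$ exactly.
* **Weights** are i.i.d. lognormal (default meanlog 0, sdlog 0.5 — a
  realistic ~130% design-effect heterogeneity). True prevalence is
  weight-independent, so weighting costs only variance, as in a
  self-weighting design with unequal sampling.
* **Missingness**: each *no* item is independently blanked (default 0.5%
  per item, reflecting the near-complete ADL and diagnosis batteries of
  harmonised ageing studies); a yes is never blanked, so a reported
  condition always survives. Healthy respondents who lose an item become
  indeterminate and are dropped — the mechanism is therefore missing *not*
  at random and inflates estimated prevalence slightly (about +0.004 at
  $\pi = 0.2$ under the default rate). This is deliberate realism; the
  recovery tests below therefore run at zero missingness so their
  tolerance reflects discretisation and sampling only, and a separate
  directional test pins the sign and mechanism of the missingness bias.
* **Seeds**: one master seed; each sex draws from a derived stream
  (master + 1 for women, + 2 for men), so one sex can be regenerated
  without touching the other. Generation is byte-reproducible.

Four presets name qualitative regimes seen in cross-national comparisons,
with parameters fixed at design time: `"null"` (identical sexes — every
true gap and component is zero), `"korea-like"` (women's survival
advantage dwarfs their disability disadvantage; truth components roughly
+2.8 vs −0.5 years), `"portugal-like"` (large opposing components, about
+2.2 mortality vs −2.6 health, leaving a small negative total near −0.4 —
the cancellation regime), and `"denmark-like"` (both components positive).
Sample size defaults to 20,000 per sex, comparable to a large national
ageing survey.

What the generator does **not** emulate: household clustering and
multi-stage design effects (weights are i.i.d.), per-condition disease
profiles, proxy respondents, and any correlation between the disability
and chronic batteries beyond their shared age structure. Passing the
recovery tests therefore shows the estimator chain is correct under
clean sampling, not that complex-survey variance is fully captured — for
real data the `deff` hook is the acknowledgement of that gap.

## Validation contracts the tests compute

* Worked-example additivity: published mortality/health contribution pairs
  for three countries aggregate to their published totals, and the largest
  ratio of survival advantage to disability disadvantage (about 13.5)
  clears its published "13-fold" description.
* Zero-prevalence limit: with $\pi \equiv 0$, HLE equals $e_{60}$ to
  $10^{-9}$ years on 100 random Gompertz tables.
* Recovery: the full pipeline (generate → classify → weight → Sullivan) on
  the null preset at 20,000 per sex lands within 0.15 years of the
  closed-form truth in every definition × sex cell; about two thirds of
  that budget is sampling noise (the estimator's standard error is
  ~0.08 years) and the rest discretisation (~0.04 years).
* Null results: the null preset's estimated gap stays within 2 standard
  errors of zero, and with deterministic inputs an identical block across
  sexes produces a component below $10^{-8}$ years.
* Additivity and convergence of the decomposition as described above, with
  the stepwise oracle as the independent cross-check.

## Known limitations

* Period, prevalence-based health expectancy: the Sullivan estimator
  assumes the cross-sectional prevalence schedule applies to the synthetic
  cohort of the period life table; it is not an incidence-based
  (multistate) estimate and can lag real health transitions.
* The variance omits life-table uncertainty and survey design effects
  beyond the scalar `deff`.
* The missing-item rule (yes dominates; otherwise drop) is one defensible
  reading of an "any difficulty" aggregate with near-complete batteries;
  with substantial missingness it would need replacing by imputation, and
  the generator's directional test shows which way the simple rule leans.
* Contributions carry no standard errors; the decomposition is reported on
  deterministic schedules (or conditional on the estimated ones).

## References

Sullivan, D. F. (1971). A single index of mortality and morbidity.
*HSMHA Health Reports* 86, 347–354.

Horiuchi, S., Wilmoth, J. R., Pletcher, S. D. (2008). A decomposition
method based on a model of continuous change. *Demography* 45, 785–801.

Jagger, C., Van Oyen, H., Robine, J.-M. (2014). *Health expectancy
calculation by the Sullivan method: a practical guide.*
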