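---
title: "Measuring income-related inequality and horizontal inequity in health care utilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring income-related inequality and horizontal inequity in health care utilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ineqhc)
```

## The problem

Health systems that offer primary care free at the point of use can still
deliver it unequally across income groups: the poor may rely on local
primary providers while the better-off bypass them, or access barriers
(distance, informal costs, work patterns) may suppress use among the poor.
`ineqhc` implements the standard health-economics toolkit for quantifying
such income-related inequality from person-level household-survey data with
a rare binary utilization outcome (did the person use the service in the
recall period), and for separating the part of the inequality that is
*justified by need* from the part that is *inequitable*.

The motivating setting is a two-stratum national survey — urban adults whose
primary care comes from family health centers, and rural adults served by
district health centers providing both outpatient and inpatient care — but
every component is generic.

## Socioeconomic ranking

Living standards are measured by household income per equivalent adult,
using the OECD-modified equivalence scale: weight 1 for the household head,
0.5 for each additional adult, 0.3 for each child (default: a member under
18). All members of a household share one equivalized income.

Each adult then receives a *fractional rank* $R_i \in (0,1)$ in the income
distribution of the analysis sample. With normalized weights
$\tilde w_i$, a tie group $g$ with total mass $w_g$ gets the mid-mass rank
(mass strictly below $g$) $+\, w_g/2$, assigned identically to all its
members. Two consequences matter:

* the weighted mean rank is exactly $1/2$ for any weights, which the index
  formulas below implicitly assume; and
* ranks are invariant under any strictly increasing transform of income, so
  it is immaterial whether incomes are ranked on the raw or the log scale.

When the analysis is stratified (urban vs rural), ranks are computed within
each stratum after exclusions, because each stratum is analyzed as its own
income distribution.

```{r}
fractional_rank(c(10, 20, 30, 40))$rank
fractional_rank(c(10, 20), weight = c(3, 1))$rank
```

## Concentration and Erreygers indices

For outcome $y$ with weighted mean $\mu$, the standard concentration index
is

$$CI = \frac{2}{\mu}\,\mathrm{cov}_w(y_i, R_i),$$

negative when utilization is concentrated among the poor. For a binary
outcome the attainable range of $CI$ shrinks as $\mu$ grows, so the package
reports the Erreygers-corrected index for bounded outcomes
$y \in [a, b]$:

$$EI = \frac{4\mu}{b - a}\,CI = \frac{8}{b-a}\,\mathrm{cov}_w(y_i, R_i).$$

The implementation computes $EI$ from the right-hand covariance form, which
makes three properties exact rather than approximate:

* *binary identity*: $EI = 4\mu\,CI$ whenever $(a,b) = (0,1)$;
* *mirror*: $EI(a + b - y) = -EI(y)$;
* *degenerate limit*: $\mu = 0$ gives $EI = 0$ (with a warning), whereas
  $CI$ is genuinely undefined there and errors.

All moments are weighted *population* moments — divide by total weight, no
$n-1$ correction — so results are reproducible bit-for-bit and the identity
above has no finite-sample fudge.

## Horizontal inequity by indirect standardization

Some of the income gradient in utilization is legitimate: older and sicker
people should use more care, and if they are disproportionately poor the raw
index conflates need with inequity. The package follows the
Wagstaff–van Doorslaer indirect-standardization convention with a linear
probability model (LPM). For rare binary outcomes, linear and nonlinear
standardizations are known to give very similar results, and the linear
model makes the decomposition below exact.

1. Fit weighted OLS of the outcome on need covariates $x_j$ (age–sex
   strata, disability, recent health complaint, days of activity missed)
   and non-need covariates $z_k$ (log income per equivalent adult, marital
   status, activity status, education, household size, log distance to the
   nearest facility):
   $h_i = \alpha + \sum_j \beta_j x_{j,i} + \sum_k \gamma_k z_{k,i} + \varepsilon_i.$
2. Form the *need-predicted* utilization with each person's own need values
   but non-need regressors fixed at their weighted sample means:
   $\hat h^X_i = \hat\alpha + \sum_j \hat\beta_j x_{j,i} + \sum_k \hat\gamma_k \bar z_k.$
3. Form the *indirectly standardized* utilization
   $\hat h^{IS}_i = h_i - \hat h^X_i + \bar h.$

The horizontal-inequity index is $HI = EI(h) - EI(\hat h^X)$. Because OLS
with an intercept preserves the mean, $EI(\hat h^{IS})$ equals the same
quantity; the package computes both routes and refuses to return if they
disagree beyond $10^{-10}$. $HI < 0$ means utilization remains pro-poor
after need adjustment. A standard-CI-based variant is available via
`horizontal_inequity(..., method = "standard")`; the default uses the
Erreygers index on both terms so that EI and HI are on one scale.

Two deliberate numerical choices:

* **Need predictions are not clipped to $[0,1]$.** An LPM prediction can
  leave the unit interval; clipping would destroy the identity
  $EI(h) - EI(\hat h^X) = EI(\hat h^{IS})$. `erreygers_index()` therefore
  takes `check_bounds = FALSE` on these internal calls while still
  enforcing bounds on user-supplied outcomes.
* **Degenerate dummies** (a category with no observations in a stratum,
  e.g. an empty age–sex cell in a small subsample) are dropped with a
  warning instead of an error, since small strata will not populate all 14
  cells. Genuine collinearity among remaining columns is still an error
  naming the offending columns.

## Decomposition

With the LPM in hand, the Erreygers index of a binary outcome decomposes
over regressors:

$$EI = 4\Big[\sum_j \beta_j\,\bar x_j\,C_{x_j} + \sum_k \gamma_k\,\bar z_k\,C_{z_k}\Big] + \text{residual},$$

where $C_{x}$ is the regressor's own standard concentration index against
the income rank. Each contribution is evaluated as
$8\,\beta\,\mathrm{cov}_w(x, R)$ — algebraically the same when $\bar x \ne 0$
and still well defined when $\bar x = 0$ (the regressor's own $C$ is then
reported as `NA`). The residual term, which the textbook formula omits, is
always reported: without it the table cannot satisfy additivity. It is
computed as $EI - \sum$ contributions and verified against the independent
expression $8\,\mathrm{cov}_w(\hat\varepsilon, R)$.

Percent contributions are signed and can exceed 100% in magnitude; when
$|EI| < 10^{-12}$ they are reported as 0 and the table is flagged
degenerate. Regressor concentration indices use the standard (not
Erreygers) index even for binary regressors, because the decomposition
formula multiplies by the regressor's own mean. Changing a dummy set's
reference category shifts individual dummy contributions (the intercept
absorbs the shift) but leaves the total and the residual unchanged — a
property asserted in the tests.

`group_contributions()` aggregates the table into report groups (all need
regressors into one "need" bar; income, education, activity status, marital
status, distance, household size separately), the conventional way these
results are displayed.

## Bootstrap inference

Confidence intervals are percentile bootstrap with, by default, 1,000
replications and the *household* as resampling unit — rows within a
household share one equivalized income and are therefore dependent.
Person-level resampling is available for comparison. Inside every replicate
the whole pipeline is recomputed: fractional ranks are re-derived (the rank
is an estimated quantity; freezing it understates variance) and, for HI,
the LPM is refitted. Replicates where the statistic fails — e.g. a resample
with zero utilization — are skipped and counted, with a hard error past 10%
failures. Percentile intervals are used because they are the simplest
method consistent with an unqualified "bootstrap CI"; indices whose
interval excludes zero are flagged significant, and no p-values are
invented. Identical seeds give bit-identical results.

## The synthetic-data generator

Restricted national survey microdata cannot be redistributed, so the
package ships a generator that emulates the *structure* of such a survey
with planted, analytically known inequality:

* households with sizes centered at 4 (truncated shifted Poisson, range
  1–15); non-head members are children with probability 0.5, giving about
  2.5 adults per household;
* log-normal equivalized income, median log income 15.2 (urban) / 14.7
  (rural), log-scale SD 1.0 / 0.9 — spanning the printed min–max range of
  roughly 12 to 21; household income is backed out through the equivalence
  scale; the head is the oldest adult;
* adults assigned to 14 age–sex strata at the survey's printed proportions
  (the urban column sums to 99.9 by rounding; the generator normalizes);
* covariates drawn with logistic income-*rank* gradients whose intercepts
  are numerically calibrated (Brent root-finding for binary covariates, a
  fixed-point update for multinomial ones) so marginal prevalences hit
  their targets exactly in expectation — disability 5.2%/5.9%, any health
  problem 7.8%/6.7%, the marital/employment/education margins, and
  utilization 1.1% (urban FHC), 2.7% (rural outpatient), 5.9% (rural
  inpatient). Rank gradients (rather than income-level gradients) make the
  planted covariate concentration indices monotone in the gradient
  parameter;
* log distance drawn normal at household level (allowing negative logged
  distances), with its own rank gradient;
* the outcome drawn directly from a linear probability model, so the
  fitted LPM is *correctly specified* and coefficient recovery is exact in
  expectation. A logit option (`logit_outcome = TRUE`) exists to study
  misspecification and is off by default.

The realized probability vector is checked before drawing: a configuration
pushing more than 1% of probabilities outside $[0,1]$ is rejected as
infeasible; otherwise probabilities are clipped and the clipping rate
recorded (it is 0 at all shipped presets). This feasibility constraint is
also why the preset coefficients are smaller in magnitude than regression
estimates typically printed for such surveys: a *generative* LPM for a 1.1%
outcome cannot carry large coefficients without leaving the unit interval,
whereas a *fitted* LPM is free to produce out-of-range fitted values.

Three calibration presets plant pure income–utilization associations with
all covariate channels switched off: `null` (no association, prevalence
5.9% — the largest of the study outcomes, chosen so null-calibration
studies have a stable event count), `pro_poor`
($p_i = 0.011 - 0.0104\,(R_i - \tfrac12)$) and `pro_rich`
($p_i = 0.059 + 0.01905\,(R_i - \tfrac12)$). For a rank-linear probability,
the large-sample Erreygers index is $8 \cdot \text{slope} \cdot
\mathrm{Var}(R) = \tfrac23\,\text{slope}$, i.e. about $-0.0069$ and
$+0.0127$ — magnitudes chosen to be representative of significantly
pro-poor urban primary care and significantly pro-rich rural inpatient
care. `oracle_ei()` turns a configuration into its planted truth by a
single very large draw (default one million adults) rather than the
closed form, so the oracle remains valid for arbitrary edited configs.

What the generator does *not* emulate: the survey's file layouts and
questionnaire codings, its clustered/stratified sampling design (weights
default to 1; the estimation code is written weighted throughout so
supplying real design weights is one column away), item nonresponse
patterns, and any attempt to reproduce a particular study's published index
or decomposition values. Passing tests on synthetic data therefore
demonstrate the *statistical machinery* — identities, calibration,
recovery, coverage — not fidelity to any real population.

## Validation design and problem sizes

The test suite checks, among others:

* covariance-form index vs an $O(n^2)$ direct-sum brute force on 1,000
  random weighted instances ($n \le 50$), to $10^{-12}$;
* the binary identity and the mirror property on random binary fixtures;
* the standardization identity and decomposition additivity (with the
  two-route residual) on 100 random fixtures of $n = 500$;
* oracle recovery: for each calibration preset, the EI estimated at
  20,000 adults falls within 3 Monte-Carlo SEs of the million-draw oracle
  in at least 95 of 100 seeded replicates;
* bootstrap calibration: under the null preset, the 95% percentile
  interval (B = 200, household resampling) covers zero in 92–98% of 200
  outer replicates of 5,000 adults;
* generator fidelity of all target prevalences within ±0.3 percentage
  points at 50,000 adults;
* end-to-end determinism of datasets, indices, intervals and report files
  under fixed seeds.

On parameter recovery, note a multiplicity subtlety: with ~30 regressors,
requiring *every* coefficient inside a 3-SE band simultaneously would fail
by construction about 8% of the time even for a perfect estimator
($0.9973^{30} \approx 0.92$). Recovery is therefore asserted
per coefficient, using HC0 robust standard errors (LPM errors are
heteroskedastic Bernoulli).

The bundled analysis script runs the three strata at their study sizes
(17,354 urban and 13,193 rural adults) with B = 1,000 bootstrap
replications, and the recovery studies at the sizes listed above; these
sizes were chosen to match the emulated survey and to keep a full
validation run comfortably interactive on a single core.

## A complete run

```{r, eval = FALSE}
cfg <- preset_config("urban_fhc", n_households = 7000, seed = 1)
d <- generate_survey(cfg)
report <- run_analysis(d, B = 1000, seed = 2)
print(report)
write_report(report, "urban-fhc-report", plot = TRUE)
```

For real data, `read_survey()` takes a CSV and a YAML config mapping
columns to roles (outcome, income or household income + composition,
weights, household id, need/non-need sets, area) and declaring the
equivalence scale; the resulting object enters the same pipeline.

## Known limitations

* The LPM is used for standardization and decomposition; nonlinear
  (probit/logit) standardization and two-part models are out of scope, as
  are Wagstaff's normalized index, generalized indices with
  inequality-aversion parameters, and survey-design-based (strata/PSU)
  variance estimation.
* Percentile intervals can undercover slightly for very rare outcomes in
  moderate samples; the bootstrap skips zero-utilization replicates, which
  for extremely rare outcomes introduces a mild selection effect (counted
  and capped at 10%).
* Whether "days of activity missed" enters the regression as a count or
  categorically is a modelling choice; it enters as a count here and is
  configurable through the need-column roles.
* The decomposition residual includes any genuine misspecification of the
  linear model, not only sampling noise.
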