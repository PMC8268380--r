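---
title: "Marginal-effect path analysis of obesity and surgical outcomes"
author: "margpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marginal-effect path analysis of obesity and surgical outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(margpath)
```

## The question and the estimand

Obesity worsens perioperative outcomes in colorectal-cancer (CRC) surgery,
but a relative measure such as an odds ratio does not compose across a causal
chain: the odds ratio of obesity on infection and the odds ratio of infection
on death cannot be multiplied into anything interpretable. margpath
implements the alternative: work throughout in *absolute marginal effects*.
For a logistic model with log-odds coefficient $\beta$ and outcome prevalence
$P$, the marginal probability change per unit of the predictor is

$$\frac{\partial P}{\partial X} = \beta \, P \, (1-P),$$

the derivative of the logistic mean function evaluated at prevalence $P$.
Absolute effects multiply along a path and add across paths. With obesity as
the exposure $X$, a set of postoperative complications $M_1,\dots,M_k$ as
mediators, and death / length of stay (LOS) / total charges as outcomes, the
mediated ("indirect") effect of the exposure on each outcome is

$$\Delta_\text{outcome} \;=\; \sum_{i=1}^{k} a_i\, b_i,$$

where $a_i = \beta^{(i)}_X P_i (1-P_i)$ is the exposure's marginal effect on
mediator $i$ (from a logistic model of the mediator on exposure plus
confounders) and $b_i$ is mediator $i$'s effect on the outcome — a marginal
effect $\beta^{\text{mort}}_i P_\text{mort}(1-P_\text{mort})$ for death, or an
ordinary-least-squares coefficient (days, US dollars) for LOS and charges.
This is the classical product-of-coefficients path decomposition, carried out
on the probability/outcome scale so the products have units (probability,
days, dollars). It is *not* a counterfactual mediation estimand: no
exposure–mediator interaction is modelled, and the causal ordering
(exposure precedes complications precede discharge outcomes) is asserted
from clinical reasoning, not estimated.

Two entry points compute the decomposition: `run_pipeline()` estimates every
edge from admission-level data, and `from_printed_tables()` /
`replay_pipeline()` rebuild it from published per-edge coefficients, which is
how a published figure's totals can be reproduced without the licensed
microdata.

## Evaluation point of the marginal effect

$P$ in $\beta P(1-P)$ is the **dependent-variable mean of the model's
estimation sample** — the event count divided by the rows entering the fit —
not the average of per-observation derivatives $\overline{p_i(1-p_i)}\beta$.
The two differ in the third decimal for rare outcomes; the dependent-mean
convention is the one under which the published per-edge values
(e.g. $0.43 \times 0.046 \times 0.954 = 0.019$) reproduce, and it is what
`marginal_effects()` uses. `marginal_effect()` refuses $P \notin (0,1)$; the
value is bounded by $|\beta|/4$ and carries $\beta$'s sign.

## Cohort definition

Admissions qualify with (in rule order, each step logged for the attrition
flow diagram): a CRC diagnosis (ICD-9-CM roots 153/154), a qualifying
resection procedure (45.7x colectomy; 48.40/41/43/49 pull-through;
48.50/52/59 abdominoperineal; 48.6x other rectal resection), age ≥ 20, and no
*other primary* cancer (roots 140–239). Codes match by string prefix on the
dot-free form, the standard claims convention.

One interpretive decision deserves emphasis. The 140–239 exclusion is read as
*other primary cancers*, carving out not only 153/154 (the index cancer) but
also 196–199, the secondary-malignancy codes. A third of the cohort is
metastatic, and in discharge abstracts metastasis is coded precisely by
196–199; excluding those codes would empty the metastatic stratum that the
matching explicitly balances on. The same codes then *define* the severity
marker (`metastasis`). Comorbidities are likewise carried as diagnosis codes
(diabetes 250.x, liver disease 571.x, alcohol abuse 303.x), so every analytic
flag derives from the code lists alone; the code book is editable YAML for
sensitivity analyses.

## Matching

Obese cases (278.0x) are matched 1:4 to non-obese controls exactly on
(age band, sex, metastasis). No algorithm is canonical for this design; the
package uses stratified uniform sampling **without replacement**, with case
and control order shuffled by the seed. Rationale: it is the simplest
procedure consistent with exact post-match balance on the matching variables
(the balance test returns $\chi^2 = 0$, $p = 1$ by construction, since each
case contributes exactly four stratum-identical controls) and with the
occasional case dropping out when its stratum's control pool is exhausted.
Age is matched on the four-level band, not exact years: band-level identity
is what the design targets, and exact-year matching would make 1:4 matching
infeasible in sparse strata. No caliper, no replacement, no propensity score.
Matching only selects and pairs — it never edits rows — and unmatched cases
are reported, not silently dropped.

## Regression layers

* **Complication models** (one per complication family):
  `complication ~ obesity + race + income quartile + elective admission +
  hospital location + teaching status`, logistic, fitted on the matched
  cohort. The adjustment set is the one conventionally shown for this
  analysis; it is fully configurable. Reference levels: White, Q1,
  non-elective, rural, non-teaching. Note that diabetes and liver disease are
  imbalanced between groups yet excluded from the default set — the default
  mirrors the published adjustment, and the config can add them.
* **Mediator selection**: complications whose obesity term has two-sided
  $p < 0.05$ (Wald) enter the path analysis. Under the default calibrated
  generator at the full cohort size this selects exactly infection, shock,
  bleeding, wound disruption, and digestive complications.
* **Mortality model**: `death ~ the selected complication flags`, logistic.
* **LOS / charges models**: OLS on the same flags, with Wald 95% CIs, $R^2$
  and adjusted $R^2$.

Each model is complete-case *per outcome* (death, LOS and charges carry
separate missingness), so the three layers legitimately use slightly
different $N$. Logistic fits use IRLS (`stats::glm`) with tolerance `1e-8`
and at most 100 iterations; Wald CIs are computed on the log-odds scale and
exponentiated, so `OR = exp(beta)` holds exactly in every report.
Quasi-separation (extreme coefficients or fitted probabilities) is flagged on
the fit and in the pipeline run log. The likelihood-ratio statistic against
the intercept-only model and the Pearson chi-square of the fit are both
reported; neither feeds the path computation.

## The synthetic generator

Real hospital-discharge microdata of this kind are licensed and cannot ship
with a package, so `sim_config()` + `generate_population()` emulate the
population the analysis expects, with the assumed causal structure built in:

* covariates are drawn from the marginals of a 107,067-admission surgical CRC
  population (sex ≈ 50/50, age skewed old, 78% White, 65% elective, 35%
  metastatic, 89% urban, 45% teaching; obesity prevalence 7.86%);
* covariates are sampled independently **except diabetes**, which is tied to
  obesity (40.7% among obese vs 18.7% among non-obese) so that the
  characteristic post-match diabetes imbalance reappears; full copula realism
  is out of scope;
* each complication is Bernoulli from its logistic model given obesity and
  the adjustment covariates, with published-scale coefficients (obesity
  log-odds 0.43/0.72/0.24/0.51/0.13 for the five mediators) and intercepts
  calibrated by `uniroot` so the analytic population-average prevalences hit
  4.6%, 0.3%, 2.1%, 1.2%, 12.0% (the remaining eight families are background
  rates unrelated to obesity);
* death is Bernoulli from the mortality model given the realized five
  mediators (log-odds 0.83/2.45/0.57/0.62/0.22, intercept calibrated to a
  2.2% death rate);
* LOS and charges are linear in the five mediator flags (8.42/8.68/3.15/
  11.09/3.94 days; 62,169/85,247/30,770/86,760/23,378 dollars; intercepts
  8.08 days and \$54,795) plus noise;
* died/LOS/charges are set missing completely at random at the small
  per-outcome rates discharge data show (≈0.06%, ≈0.002%, ≈2.9%).

**Noise model.** Only means and SDs of LOS and charges are available to
anchor dispersion, and both quantities are right-skewed and non-negative, so
the noise is a *mean-centred shifted log-normal*: a log-normal variate with
(mean 8, SD 8) days or (mean \$50k, SD \$78k) minus its mean. Centring keeps
the OLS layer correctly specified (homoskedastic, mean-zero, predictor-
independent errors), and the shift bounds the noise below at −mean, so every
outcome stays positive without truncation — truncation would bias coefficient
recovery. LOS is then rounded to whole days and charges to whole dollars, as
discharge abstracts report them; the rounding error is negligible against the
noise SD. The resulting marginals (LOS ≈ 9.2 ± 8.1 d, charges ≈ \$63k ± 82k)
sit close to the real cohort's. The conditional dispersion is genuinely a
free parameter — nothing pins it down — and it is exposed in the config.

**Calibration as exact enumeration.** Because covariates are discrete and
independent, the population-average probability of each complication model is
a finite sum over 320 covariate cells, and the mortality average a sum over
those cells × 32 complication patterns (conditionally independent given
covariates). `analytic_prevalences()` computes these exactly;
`calibrate_intercepts()` root-finds on them (the average is strictly
increasing in the intercept, so the root is unique in $(-40, 20)$, tolerance
`1e-10`); and the same enumeration serves as the no-sampling oracle that the
realized simulation rates are tested against within Monte-Carlo error.

**What passing tests show — and what they do not.** The generator reproduces
the marginal structure and the assumed exposure→mediator→outcome chain. It
does **not** reproduce hospital clustering, survey design weights, coding
error, within-patient correlation between complication families beyond
shared covariates, or any direct (non-mediated) obesity→outcome pathway.
Passing parameter-recovery tests therefore demonstrates that the estimators
are consistent and well-calibrated *under the assumed data-generating
process*, not that the substantive findings would replicate on real claims
data.

## Matching and estimation interact benignly here

Complication models are fit on the matched cohort, which is selected on
age/sex/metastasis and obesity. Those selection variables are either in the
model (obesity) or independent of the complications given the model's
covariates (the generator gives age/sex/metastasis no role in complication
risk, mirroring their absence from the published adjustment), and death is
independent of obesity given the complications. Selection of this kind
leaves the conditional-model MLEs consistent, which is why parameter-recovery
checks may fit on either the population or the matched subset; the package's
acceptance checks fit on the generated population.

## Descriptive layer

Categorical contrasts use the Pearson chi-square without continuity
correction (all intended tables are far from small-sample; a warning fires
when any expected count drops below 5). Continuous contrasts use the
classical pooled-variance two-sample t — group SDs in this setting are
near-equal — with Welch available by argument. The degenerate zero-variance
case returns $p \in \{0, 1\}$ rather than NaN. Missing outcomes are excluded
listwise per outcome and counted per group, matching how discharge tables
account for missingness. No multiplicity adjustment is applied anywhere, by
design.

## Numerical and reporting conventions

All internal arithmetic is double precision; rounding happens only at
display (marginal effects to 4 decimals; path products printed as
$\times 10^{-5}$ probability, days to 3 decimals, whole dollars). Path
totals are exact sums of exact products, invariant to mediator order. No
uncertainty intervals are attached to path products — the decomposition is
reported as a point summary, and the per-edge CIs are available in the fit
objects. The totals cover the five mediated paths only; any direct
exposure→outcome effect is outside the sum.

## Problem sizes

The test suite exercises the generator at up to 500,000 records for
prevalence calibration checks, parameter recovery at 200,000 records × 3
replicates (every generating coefficient checked against its fitted 95% CI,
with ~95% expected coverage), matching guarantees at 50,000, and the full
pipeline at the cohort's own 107,067. These sizes keep Monte-Carlo error
well below the assertion tolerances while remaining comfortable on a single
CPU.

## Known limitations

* Admissions are treated as patients (no linkage of readmissions), as the
  source data convention dictates.
* The path decomposition is descriptive-causal in the classical path-analysis
  sense; it does not identify natural direct/indirect effects under
  exposure–mediator interaction.
* The mediator set is chosen by per-model significance of the exposure term,
  which inherits the usual instability of significance-based selection near
  the threshold.
* ICD-9-CM era only; a 10th-revision code book would be a drop-in
  replacement via `default_codebook(overrides = )` / YAML.
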