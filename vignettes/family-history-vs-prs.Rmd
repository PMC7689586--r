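---
title: "Methods: comparing family history and a polygenic risk score for COPD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing family history and a polygenic risk score for COPD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fhprs` implements a complete analytic pipeline for asking whether
self-reported family history and a polygenic risk score (PRS) carry
overlapping or complementary information about COPD risk. This vignette is
the package's own account of the statistical machinery: the models, the
assumptions they lean on, the tunable parameters and why their defaults are
what they are, and the numerical decisions that make the results
deterministic and testable.

## Outcome and predictor derivation

COPD status is derived from post-bronchodilator spirometry alone. A subject
is a **case** when FEV₁ percent-predicted < 80 and FEV₁/FVC < 0.7, a
**control** when FEV₁ ≥ 80% and FEV₁/FVC ≥ 0.7, and **excluded** otherwise.
The two excluded corners are clinically meaningful groups — mild obstruction
(GOLD 1: ratio < 0.7, preserved FEV₁) and preserved-ratio impaired
spirometry (PRISm: ratio ≥ 0.7, FEV₁ < 80%) — that belong to neither the
moderate-to-severe case group nor the healthy-control group. Every record
with complete spirometry falls in exactly one class; missing spirometry
yields a missing status and the record is dropped from COPD models only.
The same exclusion rules are applied to every cohort, including imbalanced
replication-style cohorts.

**Family history** is positive when a parent is reported to have had COPD,
chronic bronchitis or emphysema. Three codings are provided:
`copdgene_full` (primary: any of the three items "yes", with "unknown"
treated as "no" — an explicit "unknown" is a response, not a missing value),
`eclipse_harmonized` (chronic bronchitis and emphysema items only, for
questionnaires without a COPD item), and `exclude_unknown` (a sensitivity
coding in which subjects whose every contributing response is "unknown"
become missing). The primary treatment of "unknown" as "no" is a
questionnaire convention, exposed as a flag precisely so the sensitivity
analysis can quantify its impact.

**PRS.** The raw score is standardised within each cohort over the full
analysis sample (cases, controls and excluded subjects alike), so "per SD"
refers to the cohort's own score distribution and is defined before any
outcome filtering. The dichotomised form flags scores strictly above the
empirical 2/3 quantile (quantile type 7); ties at the cut fall below. The
tie-break is arbitrary but fixed — determinism matters more than the
direction. Tertiles (rather than, say, a median split) make the exposed
fraction comparable to the roughly one-third prevalence of positive family
history, so the two exposures' odds ratios and attributable fractions are
on comparable footing. Fewer than three distinct scores, or zero variance,
in a group is a hard error ("degenerate PRS") rather than a silent NA.

## The three nested models

For each outcome the pipeline fits

* model 1: `Y ~ FamHx + C`
* model 2: `Y ~ PRS + C + PCs`
* model 3: `Y ~ FamHx + PRS + C + PCs`

with base covariates age (years), sex (female reference) and pack-years.
Outcome-specific covariates follow the epidemiology of each endpoint:
exacerbation outcomes add baseline FEV₁ %-predicted and current smoking,
six-minute walk distance adds height and weight, death adds the BODE index,
and CT traits add the scanner identifier. Ancestry principal components
enter only the PRS-containing models (default 5, configurable — the number
is a modelling choice, not something the data model fixes).

Binary outcomes are fitted by IRLS maximum likelihood (convergence when the
deviance change is below 1e-10, iteration cap 100, deterministic start at
β = 0). Apparent separation (any |β̂| > 15) is an error that names the
offending columns and points to the Firth estimator rather than returning
a meaningless huge coefficient. Rank deficiency likewise errors with the
collinear columns named. Wald 95% intervals are used throughout;
`exp(CI of β)` is the CI of the OR by construction.

**Firth-penalised logistic regression** maximises
ℓ(β) + ½·log det I(β) by modified IRLS with hat-value-adjusted scores and
step-halving, stopping when the penalised score norm falls below 1e-8 (cap
50 iterations). It exists for two situations the MLE handles badly: severe
case:control imbalance (a 1713:147 replication cohort) and separation,
where the Jeffreys penalty keeps estimates finite. Inference uses Wald
intervals on the penalised estimates; profile-penalised-likelihood
intervals are out of scope. On balanced, well-populated designs the penalty
is O(1) against an O(n) likelihood, and the test suite confirms Firth and
ML estimates agree to within 1% at n = 10,000.

## Discrimination, calibration, and their caveats

AUROC is the Mann–Whitney concordance probability (ties count ½), computed
by midranks in O(n log n); its variance and the paired model comparison use
the DeLong structural-components method. Two caveats are deliberate design
choices rather than oversights. First, evaluation is **in-sample**
(apparent AUC): the goal is to compare nested descriptions of one cohort,
matching standard practice for this design; cross-validation is available
as an option but off by default. Second, the paired DeLong test is known to
be anticonservative when the two models are **nested and fitted on the same
data**; the test suite verifies approximate nominal size (5% ± 2% over
1000 replicates) for non-nested correlated scores, which is the setting the
test's asymptotics actually cover. A self-comparison has exactly zero
variance; it is reported as degenerate with `p = NA` rather than 0/0.

The scaled Brier score is 1 − Brier/(p̄(1−p̄)): 1 for perfect predictions, 0
for the constant-prevalence reference, negative for worse-than-reference.
For continuous outcomes, adjusted R² = 1 − (1−R²)(n−1)/(n−p−1) and
MSE = RSS/n; the n (not n−p) denominator is a documented convention choice.

## Attributable fractions, interaction, RERI

Attributable fractions use the case-based (Miettinen) forms:
AF_exposed = (OR − 1)/OR and AF_population = p_c·(OR − 1)/OR with p_c the
exposure prevalence **among cases**. Both treat the adjusted OR as a risk
ratio, reasonable for outcomes that are not too common in the source
population; the method label and inputs are carried in the output so an
alternative (e.g. Levin's formula on population prevalence) can be
substituted and compared. No variance is attached — these are descriptive
summaries of a fitted OR.

Multiplicative interaction is the Wald test on the family-history × PRS
product term (continuous PRS by default), with the likelihood-ratio test
computed alongside as a cross-check. Additive interaction is
RERI = OR₁₁ − OR₁₀ − OR₀₁ + 1, computed either from a four-level joint
factor (family history × top-tertile PRS) or from the product-term
parameterisation — the same model in different coordinates, and the two
routes agree to numerical precision on identical data. The RERI interval is
the multivariate delta method on the coefficient covariance
(Hosmer–Lemeshow). The p-value is two-sided by default with a one-sided
option: a two-sided 95% interval covering zero can coexist with a
significant one-sided directional test, and published RERI results
sometimes mix the two conventions, so the sidedness is an explicit flag
rather than a hidden default.

## Mediation and the biserial correlation

The natural-effects decomposition asks how much of the family-history
effect on COPD travels through the PRS. The estimator is imputation-based:
fit `logit P(Y=1) ~ x + m + C` (exposure–mediator product term optional,
off by default); expand each record into two counterfactual rows with
hypothetical exposure x₁ ∈ {0,1} while x₀ keeps the observed exposure
(whose mediator value the row retains), imputing the outcome expectation
from the first model; then fit
`logit E(Y(x₁, M(x₀))) ~ x₁ + x₀ + C` on the expanded data. The x₁
coefficient is the natural direct effect (NDE), the x₀ coefficient the
natural indirect effect (NIE), total = NDE + NIE exactly, and proportion
mediated = NIE/(NDE + NIE). Under a rare outcome and the generator's linear
mediator model, NIE converges to a·β_PRS — the classical
product-of-coefficients result — which is the oracle the test suite checks
against.

Inference is a nonparametric bootstrap over subjects (default B = 1000,
percentile intervals, seeded and therefore reproducible; p-values from the
normal approximation with the bootstrap SE). The proportion-mediated ratio
is unstable when the total effect is near zero, so its interval is reported
only when the total effect's bootstrap distribution keeps one sign in at
least 97.5% of replicates; otherwise it is flagged. Identification assumes
no unmeasured exposure–outcome, mediator–outcome, or exposure–mediator
confounding beyond the adjustment set — an assumption the data cannot
verify, stated rather than tested.

The exposure–mediator association is summarised by the biserial
correlation, with two estimators because the "binned" procedure common in
applied work is ambiguous: `closed_form` converts the Pearson
point-biserial via r_b = r_pb·√(p(1−p))/φ(Φ⁻¹(p)), and `binned_ml` cuts
the continuous variable into 10 equal-count bins and maximises the
bivariate-normal likelihood of the 2 × 10 table over the latent correlation
with thresholds fixed at the marginal quantiles (a two-step polychoric-style
estimator). Under a genuinely latent-normal data-generating process the two
agree closely (verified at ρ = 0.3, n = 100,000); both are reported with
the point-biserial t-test p-value.

## Fixed-effect meta-analysis

Per-cohort model-3 estimates are pooled on the log scale with
inverse-variance weights: pooled = Σwθ/Σw, SE = 1/√Σw, Q = Σw(θ−pooled)²,
I² = max(0, (Q−df)/Q)·100. Standard errors can be recovered from printed
95% CIs as (log U − log L)/(2·1.96); printed rounding makes such recovered
SEs approximate, which is why the in-package check on published interval
bounds asserts Q < df (hence I² = 0) rather than an exact Q value. Pooling
three strata (two discovery-cohort ancestry groups plus one replication
cohort) is the default, configurable. A random-effects option exists behind
a flag for completeness but the fixed-effect model is the primary choice,
consistent with pooling a small number of cohorts with negligible observed
heterogeneity.

## The synthetic-cohort generator

`generate_synthetic_cohort()` draws, in order: family history
FH ~ Bernoulli(p) with p = 0.33; the raw PRS ~ Normal(a·FH, 1); covariates
(age truncated to 45–80 years, mean 62, SD 9; pack-years truncated at ≥ 10,
mean 47, SD 25 — a heavy-smoker enrolment criterion; half female; 45%
current smokers); disease status from
logit P = β₀ + β_FH·FH + β_PRS·PRS + γ·FH·PRS + covariate terms; then
spirometry back-filled from truncated normals on the correct side of the
case/control thresholds, so re-deriving status from the written table
reproduces the generated status exactly. Secondary outcomes (exacerbation
counts, severe exacerbations, BODE, death, SGRQ, walk distance, quantitative
CT traits) are generated from simple generalised-linear models on status,
family history and PRS.

Default effect sizes are the study conditions themselves: β_FH = log 1.67
and β_PRS = log 2.11 (the adjusted model-3 odds ratios), γ = 0, and an
intercept giving a roughly balanced case:control split as in an enriched
case–control design. The mediator shift default a = 0.1527 was derived,
once, by inverting the closed form
r_b = a·p(1−p)/(φ(Φ⁻¹(p))·√(1 + a²p(1−p))) so that the biserial
correlation between family history and the PRS equals 0.093 at p = 0.33 —
the observed weak exposure–mediator correlation this design presumes. The
linear mean-shift mechanism itself is an assumption of the generator, not
something the data model dictates.

Reproducibility is strict: one master seed spawns per-block child seeds, so
identical configurations produce bit-identical tables, and the
configuration plus latent truth (case indicator and linear predictor) are
attached to the output as attributes.

Two constructions deserve emphasis. The generator inverts the real causal
order of spirometry and status — status is drawn first and spirometry
back-filled — because the point is control over effect sizes, not
physiological realism. And the `additive` risk scale
(P = p₀ + d_FH·FH + d_PRS·PRS_top, risk differences exactly additive) exists
specifically as the null model for RERI: with γ = 0 on the logit scale but
non-null main effects, RERI is genuinely positive (multiplicative ORs are
super-additive), so additive-null calibration needs its own generator.
Type-I-error calibration of both interaction tests instead uses the
complete null (all effects zero), where both the multiplicative and the
additive null hold simultaneously.

What the generator does **not** emulate: linkage structure or genotypes
behind the PRS (the score is a single column by design; its construction
from GWAS weights is out of scope), ancestry confounding (the principal
components are pure noise), longitudinal follow-up, informative
missingness, or measurement error in family history. Passing tests
therefore demonstrate that the estimators recover the truth under the
assumed structure — not that the structure matches any particular real
cohort. The known biases of real family-history data (recall error, which
attenuates the indirect effect estimate upward or downward depending on
which variable is mismeasured) are outside what these simulations can show.

## Problem sizes and numerical conventions

The test suite exercises parameter recovery at n = 50,000 per seed over 20
seeds (coverage of the generating ORs within 3 asymptotic SEs), mediation
recovery at n = 100,000 with a rare outcome, null calibration of the
interaction tests over 1000 replicates of n = 1200, and bootstrap oracles
with 5000 (RERI) and 10,000 (DeLong) replicates — sizes chosen so
Monte-Carlo error is comfortably inside the asserted bands while the whole
suite stays quick. Tolerances on stochastic checks were derived from
asymptotic standard errors before running, not tuned afterwards; the
mediation bands are wider than pure sampling error because the
product-of-coefficients oracle itself carries O(prevalence) approximation
bias on the odds-ratio scale.

Other conventions, collected in one place: complete-case analysis per model
(a record missing any model variable is dropped for that model only);
female is the reference sex coding; normality for the characteristics table
is judged by Shapiro–Wilk at α = 0.05 on at most 5000 subsampled values per
group (mean (SD) with t-tests when both groups pass, median (IQR) with
Wilcoxon otherwise — the table's p-values are descriptive); frequent
exacerbations means strictly more than one exacerbation in the prior 12
months, which for integer counts is the same as "two or more per year";
and Bonferroni thresholds are reported as annotations, never applied as
filters.

## Known limitations

Mediation and interaction estimates inherit all the usual causal caveats
(no unmeasured confounding, correctly specified outcome model, no
exposure-induced mediator–outcome confounding). The attributable-fraction
formulas assume OR ≈ RR. DeLong comparisons of nested models are
anticonservative. SGRQ-scale effects in the single digits may indicate an
upstream transformation in any external data being analysed; the package
fits the outcome as supplied and leaves transformation to the caller.
E-values, multiple mediators, survival endpoints and multiple imputation
are out of scope.
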