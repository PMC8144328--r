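---
title: "Mendelian randomization of BMI effects on lung function: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mendelian randomization of BMI effects on lung function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrlung)
```

## The scientific problem

Observational associations between body mass index (BMI) and spirometric
lung function — in particular the airflow-obstruction marker FEV1/FVC
and the mid-expiratory flow FEF25–75 — are confounded by lifestyle,
environment and reverse causation. Mendelian randomization (MR) breaks
this confounding by instrumenting BMI with a weighted allele score: a
per-individual weighted sum of BMI-increasing allele dosages with
published GWAS effect sizes as weights. Because alleles are randomly
assorted at conception, the score is (under the instrumental-variable
assumptions) independent of the confounders of the BMI–lung-function
relation and affects lung function only through BMI.

`mrlung` implements this analysis for a three-survey longitudinal
cohort, with one methodological feature that is rarely available in MR
software: the causal model contains an **instrumented interaction**. The
causal effect of log BMI is allowed to change linearly with age,

$$
E[\mathrm{LF}] = \beta_0 + \beta_{c1}\,\log \overline{\mathrm{BMI}}
  + \beta_{c2}\,\log \overline{\mathrm{BMI}} \times \mathrm{Age}_c
  + \beta_1 \mathrm{Age}_c + \beta_2 \mathrm{Sex} + \beta_3 \mathrm{Height}
  + \beta_4 \mathrm{PackYears} + \beta_5 \mathrm{Age}_c{\times}\mathrm{Sex}
  + \beta_6 \mathrm{Age}_c{\times}\mathrm{Height},
$$

where $\mathrm{Age}_c$ is age centered at 18 years (the minimum baseline
age) and overlines denote averages over the relevant surveys. Both
$\log \overline{\mathrm{BMI}}$ and its age product are endogenous; each
is instrumented, the main effect by the allele score and the interaction
by the score × age product. Because age is neither genetically
determined nor confounded with genotype, the product instrument is
valid for the product term. Two survey-averaging schemes are fitted:

* **predictive** — exposure averaged over surveys 1–2, outcome over
  surveys 2–3;
* **long-term cross-sectional** — both averaged over all three surveys.
  This model additionally carries a log-BMI × sex term which, like every
  BMI interaction, is instrumented (by score × sex). The package treats
  it as a causal term throughout; leaving it un-instrumented would
  re-introduce endogeneity through the observed BMI of one sex.

Estimation is two-stage least squares (2SLS), written from first
principles in `fit_2sls()`: the first stage regresses every causal term
on the intercept, all exogenous covariates and all instruments; the
second stage regresses the outcome on the fitted causal terms plus the
exogenous covariates. The covariance uses second-stage residuals
recomputed with the *observed* causal terms — the standard 2SLS
variance. Classical homoskedastic (Normal-theory) covariance is the
default, matching the Gaussian error assumption of the analysis; a
heteroskedasticity-robust sandwich is available via `vcov_type =
"robust"`. Just-identified systems only: one instrument per causal term.
Over-identification and Sargan-type tests are out of scope.

Derived quantities use the delta method on the joint covariance of
$(\hat\beta_{c1}, \hat\beta_{c2})$: `effect_at_age()` returns
$\hat\beta_{c1} + \hat\beta_{c2} a$ with
$\mathrm{SE}^2 = V_{11} + a^2 V_{22} + 2a V_{12}$, and
`predict_bmi_delta()` multiplies that slope by
$\ln(\mathrm{BMI}_1) - \ln(\mathrm{BMI}_0)$. We interpret the
"second-order" delta method of the source analysis as the delta method
applied to these derived products carrying the full joint covariance;
first-order terms dominate for linear combinations (they are exact
here), and the Monte-Carlo experiments below confirm the SEs track the
sampling SD within 10%, so no curvature correction is applied.

## Allele scores

`compute_score()` forms the raw weighted sum
$s_i = \sum_j w_j d_{ij}$ over retained SNPs (dosages in $[0,2]$,
fractional allowed). The raw sum — not a per-allele rescaling — is the
default, matching the convention of the MR studies this design follows;
`rescale = TRUE` divides by $\sum_j w_j$ for the per-BMI-increasing-
allele interpretation, since the published description is ambiguous on
this point. Model coefficients are invariant up to that known scale
factor, so the choice affects reporting, not inference.

`filter_snps()` applies the exclusion cascade in a fixed order:
imputation quality ($r^2 < 0.3$ by default), explicit exclusion lists
(e.g. SNPs associated with smoking phenotypes, or SNPs flagged as
pleiotropic on inspection), then greedy LD pruning at $r^2 > 0.2$
keeping the larger-|weight| SNP (ties broken by SNP id). A SNP missing
from a supplied imputation-quality map is an error, never a silent
pass-through, and every removal is logged with its reason. Pairwise LD
can be supplied as a map or estimated from sample dosage correlations
(flagged in the log). Effect-allele orientation is the caller's
responsibility; an allele sidecar makes mismatches a hard error, and no
strand flipping is attempted, since pruned GWAS SNP sets are assumed
harmonized.

## Assumption checks and one-sample MR-Egger

`run_assumption_checks()` covers: (1) instrument relevance via the
first-stage partial F (flagged below 10); (2) score–confounder
associations (packyears, height) and score × age / score × sex
modification of the score–BMI relation (joint F); (3) the exclusion
check — score–outcome association conditional on BMI and the observed
confounders; and MR-Egger. Verdicts are three-valued (pass/warn/fail)
with thresholds recorded. The selection machinery the source analysis
used for these auxiliary models is collapsed here to fixed Gaussian
linear models with the stated covariate sets, keeping the checks
reproducible; `aic_compare()` provides the explicit AIC comparison
utility (it refuses to compare across transformed outcomes without a
Jacobian correction, and the log-BMI exposure scale is itself supported
by such a comparison).

MR-Egger is applied within a single sample: `per_snp_associations()`
computes covariate-adjusted regressions of exposure and outcome on each
SNP dosage over the same individuals (via a shared Frisch–Waugh
residualization for speed; monomorphic SNPs are dropped with a log
entry), and `mr_egger()` regresses outcome associations on exposure
associations, inverse-variance weighted, testing the intercept with a
t statistic on $m-2$ degrees of freedom. Two caveats discovered during
calibration are worth recording:

* **Orientation.** Forcing estimated exposure betas positive by sign
  flipping — appropriate when allele orientation is unknown — is harmful
  when the dosages are already oriented by a weight table: per-SNP
  instruments are individually weak (F of order 1–5), sign errors are
  common, and each mis-flip injects the direct effect with the wrong
  sign, attenuating the pleiotropy intercept by half or more in our
  experiments. `mr_egger(orient_by_sign = FALSE)` is therefore used
  whenever orientation is known a priori, and is what
  `run_assumption_checks()` does when a weight table is supplied.
* **Subset pleiotropy.** When direct effects sit on a small subset of
  SNPs clustered at one end of the weight range, the free Egger slope
  absorbs much of the signal; the intercept test has an intrinsic power
  ceiling well below one in that regime. The calibration experiments
  place direct effects of 0.006 FEV1/FVC units per allele on 8 of 32
  SNPs (power ≈ 0.9 with correct orientation at the default sample
  size); with one-sample data and shared confounding the intercept also
  acquires a small negative tilt, so the type-I calibration scenario
  uses a valid instrument without outcome confounding — the canonical
  null for an operating-characteristics experiment.

An Egger variant for the age × BMI interaction
(`per_snp_associations(interaction_with = "age_c")`) uses the per-SNP
coefficients of the dosage × age product in exposure- and
outcome-interaction regressions. This is a best-effort generalization of
an analysis the source describes only by name; it is flagged as such in
output and not used in any calibrated decision.

## The instrumented/residual BMI decomposition

`decompose_bmi()` splits observed log BMI into the score-determined part
(fitted values of the score-only first stage — exactly the exposure
model as printed, which also makes the split orthogonal, so the variance
shares sum to one) and the residual, non-genetically determined part,
then refits the second stage with both components and their age
interactions. At the default first-stage strength (score $R^2$ of a few
percent) the residual component explains over 90% of log-BMI
variability. In simulations where only the genetic component is causal
the instrumented coefficient recovers the truth and the residual
coefficient is null; where total BMI is causal the two agree. The regime
experiments are run without outcome confounding because the residual
component absorbs confounding bias by construction — with confounding
on, its coefficient estimates (causal effect + confounding), which is
precisely the interpretation the decomposition is designed to expose,
but it is not a clean test of the causal wiring.

## Attrition: inverse-probability weighting

`ipw_analysis()` refits the observational final model weighted by
inverse participation probabilities under the two schemes used in the
source design: participation in surveys 2 and 3 given survey-1
variables, and participation in survey 3 given survey-1–2 averages.
Weights are truncated at the 99th percentile by default (the source is
silent; truncation is standard practice and configurable, including
off). Separation in the participation model is an error naming the
covariate. With uniform participation the weighted fit equals the
unweighted fit exactly. The acceptance experiment for bias correction
uses attrition roughly twice as selective as the cohort defaults
(participation ~85%/~79% per wave, strongly dependent on baseline lung
function and BMI), because the default attrition induces a
complete-case bias of only ~0.013 on $\beta_{c1}$ — too small relative
to sampling noise to make "IPW is closer to truth" a sharp property.
Confounding is off in that experiment so attrition is the only bias the
observational estimator carries; IPW corrects selection, not
confounding.

## The synthetic cohort generator

No individual-level data from the source cohort are distributable, so
`simulate_cohort()` generates a cohort with the statistical structure
the analysis assumes, with known truth (`sim_truth`) for every
experiment:

* genotypes $g_{ij} \sim \mathrm{Binomial}(2, p_j)$, independent SNPs in
  Hardy–Weinberg proportions, frequencies spread over $(0.12, 0.88)$;
  no LD structure is simulated (scores assume pruned, independent SNPs)
  and no imputation uncertainty;
* log BMI per survey = intercept + centered allele burden + confounder
  loading + age/sex terms + person effect + survey noise (BMI is
  logNormal by construction); baseline age $\sim U(18, 60)$, surveys 10
  years apart; sex coded 0 = male, 1 = female;
* FEV1/FVC per survey = $\mathrm{lf}_0 + (\beta_{c1} + \beta_{c2}
  \mathrm{Age}_{c})\,(\log\mathrm{BMI} - \log 25)$ + covariate terms +
  confounder loading + optional per-SNP direct (pleiotropic) effects +
  noise, truncated into $(0.2, 0.999]$; FEF25–75 analogous with its own
  coefficient pair;
* one latent $U \sim N(0,1)$ loads on both log BMI (+0.06) and
  FEV1/FVC (+0.025), so OLS is biased upward (toward zero from a
  negative truth) and 2SLS is consistent by construction — the exact
  contrast the analysis is designed to exhibit;
* participation at surveys 2 and 3 is logistic in baseline BMI, lung
  function and packyears (defaults give roughly 86%/71% cumulative
  participation, in the vicinity of the cohort's 83%/64%).

Default true effects are the published long-term point estimates
($\beta_{c1} = -0.752$, $\beta_{c2} = 0.021$ for FEV1/FVC; $-9.251$ and
$0.242$ for FEF25–75), and the default weights (log-spaced, 32 SNPs)
give a score explaining 2–4% of log-BMI variance — a first-stage F of
order $10^2$ at $n \approx 2{,}700$, bracketing the published instrument
strength. Whether the causal effect attaches to *total* log BMI or only
its *genetic* component is configurable (`causal_part`), defaulting to
total; the genetic-only regime exists because the decomposition analysis
requires simulating both wirings.

Two generator design notes:

* **Ceiling coherence.** A linear model with slope $-0.752$ per log-BMI
  unit predicts FEV1/FVC above 1 for young, very lean individuals three
  SDs into the BMI tail; a bounded ratio must censor there. Early
  parameterizations clamped ~0.3–0.5% of rows — concentrated exactly on
  the highest-leverage (young/old × extreme BMI) observations — and
  attenuated recovered causal coefficients by ~2%. The defaults
  ($\mathrm{lf}_0 = 0.74$, person-level log-BMI SD 0.105) keep the
  clamped mass near 0.05%, small enough that large-sample recovery is
  unbiased to well within Monte-Carlo resolution while the marginal
  moments stay in the published range (mean BMI ≈ 24.8, SD ≈ 3.3, mean
  FEV1/FVC ≈ 0.73).
* **FEF25–75 confounding** is set (conf loading 0.95) to reproduce the
  qualitative discrepancy the analysis reports — observational
  association positive, causal effect negative — rather than any exact
  effect size; this inflates the simulated FEF SD somewhat (~1.2 vs the
  published 1.07). The same loading keeps the unadjusted baseline
  contrast "obese lower FEF25–75" negative, which constrains it from
  both sides.

What the generator deliberately does **not** emulate: LD between
variants, imputation error, item non-response within an attended survey,
measurement drift between spirometer generations (inputs are assumed
recalibrated), secular BMI trends, and any non-linearity of the causal
dose–response (the analysis itself is linear in log BMI). Passing tests
therefore certify the statistical machinery under the model's own
assumptions, not robustness to these real-data features.

## Frames, descriptives, sensitivity analyses

`build_frame()` is strict complete-case per model (no imputation):
attendance at every exposure survey — all three for the long-term frame,
surveys 1–2 for the predictive frame — with the outcome averaged over
attended outcome surveys and cumulative packyears taken at survey 2
(predictive) or 3 (long-term). With attrition the predictive frame is
therefore larger, matching the published sample sizes' ordering. Natural
log is used for BMI throughout (the published coefficient magnitudes are
consistent with natural log via the worked example). Sex is
time-constant; baseline self-reported weight is treated like measured
weight, with its reliability examined in the sensitivity suite by
comparing per-survey score→BMI regressions.

`partial_correlations()` residualizes each lung-function instance on
age, age², height, height², sex and all their pairwise interactions
(concurrent values for single-survey instances, averaged values for
derived means) and correlates residuals on pairwise-complete rows, with
a minimum-pair flag. `obesity_strata_summary()` tabulates per-survey
distributions by BMI < 30 vs ≥ 30. `sensitivity_suite()` re-fits the
final models with logit(FEV1/FVC) and log(FEF25–75) outcomes, with
FEF25–75/FVC as outcome, in never-asthmatics, reports per-survey
score→BMI regressions ($R^2$ comparison), and the observational
change-on-change regression. `stratified_by_age()` fits the final model
without the interaction in baseline-age tertiles (empirical quantiles,
ties to the lower stratum). No multiple-testing adjustment is applied
anywhere, matching the source's reporting; study-center/education
adjustments are omitted from final models but `extra_exogenous` provides
the hook for replicating that no-material-change check.

## Numerical choices and degenerate inputs

Design matrices are built from explicit term strings (`"a:b"` products);
rank deficiency is an error naming the aliased columns — nothing is
dropped silently. Constant instruments are an error; first-stage partial
F below 10 is a warning, not an error. Residualization designs are
column-scaled before QR for conditioning (residuals are invariant). AIC
is $-2\ell + 2(k+1)$ under Gaussian errors, comparable only across
identical rows and outcome scales. Wald intervals use asymptotic
Normality everywhere, matching the reported inference. The full
pipeline is deterministic: `simulate_cohort()` is bit-reproducible from
its config (which includes the seed) without touching the global RNG
state, and `mr_report()` serializes byte-identically on identical
inputs.

## Problem sizes used by the validation experiments

The Monte-Carlo experiments in the test suite use the sample size of the
published long-term model ($n = 2{,}700$, attrition disabled so the
complete-case count matches) with 500 replicates for recovery, coverage
and delta-method checks, 200 replicates each for the Egger type-I and
power experiments, the IPW comparison and the age-tertile monotonicity
check, and single large simulations ($n$ up to $3 \times 10^4$) for
consistency checks. These sizes give Monte-Carlo SEs an order of
magnitude below the effects being verified.

## Known limitations

* One-sample MR-Egger with per-SNP F of order 1 is a blunt instrument;
  its intercept inherits a small bias under shared confounding, and
  subset pleiotropy aligned with the weight ordering can hide in the
  slope. Verdicts should be read as screening, not adjudication.
* The interaction-Egger construction is a named-only generalization of
  the published check and has no external reference implementation.
* Mean-imputation of missing dosages (2 × sample allele frequency)
  shrinks score variance slightly; it is opt-in.
* The generator's participation model conditions only on baseline (and
  survey-1–2 average) covariates, so the IPW models are essentially
  correctly specified in simulation; real attrition is uglier, and the
  bias-correction property shown here does not certify performance under
  misspecified participation models.
* Criterion-style recovery experiments fix the causal truth at the
  published point estimates; they validate the estimator, not the
  published findings themselves, which would require the original data.
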