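---
title: "Methods: PRS modification of cancer penetrance in BRCA1/2 carriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PRS modification of cancer penetrance in BRCA1/2 carriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(carrierprs)
```

## The problem

Women carrying pathogenic variants in *BRCA1* or *BRCA2* face high average
lifetime risks of breast and epithelial ovarian cancer, but the risk is far
from uniform across carriers.  A polygenic risk score (PRS) — a weighted sum
of common risk-allele dosages, standardized to per-SD units — stratifies
that risk further.  `carrierprs` implements the analytic machinery needed to
quantify this stratification from carrier cohorts and to translate it into
absolute, age-specific risks:

1. PRS construction from SNP weight tables and genotype dosages
   (`read_weight_table()`, `compute_prs()`, `standardize_prs()`,
   `assign_percentiles()`);
2. outcome-specific censoring of a carrier cohort and calibration of
   sampling weights against external carrier incidence
   (`build_analysis_dataset()`, `calibrate_sampling_weights()`);
3. stratified weighted Cox regression with family-clustered robust
   variance, in continuous, categorical-percentile, age-varying and
   group-interaction forms (`fit_weighted_cox()` and relatives), plus
   Harrell's C with a cluster bootstrap and left-truncated prospective
   validation;
4. a constrained baseline-hazard solver converting per-SD hazard ratios
   and an average carrier incidence curve into penetrance curves by PRS
   percentile (`solve_constrained_hazard()`, `risk_by_percentile()`,
   `ten_year_risk()`);
5. a synthetic-cohort generator with the statistical structure the
   analysis assumes, so the whole pipeline is testable end to end
   (`simulate_retrospective_cohort()`, `simulate_prospective_cohort()`).

## PRS construction

A weight table supplies, per SNP, the effect allele and a per-allele
log-odds-ratio weight $w_i$; the raw score of carrier $j$ is
$\sum_i w_i g_{ij}$ with $g_{ij} \in [0,2]$ the effect-allele dosage.
Dosage files may count the opposite allele; `harmonize_dosages()` flips
$g \to 2-g$ when the allele pair is swapped.  Strand-ambiguous (A/T, C/G)
SNPs cannot be resolved from labels alone; they are matched by labels and
flagged with a warning, since the harmonisation conventions of the source
genotyping are outside the package's scope.

Missing dosages default to Hardy–Weinberg mean imputation ($2f_i$) when an
effect-allele frequency is available, mirroring the convention for imputed
dosage data; the policy is configurable.

Standardization divides the *centred* raw score by an externally estimated
reference SD.  Centring is a deliberate choice: only the SD affects hazard
ratios, and centring makes the median of the standardized score
approximately zero, which is convenient for percentile work.  Per-SD hazard
ratios estimated on this scale are directly comparable with per-SD odds
ratios from population-based studies.

Percentile categories use type-7 empirical quantiles of the score in a
reference group — by convention the carriers unaffected by the disease
under assessment — with half-open `[lower, upper)` bins, so a score exactly
at a threshold joins the upper category.  The default nine reporting
categories are 0–5, 5–10, 10–20, 20–40, 40–60 (reference), 60–80, 80–90,
90–95 and 95–100.

## Censoring rules

For the breast-cancer outcome a carrier is followed from birth (age is the
time scale) to the first of: breast cancer diagnosis, ovarian cancer
diagnosis, risk-reducing bilateral mastectomy, last follow-up, or age 80.
ER-specific outcomes keep the same censoring but count only diagnoses of
the matching estrogen-receptor status as events; an opposite-status
diagnosis censors at its age, and carriers whose breast cancer has unknown
ER status are excluded because they cannot be classified for either
subtype.  The ovarian outcome censors at risk-reducing
salpingo-oophorectomy instead of mastectomy.  Whether a breast-cancer
diagnosis also censors the ovarian analysis is not uniquely determined by
the description of the analysis as "a similar process"; the package
defaults to censoring (treatment after a breast diagnosis changes ovarian
risk and surveillance) and exposes `censor_ovarian_at_bc = FALSE` for the
alternative reading.

## Ascertainment correction

Carrier cohorts recruited through cancer genetics clinics oversample
affected women, so an unweighted Cox fit is biased — typically towards the
null, because risk sets contain too many survivors of high polygenic risk.
The weighted-cohort correction assigns age- and disease-specific sampling
weights such that the weighted age-specific incidence agrees with external
carrier incidence.  The exact weighting scheme in the source literature is
not spelled out at formula level, so the package uses the minimal scheme
with the required property: within each age bin $j$ of the age at which
follow-up ends,

$$w_{\text{aff}} = p_j / q_j, \qquad
  w_{\text{unaff}} = (1-p_j)/(1-q_j),$$

where $q_j$ is the observed affected fraction among exits in the bin and
$p_j$ the expected fraction — the external hazard integrated over the
cohort's person-time in the bin, divided by the number of exits.  The
weighted affected fraction in each bin then equals $p_j$ exactly.  Default
bins are 18–25, 5-year bins to 70, then 70–80; the tails are wider because
affected exits are sparse there in cohorts of moderate size.  With
`merge_sparse = TRUE` a degenerate bin (all exits affected or none) is
merged into its left neighbour with a warning instead of stopping, which
unattended simulation pipelines need; the default remains an error so that
interactive users see the problem.

In simulation this estimator is effectively unbiased at realistic scale:
with 5,000-carrier cohorts, half affected, the mean recovered per-SD HR
over 50 replicates was 1.290 against a generating value of 1.29, and the
95% robust CI covered the truth in 94% of replicates (the suite's
acceptance tests recompute this).  For rare outcomes with strong
oversampling the correction is slightly conservative — a percent or two on
the HR — which is logged as a known limitation rather than hidden.

## Cox models

`fit_weighted_cox()` maximises the weighted stratified partial likelihood
via `survival::coxph` (Efron ties by default, appropriate for
year-recorded ages), stratifying by country × Ashkenazi ancestry and
clustering robust variances on family.  With unit weights, one stratum and
entry at age 0 it reduces to a textbook Cox fit; the test suite pins it to
a brute-force risk-set enumeration on small data and to the closed-form
three-subject solution $\hat\beta = -\tfrac12\ln 2$.

The age-varying model treats the PRS as a time-varying covariate on the
age scale, $\beta(t) = \beta_0 + \beta_1 (t - c)$, by episode-splitting so
the covariate at risk-set age $t$ is $z \cdot (t - c)$.  Splitting at every
distinct event age is exact and is the default for modest cohorts; for
large cohorts episodes are cut at integer ages, evaluating a risk-set
member's interaction covariate at the end of its current year of age (at
most one year late, matching the resolution of year-recorded ages).

Likelihood ratio tests on weighted fits compare weighted
pseudo-log-likelihoods against a chi-square reference; this is an
approximation (weights invalidate the usual likelihood asymptotics), so
the function emits a note whenever non-unit weights are present.  The
categorical-versus-continuous comparison adds the percentile indicators on
top of the continuous score and tests the added terms, since a categorical
model is not literally nested in a continuous one.

Harrell's C is computed on the fitted linear predictor within strata and
pooled over usable pairs, with standard errors from a bootstrap that
resamples whole families; the resampling respects the within-family PRS
correlation that makes carrier observations non-independent.  How exactly
the published concordance pooled pairs across strata is not specified;
within-stratum pooling weighted by usable pairs is the package's choice.

Prospective validation uses left truncation: entry at recruitment age,
carriers affected at or before recruitment excluded, no sampling weights
(prospective person-time is not subject to prevalent-case ascertainment).

## Constrained absolute risks

Given a per-SD log hazard ratio $\beta$ and an external average carrier
incidence curve $\bar\lambda(t)$, the solver discretizes the
standard-normal PRS into $K$ categories (default 201 equal-probability
bins, each represented by its truncated-normal mean) and finds the
baseline hazard $\lambda_0(t)$ such that the prevalence-weighted average
annual disease probability among still-unaffected women equals the
external annual probability at every age:

$$\sum_k p_k S_k(t)\, e^{-\lambda_0(t) RR_k(t)}
  = e^{-\bar\lambda(t)} \sum_k p_k S_k(t),
  \qquad RR_k(t) = e^{\beta(t) z_k}.$$

Each annual equation is solved by Newton iteration, started at the
first-order ratio $\bar\lambda \sum p_k S_k / \sum p_k S_k RR_k$;
survivals are then depleted multiplicatively.  Solving the conservation
equation exactly in probability form (rather than using the first-order
ratio alone) makes the mixture-average cumulative risk reproduce the
external cumulative risk to solver precision ($<10^{-10}$), so an input
curve built to a 72% average risk by age 80 returns exactly 72% as the
category-averaged risk.  Depletion of susceptibles emerges naturally:
high-PRS categories thin out of the unaffected pool, so $\lambda_0$ sits
above the naive $\bar\lambda / E[RR]$ at older ages.

Headline percentile risks are evaluated at exact quantiles
$z = \Phi^{-1}(p)$ using the solved $\lambda_0$; the 201-bin mixture is
fine enough that doubling it moves percentile risks by well under half a
percentage point.  Ten-year risks are conditional:
$[F(a{+}10) - F(a)] / [1 - F(a)]$.  The solver supports both an
age-constant and an age-declining $\beta(t)$; the constant per-SD estimate
is the default, since which variant produced the published risk figures is
not stated.  The model is single-decrement (no competing mortality),
matching the penetrance convention for carrier risks, and no confidence
intervals are produced for predicted risks — they depend on external
incidence estimates whose uncertainty the package does not model.

Published extreme-percentile risks were derived from external
age-specific carrier incidence curves that are not redistributable; the
package ships no copy of them.  With fixture curves matched only to the
printed *average* risks, percentile risks are structurally correct
(ordered, bracketing the average, conserving it) but their exact values
depend on the curve's age shape; users with access to the external curves
can supply them as `incidence_curve` objects and reproduce the published
figures directly.

## The synthetic-cohort generator

The generator encodes the assumptions the analysis makes, and it is the
package's substitute for confidential consortium data:

* standard-normal standardized PRS, correlation 0.5 between relatives
  (families of size 1–3 with a shared Gaussian component);
* proportional hazards: individual hazard
  $\lambda_0(t)\, e^{\beta(t) z}$, with $\lambda_0$ derived from the
  configured *average* carrier incidence curve via the constrained solver,
  so the simulated marginal incidence reproduces the input curve by
  construction;
* event ages drawn by inverse-CDF on an annual grid with uniform jitter
  within the year, so ties resemble year-recorded ages;
* competing censoring: risk-reducing mastectomy (exponential from age
  30), RRSO (exponential from age 35), and a uniform age at last
  follow-up on 20–80;
* clinic-style ascertainment as two-phase outcome-dependent sampling:
  affected carriers are included preferentially until a target affected
  fraction is met — the simplest mechanism that produces nonrandom
  sampling with respect to disease status;
* ER status assigned to breast cases with configurable positive and
  missing fractions (defaults 0.35 and 0.30);
* all randomness flowing from a single seed, with the generating
  parameters returned as a truth record.

Default study conditions follow the published cohort composition: breast
analyses use cohorts half affected (the retrospective consortium cohorts
were close to 50% affected), while ovarian analyses use affected fractions
of about 11% (*BRCA1*) and 6% (*BRCA2*), as observed in those analyses.
Parameter-recovery experiments at 20,000 carriers and coverage checks at
5,000 carriers × 50 replicates keep the suite inside desk-scale compute;
these sizes give Monte-Carlo SEs of 0.01–0.03 on the log HR, small enough
to detect meaningful bias.

What the generator does *not* emulate — and therefore what passing tests
cannot vouch for on real data: genotyping and imputation noise, country
composition and country-specific incidence, informative recruitment-age
distributions, correlated family-history covariates (family history is
simulated as an independent covariate, not generated from the family's
latent risk), full pedigrees beyond sib-sized clusters, and real
ascertainment mechanisms, which are only qualitatively clinic-based.
Estimates on real cohorts depend on those features; the tests show the
estimators are correct under the stated model, not that the model is
right.

## Numerical choices and edge cases

* Newton solves of the conservation equation stop at a relative step of
  $10^{-14}$; identical inputs give bit-identical surfaces.
* Cox fitting inherits `survival`'s convergence machinery; coefficients
  beyond $|\beta| > 15$ are reported as suspected monotone likelihood.
* Collinear covariates are rejected by a rank check before fitting.
* Degenerate percentile references (all values equal, or fewer reference
  carriers than categories) are errors, as are calibration bins with no
  exits or with affected fractions of 0 or 1 (unless `merge_sparse`).
* Quantile ties go to the upper half-open bin; weight-table alleles must
  be single A/C/G/T bases and effect ≠ other.
* The `run_*` report functions write seed-stamped CSVs and are
  deterministic under a fixed seed.

## Command-line use

The package is a library, not a shell tool: the `run_retrospective()`,
`run_prospective()` and `run_risk_prediction()` functions, driven by an R
script or a YAML configuration (`read_run_config()`), are the intended
orchestration surface, and `scripts/acceptance.R` in the source repository
shows a complete scripted run.
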