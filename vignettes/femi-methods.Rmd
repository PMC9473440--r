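---
title: "Methods: scoring, harmonization and estimation in femi"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring, harmonization and estimation in femi}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(femi)
```

`femi` estimates six domains of women's empowerment — intimate partner
violence attitudes, access to family planning, reproductive healthcare,
employment, education, and household decision-making — for first-level
administrative subdivisions (admin-1) at fixed reference years, from
DHS-style survey microdata, and combines them into the Female Empowerment
Index (FEMI). This vignette explains the model and its assumptions, the
parameters that matter, the synthetic-data generator that the test suite
uses for parameter recovery, and the numerical and design choices we made
where the procedure left room.

## Respondent scoring

Every survey answer is coded to a 0–1 empowerment value and a domain score
is the mean of its coded categories *over the categories available for that
respondent*. Partial availability is the norm, not the exception: a woman
with no birth in the last three years has no antenatal category; a survey
may not have asked the literacy question. We average over what is present
rather than declaring the domain missing, which preserves sample size and
matches a pipeline that imputes only question blocks that are absent
wholesale. Each scorer returns `NA` only when *no* constituent category is
available. The alternative (strict complete-case domains) would discard
most respondents in older surveys.

Three conventions deserve a note:

* **Never-married women** score 1 on the IPV child-marriage category (no
  child marriage occurred). Decision-making and family planning are scored
  only for currently married women, mirroring who is asked those questions.
* **Unemployed respondents** get a payment-type score of 0 even when the
  payment question was not asked — unemployment determines the payment
  outcome.
* **Decision-making** uses all five decision questions (health, large
  purchases, family visits, cooking, money) with the score averaged over
  the questions answered.

Respondent scores are aggregated to survey regions by weighted mean using
the per-respondent sampling weight. Whether the original analysis applied
sampling weights is not documented; we default to weighting
(`use_weights = TRUE`) because region-level inference from a stratified
sample is the stated goal, and expose the switch for sensitivity analysis.

## Gender-inequality adjustment

Education and employment scores are computed for women and men separately
and the women's region score is multiplied by the women:men ratio:
adjusted = `w * (w / m)`, clamped to [0, 1]. Regions where both genders
score low (shared poverty) are unaffected; regions where men outscore women
are pulled down. Two degenerate cases are defined explicitly: `m = 0` with
`w > 0` applies no adjustment (the ratio is undefined and the data show no
male advantage), and `w = m = 0` gives 0. Clamping at 1 handles regions
where women outscore men; the unclamped product is available
(`clamp = FALSE`) because the adjustment's monotonicity properties are only
testable pre-clamp. The adjustment is applied at region level to aggregated
scores, not per respondent, and *after* imputation, so that imputed men's
scores can support it.

## Imputation

Surveys, especially older ones, omit whole question blocks. Missing
region–domain scores are estimated by random-forest regression pooled
across all surveys: predictors are survey year, country, region means of
age at first marriage, age at first birth, years of schooling, respondent
age, births in the last five years, and the region centroid
(longitude/latitude). For the education domain the years-of-schooling mean
is dropped (it is the outcome's own ingredient). Men's education and
employment are imputed from year, longitude and latitude only, because the
other predictors come from the women's questionnaire. Forests use 500 trees
and package-default feature subsetting, with a fixed seed derived from the
run seed; predictions are clamped to [0, 1] and flagged
`provenance = "imputed"`; observed rows are never altered. We require at
least 20 observed rows before fitting a domain's model — below that a
forest fit is too unstable to be worth reporting, and the domain is skipped
with a diagnostic. Pooling one model per domain (rather than per survey)
follows from year and country appearing in the predictor list.

## Boundary harmonization

Older surveys often report on aggregations of today's admin-1 units, or on
schemes that changed between rounds. Scores are converted onto current
admin-1 units in one of two ways, chosen automatically per survey:

* **Bracketed**: when admin-1 surveys exist before and after the
  non-standard survey, each admin-1 unit gets the year-weighted mean of its
  bracketing scores, and a per-super-region multiplicative factor rescales
  the members so the weighted super-region mean reproduces the observed
  value exactly.
* **Single-predictor**: with only one admin-1 survey available, the
  predictor's values are aggregated to the super-regions, and each member
  is shifted additively by the observed-minus-aggregate difference.

Aggregation weights are the bracketing (or predictor) survey's per-domain
sample counts, falling back to female population when counts are absent —
the aggregate being preserved is "the regional mean" and sample counts are
what the original aggregation used. Where an observed super-region value or
an interpolated aggregate is exactly 0 the multiplicative factor is
undefined, and the bracketed method switches to the additive shift.
Clamping to [0, 1] is applied after, never during, factor application, so
aggregate preservation is exact pre-clamp (the tests verify it to 1e-9).
Partial-country surveys need no special casing here: estimation assesses
survey availability per region, so a survey covering only the south of a
country simply contributes nothing to northern regions (this also covers
the split-country interpolation case generically).

## Reference-year estimation

Each (region, domain) gets exactly one estimate per reference year, by a
three-way rule on the surveys available *for that region*:

1. **direct** — a survey within ±2 years is reassigned to the reference
   year. With two qualifying surveys the nearer wins; an exact tie goes to
   the later survey (more current fieldwork).
2. **linear** — otherwise, with two or more surveys, an OLS line through
   all of the region's (year, score) points is evaluated at the reference
   year and clamped. We fit on all available points, not just the outer
   two; with exactly two points this is the interpolating line. A series
   with a single distinct year falls back to its mean.
3. **rf** — otherwise a random forest predicts the score from HDI and
   maternal mortality (country-year), population density (region), and the
   region's own survey value when one exists. The forest is trained on all
   direct/linear region-year estimates, pooled continent-wide, one model
   per domain. Targets that have a survey of their own are predicted with
   the survey-value feature; targets with none use a covariates-only
   forest — a median-filled constant would poison the feature, not proxy
   it.

Random forests interpolate but do not extrapolate: a never-surveyed country
whose covariates lie outside the surveyed countries' range will be
predicted at the boundary of the training span. This is a real limitation
of covariate-based gap-filling and is visible in the tests, which evaluate
the RF branch on an interior-covariate country.

FEMI is computed last, as the arithmetic mean of the six domain estimates —
only after imputation and estimation guarantee all six are present. A
median combiner is available (`combiner = "median"`) since a median-based
description of the composite is sometimes preferred; the mean is the
definition.

## Summary statistics

Population-weighted quantiles use the left-continuous cumulative-weight
rule: the q-quantile is the smallest value whose normalized cumulative
weight reaches q. With equal weights this is the inverse empirical CDF
(`quantile(type = 1)`), which the tests pin down. Weights are per-region
female population, reading "for all women" as weighting regions by the
women they contain. Continental summaries report the weighted median and
10th/90th percentiles per domain and year; within-country inequality is the
weighted p90 − p10 across a country's admin-1 units; cross-domain Pearson
correlations use each country's most recent survey; national regressions
fit FEMI on HDI, GDI, GII and log10 GDP per capita by OLS. The age-cohort
check (`cohort_sensitivity()`) compares weighted scores of the 18–30
subsample against 18–49 for the recall-sensitive domains (child marriage,
reproductive healthcare, education).

## The synthetic-data generator

`simulate_surveys()` draws complete survey bundles from known latent
scores: per-domain baselines with a latitude gradient (emulating the
north–south continental gradient), a linear annual trend, an optional
per-country level shift, lognormal or unit sampling weights, region schemes
that change between rounds (`aggregated:k` merges a country's regions into
latitude-contiguous super-regions), omitted question blocks, and
partial-country coverage. Answers are drawn so that every coded category
has expectation exactly equal to the region's latent score — three-point
distributions (e.g. antenatal visits on {0, 2, 4}) solve the expectation
constraint for the intermediate codes — which makes the whole pipeline
testable by parameter recovery, with the generator's `truth` table as the
oracle. Men's latent scores are the women's divided by the `gap_ratio`
(default 0.9, women scoring 90% of men), so the gender adjustment has a
known target.

Deliberate idealizations, and what they mean for the tests: all simulated
women are currently married and have had a child, so every domain applies
to every respondent and region means are unbiased for the latent scores
(never-married women would force two categories to 1 by construction);
there is no cluster sampling, nonresponse, or interviewer effect; latent
noise defaults to 0 so deviations are pure sampling noise. Passing recovery
tests therefore show the pipeline's stages are correct and unbiased under
clean sampling — they do not certify behavior under the messier designs of
real surveys.

Test problem sizes, chosen to make sampling noise small relative to the
tolerances while keeping the default suite quick: single-region unbiasedness
uses 200 seeds at 1,000 women/region (binomial SE ≈ 0.016 per seed, ≈ 0.001
over seeds against a 0.005 bias bound); the end-to-end FEMI recovery uses a
10-country × 5-region continent at 1,000 women/region with surveys in
1994/2004/2014; imputation recovery uses 100 seeds of a 6-country ×
4-region design at 150 women/region with one survey's IPV block deleted.

## Known limitations

* The antenatal-visit threshold is applied per birth and averaged across a
  woman's recent births; whether visits should instead be totalled per
  woman is ambiguous in the source material.
* Child marriage is read from age at first marriage; first cohabitation is
  not distinguished.
* Point estimates only: no uncertainty propagation through imputation,
  harmonization or extrapolation.
* The RF extrapolation branch cannot leave the training covariate span
  (see above), and for never-surveyed countries it captures only
  between-country variation — within-country structure is invisible to
  country-level covariates.
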