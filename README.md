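# femi

Subnational women's empowerment estimation from DHS-style survey microdata.

Nationally representative household surveys (such as the Demographic and
Health Surveys) ask women directly about the decisions they can make, the
work they do, the schooling they received, the healthcare they got during
pregnancy, and their attitudes to partner violence. `femi` turns those
respondent-level answers into comparable **admin-1 (state/province) scores
for six empowerment domains** and a composite, the **Female Empowerment
Index (FEMI)**, at fixed reference years — the kind of subnational series
needed to see where progress is happening and where it is not. It is aimed
at quantitative social scientists and epidemiologists working with survey
microdata across many countries and survey rounds.

## The method

Every answer is coded on a 0 (disempowerment) to 1 (empowerment) scale and
averaged into six domain scores per respondent:

| Domain | Coding |
| --- | --- |
| Intimate Partner Violence | mean of two categories: share of five "is beating justified ..." questions answered *no*, and 1 unless married before age 18 |
| Family Planning | modern contraceptive use, among married women not wanting a child within 2 years |
| Reproductive Healthcare | mean of four categories over births in the last 3 years: antenatal visits (0 / 0.5 for 1–3 / 1 for 4+), professional delivery, postnatal check, and no adolescent childbearing |
| Employment | mean of work regularity (1 / 0.5 / 0) and payment type (1 cash / 0.75 mixed / 0.5 in-kind / 0 unpaid) |
| Education | mean of (≥ 6 years schooling) and literacy |
| Decision-Making | share of five household decisions the woman has a say in |

Respondent scores are aggregated to survey regions with sampling weights.
Education and Employment are computed for men too and the women's score is
multiplied by the women:men ratio (`w · w/m`, clamped to [0, 1]) so that
gender gaps — not shared poverty — lower the score. Region–domain scores a
survey did not measure are imputed by random-forest regression on survey
year, country, region demographics and centroid. Scores reported on
historical or aggregated region schemes are harmonized onto current admin-1
units by one of two interpolation procedures that preserve the observed
super-region aggregates exactly. Estimates for the reference years (1995,
2005, 2015 by default) then come from a three-way rule per region: a survey
within ±2 years is reassigned directly; two or more surveys give a linear
trend; otherwise a random forest predicts from HDI, maternal mortality,
population density and the region's own survey value where available.
FEMI is the arithmetic mean of the six domain estimates, summarized with
population-weighted medians and 10th–90th percentile ranges.

A synthetic-data generator (`simulate_surveys()`, `make_fixture()`) draws
whole multi-country survey bundles with known latent scores, latitude
gradients, annual trends, scheme changes and missing question blocks, so
every stage of the pipeline is validated by parameter recovery.

## Worked example

```r
library(femi)
sim <- make_fixture("tiny-2country", seed = 1)   # 2 countries x 3 regions, surveys 2004 & 2014
fit <- femi(sim$surveys, sim$regions, sim$crosswalk, sim$covariates, seed = 1)
fit
#> Subnational empowerment estimates (FEMI)
#>   surveys: 4   admin-1 regions: 6   reference years: 1995, 2005, 2015
#>   estimates by method: direct=72  linear=36
#>   FEMI 1995: median 0.387 across 6 regions
#>   FEMI 2005: median 0.448 across 6 regions
#>   FEMI 2015: median 0.542 across 6 regions
```

2015 is covered by the 2014 surveys (within the ±2-year window), so its 72
domain estimates are direct reassignments; 1995 predates both surveys and is
linearly extrapolated. The population-weighted continental summary:

```r
subset(summary(fit)$continental, year == 2015)
#>  year                  domain       p10       p50       p90
#>  2015         decision_making 0.3966667 0.5433333 0.6616667
#>  2015               education 0.2132966 0.4112251 0.5347711
#>  2015              employment 0.2356538 0.5461534 0.6918630
#>  2015         family_planning 0.3292683 0.4186047 0.6666667
#>  2015                    femi 0.3750161 0.5284269 0.6411971
#>  2015                     ipv 0.4291667 0.6150000 0.6850000
#>  2015 reproductive_healthcare 0.4572917 0.6135417 0.7479167
```

Each row is the population-weighted median and 10th/90th percentile of the
regional scores: e.g. the median region scores 0.53 on FEMI in 2015, with
the 10th–90th percentile band [0.38, 0.64] describing subnational
inequality. `summary(fit)` also returns per-country 10–90 ranges,
cross-domain Pearson correlations, and national regressions of FEMI on HDI,
GDI, GII and log GDP. The file-level pipeline (`run_pipeline()`) persists
every stage as CSV with an md5 manifest.

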