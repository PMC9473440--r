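fake_estimates <- function(values_by_domain, year = 2015,
                           regions = paste0("r", seq_len(
                             length(values_by_domain[[1]])))) {
  do.call(rbind, lapply(names(values_by_domain), function(d) {
    data.frame(admin1_id = regions, country_code = "C", year = year,
               domain = d, estimate = values_by_domain[[d]],
               method = "direct", n_surveys_used = 1L,
               stringsAsFactors = FALSE)
  }))
}

all_domains <- c("ipv", "family_planning", "reproductive_healthcare",
                 "employment", "education", "decision_making")

test_that("FEMI is the arithmetic mean of the six domains", {
  vals <- as.list(setNames(c(0.3, 0.4, 0.5, 0.6, 0.7, 0.8), all_domains))
  est <- fake_estimates(lapply(vals, function(v) v))
  out <- compute_femi(est)
  expect_equal(out$estimate[out$domain == "femi"], 0.55)
  # all-equal and all-zero cases
  est0 <- fake_estimates(setNames(rep(list(0), 6), all_domains))
  expect_equal(compute_femi(est0)$estimate[7], 0)
  estc <- fake_estimates(setNames(rep(list(0.42), 6), all_domains))
  out <- compute_femi(estc)
  expect_equal(out$estimate[out$domain == "femi"], 0.42)
  # idempotent: femi rows are recomputed from domains only
  again <- compute_femi(out[out$domain != "femi", ])
  expect_equal(again, out, ignore_attr = TRUE)
  # median combiner switch
  vals <- setNames(as.list(c(0, 0.1, 0.5, 0.5, 0.9, 1)), all_domains)
  est <- fake_estimates(vals)
  expect_equal(compute_femi(est, "median")$estimate[7], 0.5)
})

test_that("a missing domain makes FEMI an error naming the region", {
  est <- fake_estimates(setNames(rep(list(0.5), 5), all_domains[-1]))
  expect_error(compute_femi(est), "ipv")
})

test_that("weighted quantiles use the cumulative-weight rule", {
  expect_equal(unname(weighted_quantile(c(0.2, 0.5, 0.8), probs = 0.5)),
               0.5)
  expect_equal(unname(weighted_quantile(c(0.2, 0.5, 0.8), c(1, 1, 2),
                                        0.5)), 0.5)
  expect_equal(unname(weighted_quantile(c(0.2, 0.5, 0.8), probs = 0)),
               0.2)
  # heavier tail drags the quantile
  expect_equal(unname(weighted_quantile(c(0.2, 0.5, 0.8), c(1, 1, 6),
                                        0.5)), 0.8)
  expect_error(weighted_quantile(numeric(0)), "no non-missing")
  expect_error(weighted_quantile(c(1, 2), c(0, 0)), "not all zero")
})

test_that("equal-weight quantiles match the inverse empirical CDF", {
  set.seed(13)
  for (rep in 1:20) {
    x <- runif(sample(3:40, 1))
    probs <- runif(5)
    expect_equal(unname(weighted_quantile(x, probs = probs)),
                 unname(quantile(x, probs = probs, type = 1)))
  }
})

test_that("subnational ranges are the weighted p90 minus p10", {
  est <- compute_femi(fake_estimates(setNames(
    rep(list(rep(0.4, 4)), 6), all_domains)))
  regions <- data.frame(admin1_id = paste0("r", 1:4), country_code = "C",
                        longitude = 0, latitude = 0,
                        female_population = 1, pop_density = 1)
  rng <- country_subnational_range(est, regions, 2015)
  expect_true(all(rng$range == 0))
  vals <- seq(0.1, 1, by = 0.1)
  est <- fake_estimates(list(ipv = vals))
  regions <- data.frame(admin1_id = paste0("r", 1:10), country_code = "C",
                        longitude = 0, latitude = 0,
                        female_population = 1, pop_density = 1)
  rng <- country_subnational_range(est, regions, 2015)
  q <- quantile(vals, c(0.1, 0.9), type = 1)
  expect_equal(rng$range, unname(q[2] - q[1]))
  est <- fake_estimates(list(ipv = c(0.2, 0.8)), regions = c("r1", "r2"))
  rng <- country_subnational_range(est, regions[1:2, ], 2015)
  expect_equal(rng$range, 0.6)
})

test_that("domain correlations use the latest survey and are symmetric", {
  h <- expand.grid(admin1_id = paste0("r", 1:20),
                   domain = all_domains, stringsAsFactors = FALSE)
  h$survey_id <- "s2"; h$country_code <- "C"; h$survey_year <- 2014
  set.seed(5)
  x <- runif(20)
  h$score <- NA_real_
  for (d in all_domains) h$score[h$domain == d] <- x
  h$score[h$domain == "education"] <- 2 * x + 1  # perfectly collinear
  # an older survey with pure noise must be ignored
  old <- h; old$survey_id <- "s1"; old$survey_year <- 2000
  old$score <- runif(nrow(old))
  cm <- domain_correlations(rbind(h, old))
  expect_equal(cm["ipv", "education"], 1.0)
  expect_equal(cm["ipv", "ipv"], 1.0)
  expect_equal(cm, t(cm))
})

test_that("independent domains show near-zero correlation", {
  set.seed(77)
  h <- do.call(rbind, lapply(all_domains, function(d)
    data.frame(admin1_id = paste0("r", 1:500), domain = d,
               survey_id = "s1", country_code = "C", survey_year = 2014,
               score = runif(500), stringsAsFactors = FALSE)))
  cm <- domain_correlations(h)
  off <- cm[upper.tri(cm)]
  expect_true(all(abs(off) < 0.15))
})

test_that("national regressions recover an exact linear relation", {
  covs <- data.frame(country_code = paste0("C", 1:20), year = 2015,
                     hdi = seq(0.3, 0.8, length.out = 20),
                     maternal_mortality = 500, gdp_per_capita = 1000,
                     gdi = 0.8, gii = 0.4)
  cf <- data.frame(country_code = covs$country_code, year = 2015,
                   femi = 0.1 + 0.5 * covs$hdi)
  out <- national_regressions(cf, covs, indices = "hdi")
  expect_equal(out$stats$slope, 0.5)
  expect_equal(out$stats$intercept, 0.1)
  expect_equal(out$stats$pearson_r, 1.0)
  expect_true(all(abs(out$residuals$residual) < 1e-12))
  # degenerate design: identical covariate values
  covs$gdi <- 0.5
  expect_error(national_regressions(cf, covs, indices = "gdi"),
               "degenerate")
  # countries without the index are dropped with a diagnostic
  covs$gii <- seq(0.2, 0.6, length.out = 20)
  covs$gii[1] <- NA
  out <- national_regressions(cf, covs, indices = "gii")
  expect_equal(out$stats$n, 19)
  expect_match(out$dropped, "C1/2015")
})

test_that("regression on log GDP recovers the simulated slope", {
  set.seed(3)
  gdp <- exp(runif(40, 5.5, 9.5))
  covs <- data.frame(country_code = paste0("C", 1:40), year = 2015,
                     hdi = 0.5, maternal_mortality = 500,
                     gdp_per_capita = gdp, gdi = 0.8, gii = 0.4)
  cf <- data.frame(country_code = covs$country_code, year = 2015,
                   femi = 0.2 + 0.1 * log10(gdp) + rnorm(40, 0, 0.01))
  out <- national_regressions(cf, covs, indices = "gdp_per_capita")
  expect_lt(abs(out$stats$slope - 0.1), 0.01)
})

test_that("cohort check is zero when the subsamples coincide", {
  rw <- random_women(200, seed = 23)
  rw$women$age <- sample(18:30, 200, replace = TRUE)
  surveys <- femi_surveys(
    rw$women,
    rw$women[1:5, c("respondent_id", "survey_id", "region_id",
                    "sample_weight", "years_schooling", "literate",
                    "work_regularity", "payment_type")],
    rw$births,
    data.frame(survey_id = "s1", country_code = "C", survey_year = 2010L,
               scheme_id = "sc", omitted_questions = NA_character_))
  out <- cohort_sensitivity(surveys)
  expect_equal(out$difference, rep(0, 3))
})

test_that("an injected cohort effect appears in the education difference", {
  cfg <- sim_config(n_countries = 1, regions_per_country = 2,
                    survey_years = 2010, n_women = 25000, n_men = 100,
                    lat_gradient = 0, trend = 0,
                    cohort_effect = c(education = 0.1), seed = 29)
  sim <- simulate_surveys(cfg)
  out <- cohort_sensitivity(sim$surveys)
  # ages are uniform on 15-49; women aged <= 30 carry the +0.1 shift, and
  # the 18-49 group contains a 13/32 share of them, so the expected
  # 18-30 minus 18-49 difference is 0.1 * (1 - 13/32)
  expected <- 0.1 * (1 - 13 / 32)
  got <- out$difference[out$domain == "education"]
  expect_lt(abs(got - expected), 0.02)
  # domains without an injected effect stay near zero
  expect_lt(abs(out$difference[out$domain == "reproductive_healthcare"]),
            0.02)
})

test_that("continental medians recover the latent population median", {
  cfg <- sim_config(n_countries = 10, regions_per_country = 10,
                    survey_years = 2015, n_women = 300, n_men = 100,
                    seed = 37)
  sim <- simulate_surveys(cfg)
  scores <- apply_inequality_adjustment(score_surveys(sim$surveys))
  est <- data.frame(admin1_id = scores$region_id,
                    country_code = substr(scores$region_id, 1, 3),
                    year = 2015, domain = scores$domain,
                    estimate = scores$score, method = "direct",
                    n_surveys_used = 1L)
  cont <- continental_summary(est, sim$regions)
  lat <- sim$truth$latent
  lat <- lat[lat$year == 2015, ]
  w <- sim$regions$female_population
  for (d in all_domains) {
    truth_med <- weighted_quantile(
      lat$latent_score[lat$domain == d],
      w[match(lat$admin1_id[lat$domain == d], sim$regions$admin1_id)],
      0.5)
    expect_lt(abs(cont$p50[cont$domain == d & cont$year == 2015] -
                    truth_med), 0.02)
  }
})
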