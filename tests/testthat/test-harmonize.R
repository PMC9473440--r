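two_unit_setup <- function() {
  list(membership = c(r1 = "G", r2 = "G"),
       weights = c(r1 = 1, r2 = 1))
}

test_that("bracketed harmonization interpolates and rescales", {
  s <- two_unit_setup()
  # year-weighted mean: 0.4@2000 and 0.6@2010 at 2004 -> 0.48
  h <- harmonize_bracketed(c(G = 0.48), before = c(r1 = 0.4, r2 = 0.4),
                           after = c(r1 = 0.6, r2 = 0.6),
                           target_year = 2004, before_year = 2000,
                           after_year = 2010,
                           s$membership, s$weights)
  expect_equal(h$score, c(0.48, 0.48))
  # adjustment factor scales members to match the observed aggregate
  h <- harmonize_bracketed(c(G = 0.55),
                           before = c(r1 = 0.48, r2 = 0.52),
                           after = c(r1 = 0.48, r2 = 0.52),
                           target_year = 2004, before_year = 2000,
                           after_year = 2010,
                           s$membership, s$weights)
  expect_equal(h$score, c(0.48, 0.52) * 1.1)
  # observed equal to the interpolated aggregate: identity
  h <- harmonize_bracketed(c(G = 0.5),
                           before = c(r1 = 0.48, r2 = 0.52),
                           after = c(r1 = 0.48, r2 = 0.52),
                           target_year = 2004, before_year = 2000,
                           after_year = 2010,
                           s$membership, s$weights)
  expect_equal(h$score, c(0.48, 0.52))
  # observed 0 switches to the additive rule and yields zeros
  h <- harmonize_bracketed(c(G = 0),
                           before = c(r1 = 0.1, r2 = 0.1),
                           after = c(r1 = 0.1, r2 = 0.1),
                           target_year = 2004, before_year = 2000,
                           after_year = 2010,
                           s$membership, s$weights)
  expect_equal(h$score, c(0, 0))
})

test_that("single-predictor harmonization shifts by the aggregate offset", {
  s <- two_unit_setup()
  h <- harmonize_single(c(G = 0.46), predictor = c(r1 = 0.38, r2 = 0.42),
                        s$membership, s$weights)
  expect_equal(h$score, c(0.44, 0.48))
  # observed equals the predictor aggregate: identity
  h <- harmonize_single(c(G = 0.40), predictor = c(r1 = 0.38, r2 = 0.42),
                        s$membership, s$weights)
  expect_equal(h$score, c(0.38, 0.42))
  # clamping applies after the shift
  h <- harmonize_single(c(G = 0), predictor = c(r1 = 0.02, r2 = 0.04),
                        s$membership, s$weights)
  expect_equal(h$score, c(0, 0.01))
  expect_equal(h$score_unclamped, c(-0.01, 0.01))
})

test_that("harmonization errors name the missing pieces", {
  s <- two_unit_setup()
  expect_error(harmonize_single(c(G = 0.4), predictor = c(r1 = 0.4),
                                s$membership, s$weights), "r2")
  expect_error(harmonize_bracketed(c(G = 0.4), c(r1 = 0.4, r2 = 0.4),
                                   c(r1 = 0.5), 2004, 2000, 2010,
                                   s$membership, s$weights), "r2")
  expect_error(harmonize_single(c(G = 0.4), c(r1 = 0.4, r2 = 0.4),
                                s$membership, c(r1 = 0, r2 = 0)),
               "zero or missing")
})

test_that("super-region aggregates are preserved before clamping", {
  sim <- make_fixture("scheme-change", seed = 12, n_women = 120)
  fitted_scores <- apply_inequality_adjustment(
    score_surveys(sim$surveys))
  h <- harmonize_scores(fitted_scores, sim$surveys$meta, sim$crosswalk,
                        sim$regions)
  target <- h[h$survey_id == "C01-2006", ]
  # reconstruct the observed super-region values and the weights used
  obs <- fitted_scores[fitted_scores$survey_id == "C01-2006", ]
  cw <- sim$crosswalk[grepl("agg", sim$crosswalk$scheme_id), ]
  std <- h[h$survey_id %in% c("C01-1998", "C01-2014"), ]
  for (dom in unique(target$domain)) {
    for (g in unique(cw$region_id)) {
      members <- cw$admin1_id[cw$region_id == g]
      src <- std[std$domain == dom & std$admin1_id %in% members, ]
      w <- tapply(src$effective_n, src$admin1_id, sum)[members]
      got <- target$score_unclamped[target$domain == dom &
                                      target$admin1_id %in% members]
      names(got) <- target$admin1_id[target$domain == dom &
                                       target$admin1_id %in% members]
      agg <- sum(got[members] * w) / sum(w)
      expect_equal(agg, obs$score[obs$domain == dom &
                                    obs$region_id == g],
                   tolerance = 1e-9)
    }
  }
})

test_that("identity schemes pass through harmonization unchanged", {
  sim <- make_fixture("tiny-2country", seed = 8, n_women = 40)
  scores <- apply_inequality_adjustment(score_surveys(sim$surveys))
  h <- harmonize_scores(scores, sim$surveys$meta, sim$crosswalk,
                        sim$regions)
  m <- merge(scores, h, by.x = c("survey_id", "region_id", "domain"),
             by.y = c("survey_id", "admin1_id", "domain"))
  expect_equal(nrow(m), nrow(scores))
  expect_equal(m$score.x, m$score.y)
  expect_true(all(m$provenance.y == "observed"))
})

test_that("harmonized values recover the latent admin-1 pattern", {
  sim <- make_fixture("scheme-change", seed = 31, n_women = 1000)
  scores <- apply_inequality_adjustment(score_surveys(sim$surveys))
  h <- harmonize_scores(scores, sim$surveys$meta, sim$crosswalk,
                        sim$regions)
  h06 <- h[h$survey_id == "C01-2006", ]
  lat <- sim$truth$latent
  lat <- lat[lat$year == 2006 &
               lat$domain %in% unique(h06$domain), ]
  m <- merge(h06, lat, by = c("admin1_id", "domain"))
  expect_gt(cor(m$score, m$latent_score), 0.9)
})

test_that("admin-2 scores aggregate to admin-1 by weighted mean", {
  mapping <- c(a = "A", b = "A", c = "C")
  expect_equal(aggregate_admin2(c(a = 0.2, b = 0.4, c = 0.9), mapping),
               c(A = 0.3, C = 0.9))
  expect_equal(aggregate_admin2(c(a = 0.2, b = 0.4, c = 0.9), mapping,
                                weights = c(a = 1, b = 3, c = 2)),
               c(A = 0.35, C = 0.9))
  expect_error(aggregate_admin2(c(z = 0.5), mapping), "not mapped")
})
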