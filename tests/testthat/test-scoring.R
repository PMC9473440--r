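test_that("answer coders reproduce the published coding values", {
  expect_identical(code_antenatal(c(0L, 1L, 2L, 3L, 4L, 7L)),
                   c(0, 0.5, 0.5, 0.5, 1, 1))
  expect_identical(code_work_regularity(c("all_year",
                                          "part_year_or_seasonal", "none")),
                   c(1, 0.5, 0))
  expect_identical(code_payment_type(c("cash", "cash_and_in_kind",
                                       "in_kind_only", "unpaid")),
                   c(1, 0.75, 0.5, 0))
  expect_identical(code_decision_answer(c("self", "self_and_partner",
                                          "partner_only", "other")),
                   c(1, 1, 0, 0))
  expect_true(is.na(code_antenatal(NA_integer_)))
  expect_true(is.na(code_decision_answer(NA_character_)))
})

test_that("IPV combines attitude and child-marriage categories", {
  w <- make_woman(beating = rep("no", 5), age_first_marriage = 20L)
  expect_equal(score_ipv(w), 1.0)
  w <- make_woman(beating = c("yes", "yes", "no", "no", "no"),
                  age_first_marriage = 16L)
  expect_equal(score_ipv(w), (0.6 + 0) / 2)
  # only the sexual-violence category available
  w <- make_woman(beating = rep(NA_character_, 5), age_first_marriage = 16L)
  expect_equal(score_ipv(w), 0.0)
  # never married: no child marriage occurred
  w <- make_woman(currently_married = FALSE,
                  beating = c("no", rep(NA_character_, 4)))
  expect_equal(score_ipv(w), 1.0)
  # nothing available
  w <- make_woman(beating = rep(NA_character_, 5))
  expect_true(is.na(score_ipv(w)))
})

test_that("employment averages regularity and payment codes", {
  w <- make_woman(work_regularity = "all_year", payment_type = "cash")
  expect_equal(score_employment(w), 1.0)
  w <- make_woman(work_regularity = "all_year",
                  payment_type = "cash_and_in_kind")
  expect_equal(score_employment(w), (1 + 0.75) / 2)
  w <- make_woman(work_regularity = "part_year_or_seasonal",
                  payment_type = "in_kind_only")
  expect_equal(score_employment(w), 0.5)
  # unemployment forces the payment component to 0
  w <- make_woman(work_regularity = "none", payment_type = NA_character_)
  expect_equal(score_employment(w), 0)
})

test_that("education averages schooling and literacy components", {
  expect_equal(score_education(make_woman(years_schooling = 8L,
                                          literate = TRUE)), 1.0)
  expect_equal(score_education(make_woman(years_schooling = 4L,
                                          literate = TRUE)), 0.5)
  expect_equal(score_education(make_woman(years_schooling = 0L)), 0.0)
  expect_true(is.na(score_education(make_woman())))
})

test_that("reproductive healthcare averages the four care categories", {
  w <- make_woman(age_first_birth = 19L)
  b <- make_birth(antenatal_visits = 2L, professional_delivery = TRUE,
                  postnatal_within_2mo = FALSE)
  expect_equal(score_reproductive_healthcare(w, b), (0.5 + 1 + 0 + 1) / 4)
  w <- make_woman(age_first_birth = 17L)
  b <- make_birth(antenatal_visits = 5L, professional_delivery = TRUE,
                  postnatal_within_2mo = TRUE)
  expect_equal(score_reproductive_healthcare(w, b), (1 + 1 + 1 + 0) / 4)
  # childless women: only the adolescent-childbearing category applies
  w <- make_woman()
  expect_equal(score_reproductive_healthcare(w, NULL), 1.0)
  # two births average within each category
  w <- make_woman(age_first_birth = 20L)
  b <- rbind(make_birth(antenatal_visits = 0L,
                        professional_delivery = TRUE,
                        postnatal_within_2mo = TRUE),
             make_birth(antenatal_visits = 4L,
                        professional_delivery = FALSE,
                        postnatal_within_2mo = TRUE))
  expect_equal(score_reproductive_healthcare(w, b),
               (0.5 + 0.5 + 1 + 1) / 4)
})

test_that("decision-making averages answered questions for married women", {
  w <- make_woman(decision = c("self", "self_and_partner", "partner_only",
                               "partner_only", NA))
  expect_equal(score_decision_making(w), 0.5)
  w <- make_woman(decision = rep("self", 5))
  expect_equal(score_decision_making(w), 1.0)
  w <- make_woman(decision = c("self", rep(NA_character_, 4)))
  expect_equal(score_decision_making(w), 1.0)
  w <- make_woman(currently_married = FALSE, decision = rep("self", 5))
  expect_true(is.na(score_decision_making(w)))
})

test_that("family planning uses the married-not-wanting denominator", {
  w <- make_woman(wants_child_within_2y = FALSE,
                  uses_modern_contraception = TRUE)
  expect_equal(score_family_planning(w), 1)
  w <- make_woman(wants_child_within_2y = FALSE,
                  uses_modern_contraception = FALSE)
  expect_equal(score_family_planning(w), 0)
  # wanting a child now: outside the denominator
  w <- make_woman(wants_child_within_2y = TRUE,
                  uses_modern_contraception = TRUE)
  expect_true(is.na(score_family_planning(w)))
  w <- make_woman(currently_married = FALSE,
                  wants_child_within_2y = FALSE,
                  uses_modern_contraception = TRUE)
  expect_true(is.na(score_family_planning(w)))
})

test_that("vectorized scorers agree exactly with the hand-written oracle", {
  rw <- random_women(400, seed = 99)
  got <- data.frame(
    ipv = score_ipv(rw$women),
    family_planning = score_family_planning(rw$women),
    reproductive_healthcare = score_reproductive_healthcare(rw$women,
                                                            rw$births),
    employment = score_employment(rw$women),
    education = score_education(rw$women),
    decision_making = score_decision_making(rw$women))
  for (i in seq_len(nrow(rw$women))) {
    rec <- as.list(rw$women[i, ])
    b <- rw$births[rw$births$respondent_id == rw$women$respondent_id[i], ]
    want <- oracle_score_one(rec, b)
    for (dom in names(want))
      expect_equal(got[[dom]][i], want[[dom]],
                   info = sprintf("row %d domain %s", i, dom))
  }
})

test_that("regional aggregation takes weighted means and flags empty domains", {
  sc <- data.frame(survey_id = "s1", region_id = "r1",
                   sample_weight = c(1, 1), ipv = c(0.4, 0.6))
  agg <- aggregate_region(sc, "ipv")
  expect_equal(agg$score, 0.5)
  expect_equal(agg$effective_n, 2)
  sc <- data.frame(survey_id = "s1", region_id = "r1",
                   sample_weight = c(3, 1), ipv = c(1, 0))
  expect_equal(aggregate_region(sc, "ipv")$score, 0.75)
  # weights off: plain mean
  expect_equal(aggregate_region(sc, "ipv", use_weights = FALSE)$score, 0.5)
  # all-missing domain becomes a missing row with zero contributors
  sc$ipv <- NA_real_
  agg <- aggregate_region(sc, "ipv")
  expect_true(is.na(agg$score))
  expect_equal(agg$effective_n, 0)
})

test_that("scoring is invariant to record order", {
  rw <- random_women(200, seed = 7)
  rw$women$region_id <- rep(c("r1", "r2"), 100)
  men <- rw$women[1:40, c("respondent_id", "survey_id", "region_id",
                          "sample_weight", "years_schooling", "literate",
                          "work_regularity", "payment_type")]
  surveys <- femi_surveys(rw$women, men, rw$births,
                          data.frame(survey_id = "s1", country_code = "C",
                                     survey_year = 2010L, scheme_id = "sc",
                                     omitted_questions = NA_character_))
  perm <- sample(nrow(rw$women))
  surveys2 <- surveys
  surveys2$women <- surveys$women[perm, ]
  a <- score_surveys(surveys)
  b <- score_surveys(surveys2)
  expect_equal(a[order(a$survey_id, a$region_id, a$domain), ],
               b[order(b$survey_id, b$region_id, b$domain), ],
               ignore_attr = TRUE)
})

test_that("inequality adjustment follows the women-to-men ratio rule", {
  expect_equal(adjust_for_inequality(0.5, 0.625), 0.4)
  expect_equal(adjust_for_inequality(0.3, 0.3), 0.3)
  # women outscoring men clamps at 1
  expect_equal(adjust_for_inequality(0.9, 0.5), 1.0)
  expect_equal(adjust_for_inequality(0.9, 0.5, clamp = FALSE), 1.62)
  # men at zero: no adjustment; both zero: zero
  expect_equal(adjust_for_inequality(0.4, 0), 0.4)
  expect_equal(adjust_for_inequality(0, 0), 0)
  # adjusted <= women iff men >= women; monotone in women for fixed men
  w <- runif(50); m <- runif(50)
  adj <- adjust_for_inequality(w, m, clamp = FALSE)
  expect_equal(adj <= w + 1e-12, m >= w - 1e-12)
  ws <- sort(runif(20))
  expect_true(all(diff(adjust_for_inequality(ws, 0.5, clamp = FALSE)) > 0))
})

test_that("region-level adjustment uses the men's auxiliary rows", {
  tab <- data.frame(
    survey_id = "s1", region_id = "r1",
    domain = c("education", "education_men", "employment",
               "employment_men", "ipv"),
    score = c(0.5, 0.625, 0.4, 0.4, 0.7),
    effective_n = 10, women_raw = NA_real_, men_raw = NA_real_,
    provenance = "observed", stringsAsFactors = FALSE)
  adj <- apply_inequality_adjustment(tab)
  expect_setequal(adj$domain, c("education", "employment", "ipv"))
  expect_equal(adj$score[adj$domain == "education"], 0.4)
  expect_equal(adj$score[adj$domain == "employment"], 0.4)
  expect_equal(adj$score[adj$domain == "ipv"], 0.7)
  expect_equal(adj$women_raw[adj$domain == "education"], 0.5)
  expect_equal(adj$men_raw[adj$domain == "education"], 0.625)
})
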