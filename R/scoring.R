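# Respondent-level domain scoring and region-level aggregation.
#
# Every answer is coded on a 0 (disempowered) .. 1 (empowered) scale;
# a domain score is the mean of its coded categories over the categories
# that apply to (and were asked of) the respondent. Domains:
#   ipv                      attitudes to partner violence + child marriage
#   family_planning          modern contraception among married women who do
#                            not want a child within two years
#   reproductive_healthcare  antenatal/delivery/postnatal care + adolescent
#                            childbearing
#   employment               work regularity + payment type (gender-adjusted)
#   education                >= 6 years schooling + literacy (gender-adjusted)
#   decision_making          say in five household decisions

#' Elementary answer coders
#'
#' Vectorized coders mapping raw survey answers to empowerment scores.
#'
#' * `code_antenatal()`: professional antenatal visits for one birth —
#'   0 visits scores 0, one to three visits 0.5, four or more 1.
#' * `code_work_regularity()`: `all_year` scores 1,
#'   `part_year_or_seasonal` 0.5, `none` 0.
#' * `code_payment_type()`: `cash` scores 1, `cash_and_in_kind` 0.75,
#'   `in_kind_only` 0.5, `unpaid` 0.
#' * `code_decision_answer()`: `self` and `self_and_partner` score 1
#'   (the woman has a say); `partner_only` and `other` score 0.
#'
#' `NA` answers stay `NA`.
#'
#' @param visits integer vector of antenatal visit counts.
#' @param x character vector of coded answers.
#' @return numeric vector of scores in `[0, 1]`.
#' @name answer-coders
NULL

#' @rdname answer-coders
#' @export
code_antenatal <- function(visits) {
  ifelse(is.na(visits), NA_real_,
         ifelse(visits >= 4, 1, ifelse(visits >= 1, 0.5, 0)))
}

#' @rdname answer-coders
#' @export
code_work_regularity <- function(x) {
  unname(c(all_year = 1, part_year_or_seasonal = 0.5, none = 0)[x])
}

#' @rdname answer-coders
#' @export
code_payment_type <- function(x) {
  unname(c(cash = 1, cash_and_in_kind = 0.75, in_kind_only = 0.5,
           unpaid = 0)[x])
}

#' @rdname answer-coders
#' @export
code_decision_answer <- function(x) {
  ifelse(is.na(x), NA_real_, as.numeric(x %in% c("self", "self_and_partner")))
}

# mean over available (non-NA) components, row-wise over a matrix
row_partial_mean <- function(m) {
  k <- rowSums(!is.na(m))
  s <- rowSums(m, na.rm = TRUE)
  ifelse(k == 0, NA_real_, s / k)
}

#' Score the intimate-partner-violence domain
#'
#' Two equally weighted categories. Physical violence: the share of the five
#' beating-justified attitude questions answered "no" (beating not justified),
#' over the questions answered. Sexual violence: 1 unless the respondent was
#' married before age 18 (child marriage; never-married women score 1).
#' The domain is the mean of the available categories and is missing when
#' neither category is available.
#'
#' @param record one or more rows of the `women` table.
#' @return numeric vector of scores in `[0, 1]`, `NA` where unavailable.
#' @export
score_ipv <- function(record) {
  beat <- as.matrix(as.data.frame(
    lapply(record[BEATING_COLS],
           function(x) ifelse(is.na(x), NA_real_, as.numeric(x == "no")))))
  physical <- row_partial_mean(beat)
  afm <- record$age_first_marriage
  sexual <- ifelse(!is.na(afm), as.numeric(afm >= 18),
                   ifelse(!is.na(record$currently_married) &
                            !record$currently_married, 1, NA_real_))
  row_partial_mean(cbind(physical, sexual))
}

#' Score the employment domain (unadjusted)
#'
#' Mean of the work-regularity and payment-type codes (see
#' [code_work_regularity()], [code_payment_type()]). Respondents with no
#' employment get a payment score of 0. Works on women's and men's records
#' alike; the gender-inequality adjustment is applied later at region level
#' by [adjust_for_inequality()].
#'
#' @param record rows of the `women` or `men` table.
#' @return numeric vector of scores in `[0, 1]`, `NA` where unavailable.
#' @export
score_employment <- function(record) {
  reg <- code_work_regularity(record$work_regularity)
  pay <- code_payment_type(record$payment_type)
  pay[!is.na(record$work_regularity) &
        record$work_regularity == "none"] <- 0
  row_partial_mean(cbind(reg, pay))
}

#' Score the education domain (unadjusted)
#'
#' Mean of two binary components: completed at least six years of schooling,
#' and able to read a simple paragraph. Missing components are dropped from
#' the mean.
#'
#' @inheritParams score_employment
#' @return numeric vector of scores, `NA` where unavailable.
#' @export
score_education <- function(record) {
  sch <- ifelse(is.na(record$years_schooling), NA_real_,
                as.numeric(record$years_schooling >= 6))
  lit <- ifelse(is.na(record$literate), NA_real_,
                as.numeric(record$literate))
  row_partial_mean(cbind(sch, lit))
}

#' Score the reproductive-healthcare domain
#'
#' Four categories: antenatal care (0/0.5/1 by professional visit count, see
#' [code_antenatal()]), professional delivery and a postnatal check within two
#' months — each averaged over the respondent's births in the last three
#' years — plus adolescent childbearing (1 unless the first birth was before
#' age 18; childless women score 1). The domain is the mean of the available
#' categories; the three birth-based categories are missing for women with no
#' birth in the last three years.
#'
#' @param record rows of the `women` table.
#' @param births the birth-event table (`respondent_id`, `survey_id`,
#'   `antenatal_visits`, `professional_delivery`, `postnatal_within_2mo`).
#' @return numeric vector of scores, `NA` where unavailable.
#' @export
score_reproductive_healthcare <- function(record, births) {
  key <- paste(record$survey_id, record$respondent_id)
  if (!is.null(births) && nrow(births)) {
    bkey <- paste(births$survey_id, births$respondent_id)
    per_birth_mean <- function(x) {
      v <- tapply(x, bkey, function(z) {
        z <- z[!is.na(z)]
        if (!length(z)) NA_real_ else mean(z)
      })
      unname(v[key])
    }
    ante <- per_birth_mean(code_antenatal(births$antenatal_visits))
    deliv <- per_birth_mean(as.numeric(births$professional_delivery))
    post <- per_birth_mean(as.numeric(births$postnatal_within_2mo))
  } else {
    ante <- deliv <- post <- rep(NA_real_, nrow(record))
  }
  afb <- record$age_first_birth
  adolescent <- ifelse(!is.na(afb), as.numeric(afb >= 18), 1)
  row_partial_mean(cbind(ante, deliv, post, adolescent))
}

#' Score the decision-making domain
#'
#' Each of the five household-decision questions is coded 1 when the
#' respondent decides alone or jointly with her partner (see
#' [code_decision_answer()]); the domain is the mean over the questions
#' answered. Asked of currently married women; missing otherwise.
#'
#' @param record rows of the `women` table.
#' @return numeric vector of scores, `NA` where unavailable.
#' @export
score_decision_making <- function(record) {
  dec <- as.matrix(as.data.frame(
    lapply(record[DECISION_COLS], code_decision_answer)))
  out <- row_partial_mean(dec)
  out[is.na(record$currently_married) | !record$currently_married] <- NA_real_
  out
}

#' Score the family-planning domain
#'
#' 1 if the respondent uses a modern contraceptive method, 0 otherwise —
#' computed only over the domain's denominator: currently married women who
#' do not want a child within the next two years. All other respondents are
#' missing (excluded from the denominator).
#'
#' @param record rows of the `women` table.
#' @return numeric vector with values in `{0, 1}` or `NA`.
#' @export
score_family_planning <- function(record) {
  eligible <- !is.na(record$currently_married) & record$currently_married &
    !is.na(record$wants_child_within_2y) & !record$wants_child_within_2y
  ifelse(eligible,
         ifelse(is.na(record$uses_modern_contraception), NA_real_,
                as.numeric(record$uses_modern_contraception)),
         NA_real_)
}

#' Score every respondent in a survey bundle
#'
#' Applies the six domain scorers to the women's table (and the education and
#' employment scorers to the men's table) of a survey bundle.
#'
#' @param surveys `femi_surveys` object.
#' @return list with elements `women` and `men`: data frames of per-respondent
#'   domain scores alongside `respondent_id`, `survey_id`, `region_id`,
#'   `sample_weight` and (for women) `age`.
#' @export
score_respondents <- function(surveys) {
  stopifnot(inherits(surveys, "femi_surveys"))
  w <- surveys$women
  women <- data.frame(
    respondent_id = w$respondent_id, survey_id = w$survey_id,
    region_id = w$region_id, sample_weight = w$sample_weight, age = w$age,
    ipv = score_ipv(w),
    family_planning = score_family_planning(w),
    reproductive_healthcare = score_reproductive_healthcare(w,
                                                            surveys$births),
    employment = score_employment(w),
    education = score_education(w),
    decision_making = score_decision_making(w),
    stringsAsFactors = FALSE)
  m <- surveys$men
  men <- data.frame(
    respondent_id = m$respondent_id, survey_id = m$survey_id,
    region_id = m$region_id, sample_weight = m$sample_weight,
    education = score_education(m),
    employment = score_employment(m),
    stringsAsFactors = FALSE)
  list(women = women, men = men)
}

#' Aggregate respondent scores to region level
#'
#' Weighted mean of the non-missing respondent scores per
#' (survey, region, domain); `effective_n` counts the contributing
#' respondents. Domains with zero contributors are emitted as missing rows
#' (`effective_n = 0`) — the inputs to imputation.
#'
#' @param scores per-respondent score table (`survey_id`, `region_id`,
#'   `sample_weight`, one column per domain).
#' @param domains domain columns to aggregate.
#' @param use_weights apply the per-respondent sampling weight (default TRUE);
#'   when FALSE every respondent counts equally.
#' @return data frame with columns `survey_id`, `region_id`, `domain`,
#'   `score`, `effective_n`.
#' @export
aggregate_region <- function(scores, domains, use_weights = TRUE) {
  w <- if (use_weights) scores$sample_weight else rep(1, nrow(scores))
  key <- interaction(scores$survey_id, scores$region_id, drop = TRUE,
                     sep = "\r")
  out <- list()
  for (dom in domains) {
    x <- scores[[dom]]
    sc <- tapply(seq_along(x), key, function(i) wmean(x[i], w[i]))
    nn <- tapply(seq_along(x), key, function(i) sum(!is.na(x[i])))
    parts <- strsplit(names(sc), "\r", fixed = TRUE)
    out[[dom]] <- data.frame(
      survey_id = vapply(parts, `[[`, "", 1L),
      region_id = vapply(parts, `[[`, "", 2L),
      domain = dom, score = as.numeric(sc),
      effective_n = as.numeric(nn), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$survey_id, res$region_id, res$domain), , drop = FALSE]
}

#' Score a survey bundle into a region score table
#'
#' Runs respondent scoring and regional aggregation for the six women's
#' domains plus the men's education/employment auxiliaries (carried as
#' domains `education_men` and `employment_men` until the inequality
#' adjustment). Education and employment rows hold the *unadjusted* women's
#' scores; apply [apply_inequality_adjustment()] after imputation.
#'
#' @param surveys `femi_surveys` object.
#' @param use_weights apply sampling weights when aggregating (default TRUE).
#' @return region score table (`survey_id`, `region_id`, `domain`, `score`,
#'   `effective_n`, `women_raw`, `men_raw`, `provenance`).
#' @export
score_surveys <- function(surveys, use_weights = TRUE) {
  resp <- score_respondents(surveys)
  women <- aggregate_region(resp$women, femi_domains(), use_weights)
  men <- aggregate_region(resp$men, c("education", "employment"), use_weights)
  men$domain <- paste0(men$domain, "_men")
  tab <- rbind(women, men)
  tab$women_raw <- ifelse(grepl("_men$", tab$domain), NA_real_, tab$score)
  tab$men_raw <- ifelse(grepl("_men$", tab$domain), tab$score, NA_real_)
  tab$provenance <- "observed"
  rownames(tab) <- NULL
  tab
}

#' Gender-inequality adjustment
#'
#' Multiplies the women's region score by the inequality ratio (women's score
#' divided by men's score), clamped to `[0, 1]`: regions where men outscore
#' women are pulled down, regions where both genders score low (shared
#' poverty) are untouched, and scores are capped at 1 where women outscore
#' men. A men's score of exactly 0 leaves the women's score unadjusted
#' (the ratio is undefined); both scores 0 give 0.
#'
#' @param women_score,men_score region-level scores in `[0, 1]`.
#' @param clamp clamp the result to `[0, 1]` (default TRUE); `FALSE` exposes
#'   the raw product for diagnostic use.
#' @return adjusted scores.
#' @export
adjust_for_inequality <- function(women_score, men_score, clamp = TRUE) {
  out <- ifelse(is.na(men_score) | men_score == 0, women_score,
                women_score * (women_score / men_score))
  if (clamp) out <- clamp01(out)
  out
}

#' Apply the inequality adjustment to a region score table
#'
#' Replaces the education and employment scores with their gender-adjusted
#' values using the matching `education_men` / `employment_men` rows, fills
#' `women_raw` / `men_raw`, and drops the men's auxiliary rows. Rows where
#' either input was imputed are flagged `imputed`.
#'
#' @param region_scores region score table from [score_surveys()] (after
#'   imputation, so that men's values exist for every region).
#' @return region score table restricted to the six women's domains.
#' @export
apply_inequality_adjustment <- function(region_scores) {
  rs <- region_scores
  for (dom in c("education", "employment")) {
    wi <- which(rs$domain == dom)
    mi <- which(rs$domain == paste0(dom, "_men"))
    mkey <- paste(rs$survey_id[mi], rs$region_id[mi])
    match_i <- match(paste(rs$survey_id[wi], rs$region_id[wi]), mkey)
    men_score <- rs$score[mi][match_i]
    men_prov <- rs$provenance[mi][match_i]
    rs$women_raw[wi] <- rs$score[wi]
    rs$men_raw[wi] <- men_score
    rs$score[wi] <- adjust_for_inequality(rs$score[wi], men_score)
    rs$provenance[wi] <- ifelse(
      !is.na(men_prov) & (men_prov == "imputed" | rs$provenance[wi] == "imputed"),
      "imputed", rs$provenance[wi])
  }
  out <- rs[rs$domain %in% femi_domains(), , drop = FALSE]
  rownames(out) <- NULL
  out
}
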