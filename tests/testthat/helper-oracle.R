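# Straight-line, loop-based re-implementation of the answer coding rules,
# kept deliberately independent of the package internals: used to check
# that the vectorized scorers agree with a plain reading of the rules.

oracle_mean <- function(xs) {
  xs <- xs[!is.na(xs)]
  if (length(xs) == 0) NA_real_ else sum(xs) / length(xs)
}

oracle_score_one <- function(rec, births) {
  # rec: one-row list of a women-table record; births: rows for that woman
  beat_cols <- c("beat_goes_out", "beat_neglect", "beat_argues",
                 "beat_refuses_sex", "beat_burns_food")
  dec_cols <- c("decision_health", "decision_purchases", "decision_visits",
                "decision_food", "decision_money")
  # --- IPV ---
  phys <- c()
  for (cn in beat_cols) {
    a <- rec[[cn]]
    if (!is.na(a)) phys <- c(phys, if (a == "no") 1 else 0)
  }
  phys <- if (length(phys)) sum(phys) / length(phys) else NA_real_
  sexual <- NA_real_
  if (!is.na(rec$age_first_marriage)) {
    sexual <- if (rec$age_first_marriage >= 18) 1 else 0
  } else if (!is.na(rec$currently_married) && !rec$currently_married) {
    sexual <- 1
  }
  ipv <- oracle_mean(c(phys, sexual))
  # --- employment ---
  reg <- NA_real_
  if (!is.na(rec$work_regularity))
    reg <- switch(rec$work_regularity, all_year = 1,
                  part_year_or_seasonal = 0.5, none = 0)
  pay <- NA_real_
  if (!is.na(rec$payment_type))
    pay <- switch(rec$payment_type, cash = 1, cash_and_in_kind = 0.75,
                  in_kind_only = 0.5, unpaid = 0)
  if (!is.na(rec$work_regularity) && rec$work_regularity == "none") pay <- 0
  employment <- oracle_mean(c(reg, pay))
  # --- education ---
  sch <- if (is.na(rec$years_schooling)) NA_real_ else
    if (rec$years_schooling >= 6) 1 else 0
  lit <- if (is.na(rec$literate)) NA_real_ else if (rec$literate) 1 else 0
  education <- oracle_mean(c(sch, lit))
  # --- reproductive healthcare ---
  antes <- c(); delivs <- c(); posts <- c()
  if (!is.null(births) && nrow(births) > 0) {
    for (i in seq_len(nrow(births))) {
      av <- births$antenatal_visits[i]
      if (!is.na(av))
        antes <- c(antes, if (av == 0) 0 else if (av <= 3) 0.5 else 1)
      pd <- births$professional_delivery[i]
      if (!is.na(pd)) delivs <- c(delivs, if (pd) 1 else 0)
      pn <- births$postnatal_within_2mo[i]
      if (!is.na(pn)) posts <- c(posts, if (pn) 1 else 0)
    }
  }
  ante <- if (length(antes)) sum(antes) / length(antes) else NA_real_
  deliv <- if (length(delivs)) sum(delivs) / length(delivs) else NA_real_
  post <- if (length(posts)) sum(posts) / length(posts) else NA_real_
  adolescent <- if (!is.na(rec$age_first_birth)) {
    if (rec$age_first_birth >= 18) 1 else 0
  } else 1
  rh <- oracle_mean(c(ante, deliv, post, adolescent))
  # --- decision-making ---
  dm <- NA_real_
  if (!is.na(rec$currently_married) && rec$currently_married) {
    vals <- c()
    for (cn in dec_cols) {
      a <- rec[[cn]]
      if (!is.na(a))
        vals <- c(vals, if (a %in% c("self", "self_and_partner")) 1 else 0)
    }
    if (length(vals)) dm <- sum(vals) / length(vals)
  }
  # --- family planning ---
  fp <- NA_real_
  if (!is.na(rec$currently_married) && rec$currently_married &&
      !is.na(rec$wants_child_within_2y) && !rec$wants_child_within_2y) {
    if (!is.na(rec$uses_modern_contraception))
      fp <- if (rec$uses_modern_contraception) 1 else 0
  }
  list(ipv = ipv, family_planning = fp, reproductive_healthcare = rh,
       employment = employment, education = education,
       decision_making = dm)
}

# A single women-table row with every field settable; defaults are a
# married 30-year-old with no answers recorded.
make_woman <- function(respondent_id = "w1", survey_id = "s1",
                       region_id = "r1", sample_weight = 1, age = 30L,
                       currently_married = TRUE,
                       age_first_marriage = NA_integer_,
                       age_first_birth = NA_integer_,
                       wants_child_within_2y = NA,
                       uses_modern_contraception = NA,
                       decision = rep(NA_character_, 5),
                       beating = rep(NA_character_, 5),
                       years_schooling = NA_integer_, literate = NA,
                       work_regularity = NA_character_,
                       payment_type = NA_character_,
                       births_last_5y = 0L) {
  df <- data.frame(
    respondent_id = respondent_id, survey_id = survey_id,
    region_id = region_id, sample_weight = sample_weight, age = age,
    currently_married = currently_married,
    age_first_marriage = age_first_marriage,
    age_first_birth = age_first_birth,
    wants_child_within_2y = wants_child_within_2y,
    uses_modern_contraception = uses_modern_contraception,
    stringsAsFactors = FALSE)
  dec_cols <- c("decision_health", "decision_purchases", "decision_visits",
                "decision_food", "decision_money")
  beat_cols <- c("beat_goes_out", "beat_neglect", "beat_argues",
                 "beat_refuses_sex", "beat_burns_food")
  for (i in 1:5) df[[dec_cols[i]]] <- decision[i]
  for (i in 1:5) df[[beat_cols[i]]] <- beating[i]
  df$years_schooling <- years_schooling
  df$literate <- literate
  df$work_regularity <- work_regularity
  df$payment_type <- payment_type
  df$births_last_5y <- births_last_5y
  df
}

make_birth <- function(respondent_id = "w1", survey_id = "s1",
                       antenatal_visits = NA_integer_,
                       professional_delivery = NA,
                       postnatal_within_2mo = NA) {
  data.frame(respondent_id = respondent_id, survey_id = survey_id,
             antenatal_visits = antenatal_visits,
             professional_delivery = professional_delivery,
             postnatal_within_2mo = postnatal_within_2mo,
             stringsAsFactors = FALSE)
}

# Randomized respondents exercising every missingness pattern.
random_women <- function(n, seed) {
  set.seed(seed)
  maybe <- function(x, p_na = 0.25)
    ifelse(runif(length(x)) < p_na, NA, x)
  lvl <- function(levels, n, p_na = 0.25) {
    x <- sample(levels, n, replace = TRUE)
    x[runif(n) < p_na] <- NA
    x
  }
  women <- do.call(rbind, lapply(seq_len(n), function(i) make_woman(
    respondent_id = sprintf("w%04d", i))))
  women$age <- sample(15:49, n, replace = TRUE)
  women$currently_married <- maybe(runif(n) < 0.7, 0.1)
  women$age_first_marriage <- maybe(sample(12:35, n, replace = TRUE), 0.3)
  women$age_first_birth <- maybe(sample(12:35, n, replace = TRUE), 0.3)
  women$wants_child_within_2y <- maybe(runif(n) < 0.4)
  women$uses_modern_contraception <- maybe(runif(n) < 0.5)
  for (cn in c("decision_health", "decision_purchases", "decision_visits",
               "decision_food", "decision_money"))
    women[[cn]] <- lvl(c("self", "self_and_partner", "partner_only",
                         "other"), n)
  for (cn in c("beat_goes_out", "beat_neglect", "beat_argues",
               "beat_refuses_sex", "beat_burns_food"))
    women[[cn]] <- lvl(c("yes", "no"), n)
  women$years_schooling <- maybe(sample(0:16, n, replace = TRUE))
  women$literate <- maybe(runif(n) < 0.5)
  women$work_regularity <- lvl(c("all_year", "part_year_or_seasonal",
                                 "none"), n)
  women$payment_type <- lvl(c("cash", "cash_and_in_kind", "in_kind_only",
                              "unpaid"), n)
  women$births_last_5y <- sample(0:4, n, replace = TRUE)
  nb <- sample(0:2, n, replace = TRUE)
  births <- do.call(rbind, lapply(which(nb > 0), function(i) {
    k <- nb[i]
    data.frame(respondent_id = women$respondent_id[i], survey_id = "s1",
               antenatal_visits = maybe(sample(0:9, k, replace = TRUE)),
               professional_delivery = maybe(runif(k) < 0.5),
               postnatal_within_2mo = maybe(runif(k) < 0.5),
               stringsAsFactors = FALSE)
  }))
  list(women = women, births = births)
}
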