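# Synthetic DHS-like survey generator with known latent region scores.
#
# Respondent answers are drawn so that the expected coded respondent score
# for every domain equals the region's latent score, which makes every
# downstream stage testable by parameter recovery. Latent scores follow a
# latitude gradient plus a linear annual trend, emulating the north-south
# empowerment gradient seen across Sub-Saharan Africa.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_surveys()]. Defaults describe a
#' small two-country continent; every argument can be overridden.
#'
#' Latent region scores are
#' `clamp(baseline + lat_gradient * (lat - mean lat) + trend * (year - 2005))`
#' per domain, in score units. Answers are drawn so each coded category has
#' expectation equal to the latent score; men's latent scores are the women's
#' divided by `gap_ratio` (clamped to 1), so `gap_ratio` is the women:men
#' score ratio.
#'
#' @param n_countries number of countries.
#' @param regions_per_country admin-1 regions per country.
#' @param baseline named per-domain latent baseline at the mean latitude in
#'   2005 (women's unadjusted scores).
#' @param lat_gradient per-domain score change per degree latitude (scalar or
#'   named vector); negative means lower scores further north.
#' @param trend per-domain score change per year (scalar or named vector).
#' @param survey_years integer years, or a list of year vectors per country.
#' @param schemes region scheme per survey: `"admin1"` or `"aggregated:k"`
#'   (merge each country's regions into `k` latitude-contiguous
#'   super-regions). Scalar, or a list parallel to `survey_years`.
#' @param n_women,n_men respondents per admin-1 region per survey.
#' @param missing_plan named list: survey id -> character vector of question
#'   blocks omitted from that survey. Blocks: `ipv`, `beating`,
#'   `decision_making`, `family_planning`, `education`, `employment`,
#'   `reproductive_healthcare`, `education_men`, `employment_men`.
#' @param coverage named list: survey id -> admin-1 ids covered (partial
#'   country surveys); default full coverage.
#' @param gap_ratio women:men latent score ratio for education/employment.
#' @param country_effect_sd sd of a per-country latent shift applied to all
#'   domains (default 0); gives countries distinct levels that their
#'   development covariates track.
#' @param noise_sd sd of region-by-survey latent noise (score units).
#' @param lognormal_weights draw lognormal sampling weights instead of 1.0.
#' @param prop_wants_child probability a woman wants a child within 2 years.
#' @param prop_recent_birth probability of a birth in the last three years.
#' @param cohort_effect named per-domain latent shift added for respondents
#'   aged 30 or younger (default none).
#' @param truth_years years at which the latent ground truth is tabulated.
#' @param seed integer RNG seed; fixed seed gives byte-identical output.
#' @return object of class `femi_sim_config`.
#' @export
sim_config <- function(n_countries = 2,
                       regions_per_country = 3,
                       baseline = c(ipv = 0.52, family_planning = 0.43,
                                    reproductive_healthcare = 0.58,
                                    employment = 0.49, education = 0.35,
                                    decision_making = 0.49),
                       lat_gradient = -0.015,
                       trend = 0.006,
                       survey_years = c(2004, 2014),
                       schemes = "admin1",
                       n_women = 200,
                       n_men = 100,
                       missing_plan = list(),
                       coverage = list(),
                       gap_ratio = 0.9,
                       country_effect_sd = 0,
                       noise_sd = 0,
                       lognormal_weights = FALSE,
                       prop_wants_child = 0.3,
                       prop_recent_birth = 0.6,
                       cohort_effect = NULL,
                       truth_years = c(1995, 2005, 2015),
                       seed = 1L) {
  doms <- femi_domains()
  expand <- function(x) {
    if (length(x) == 1 && is.null(names(x)))
      return(stats::setNames(rep(as.numeric(x), length(doms)), doms))
    miss <- setdiff(doms, names(x))
    if (length(miss)) stopf("missing domain '%s'", miss[[1]])
    x[doms]
  }
  cfg <- list(
    n_countries = as.integer(n_countries),
    regions_per_country = as.integer(regions_per_country),
    baseline = expand(baseline), lat_gradient = expand(lat_gradient),
    trend = expand(trend), survey_years = survey_years, schemes = schemes,
    n_women = as.integer(n_women), n_men = as.integer(n_men),
    missing_plan = missing_plan, coverage = coverage,
    gap_ratio = gap_ratio, country_effect_sd = country_effect_sd,
    noise_sd = noise_sd,
    lognormal_weights = lognormal_weights,
    prop_wants_child = prop_wants_child,
    prop_recent_birth = prop_recent_birth,
    cohort_effect = cohort_effect, truth_years = truth_years,
    seed = as.integer(seed))
  stopifnot(cfg$n_countries >= 1, cfg$regions_per_country >= 1,
            cfg$n_women >= 1, cfg$n_men >= 1)
  for (sch in unlist(cfg$schemes)) {
    if (grepl("^aggregated:", sch)) {
      k <- as.integer(sub("^aggregated:", "", sch))
      if (is.na(k) || k < 1 || k > cfg$regions_per_country)
        stopf("scheme '%s': k must be in [1, regions_per_country]", sch)
    } else if (sch != "admin1") stopf("unknown scheme '%s'", sch)
  }
  class(cfg) <- "femi_sim_config"
  cfg
}

sim_country_years <- function(cfg, ci) {
  if (is.list(cfg$survey_years)) cfg$survey_years[[ci]] else cfg$survey_years
}

sim_survey_scheme <- function(cfg, ci, yi) {
  sch <- if (is.list(cfg$schemes)) cfg$schemes[[ci]] else cfg$schemes
  if (length(sch) > 1) sch[[yi]] else sch
}

# three-point categorical on coded values (v0, vmid, v1) with expectation p;
# returns matrix of probabilities (p0, pmid, p1) per element of p
three_point_probs <- function(p, mid_cap = 0.5) {
  pm <- pmin(mid_cap, 2 * p, 2 * (1 - p))
  p1 <- p - pm / 2
  p0 <- 1 - p1 - pm
  cbind(p0 = p0, pmid = pm, p1 = p1)
}

draw_cat <- function(n, probs, values) {
  # probs: n x k matrix, rows summing to 1
  u <- stats::runif(n)
  cum <- t(apply(probs, 1, cumsum))
  idx <- rowSums(u > cum) + 1L
  values[idx]
}

sim_latent <- function(cfg, domain, latv, year, lat_ref, shift = 0) {
  clamp01(cfg$baseline[[domain]] +
            cfg$lat_gradient[[domain]] * (latv - lat_ref) +
            cfg$trend[[domain]] * (year - 2005) + shift)
}

# payment-type mixture over (cash, mixed, in-kind, unpaid) with
# conditional-on-employed expectation t
payment_probs <- function(t) {
  m <- pmin(0.2, t / 1.25, (1 - t) / 0.75)
  m <- pmax(0, m)
  a <- t - 1.25 * m
  d <- 1 - a - 2 * m
  cbind(cash = a, mixed = m, ik = m, unpaid = pmax(0, d))
}

sim_women_block <- function(cfg, admin1, p, survey_id, region_of) {
  # p: matrix regions x domains of target latent scores (women, unadjusted)
  n <- cfg$n_women
  R <- nrow(admin1)
  N <- n * R
  ri <- rep(seq_len(R), each = n)
  pr <- function(dom) p[ri, dom]
  age <- sample(15:49, N, replace = TRUE)
  young <- age <= 30
  adj <- function(dom) {
    x <- pr(dom)
    ce <- cfg$cohort_effect
    if (!is.null(ce) && !is.na(ce[dom]) && !is.null(names(ce)) &&
        dom %in% names(ce))
      x <- clamp01(x + ifelse(young, ce[[dom]], 0))
    x
  }
  p_ipv <- adj("ipv"); p_fp <- adj("family_planning")
  p_rh <- adj("reproductive_healthcare"); p_emp <- adj("employment")
  p_edu <- adj("education"); p_dm <- adj("decision_making")

  bern <- function(p) stats::runif(N) < p
  w <- data.frame(
    respondent_id = sprintf("%s-W%05d", survey_id, seq_len(N)),
    survey_id = survey_id,
    region_id = region_of[admin1$admin1_id[ri]],
    sample_weight = if (cfg$lognormal_weights)
      stats::rlnorm(N, 0, 0.3) else rep(1, N),
    age = age,
    currently_married = TRUE,
    stringsAsFactors = FALSE)
  # IPV: child marriage (sexual category) and the five attitude questions
  married_adult <- bern(p_ipv)
  w$age_first_marriage <- ifelse(married_adult,
                                 sample(18:30, N, replace = TRUE),
                                 sample(14:17, N, replace = TRUE))
  w$age_first_birth <- NA_integer_  # filled below with RH adolescent category
  w$wants_child_within_2y <- bern(cfg$prop_wants_child)
  w$uses_modern_contraception <- bern(p_fp)
  for (col in DECISION_COLS) {
    say <- bern(p_dm)
    w[[col]] <- ifelse(say,
                       ifelse(stats::runif(N) < 0.5, "self",
                              "self_and_partner"),
                       ifelse(stats::runif(N) < 0.8, "partner_only", "other"))
  }
  for (col in BEATING_COLS) w[[col]] <- ifelse(bern(p_ipv), "no", "yes")
  w$years_schooling <- ifelse(bern(p_edu), 8L, 3L)
  w$literate <- bern(p_edu)
  # employment: regularity on (none, part, all_year); payment conditional
  regp <- three_point_probs(p_emp, mid_cap = 0.4)
  w$work_regularity <- draw_cat(N, regp,
                                c("none", "part_year_or_seasonal",
                                  "all_year"))
  employed <- w$work_regularity != "none"
  t_pay <- ifelse(1 - regp[, "p0"] > 0, p_emp / (1 - regp[, "p0"]), 0)
  t_pay <- clamp01(t_pay)
  payp <- payment_probs(t_pay)
  pay <- draw_cat(N, payp, c("cash", "cash_and_in_kind", "in_kind_only",
                             "unpaid"))
  w$payment_type <- ifelse(employed, pay, "unpaid")
  # reproductive healthcare: adolescent childbearing + recent-birth care
  adult_birth <- bern(p_rh)
  w$age_first_birth <- ifelse(adult_birth, sample(18:28, N, replace = TRUE),
                              sample(14:17, N, replace = TRUE))
  recent <- bern(cfg$prop_recent_birth)
  w$births_last_5y <- as.integer(recent) +
    stats::rbinom(N, 1, 0.3)
  nb <- sum(recent)
  antep <- three_point_probs(p_rh[recent], mid_cap = 0.5)
  births <- data.frame(
    respondent_id = w$respondent_id[recent],
    survey_id = survey_id,
    antenatal_visits = draw_cat(nb, antep, c(0L, 2L, 4L)),
    professional_delivery = stats::runif(nb) < p_rh[recent],
    postnatal_within_2mo = stats::runif(nb) < p_rh[recent],
    stringsAsFactors = FALSE)
  list(women = w, births = births)
}

sim_men_block <- function(cfg, admin1, p_men, survey_id, region_of) {
  n <- cfg$n_men
  R <- nrow(admin1)
  N <- n * R
  ri <- rep(seq_len(R), each = n)
  bern <- function(p) stats::runif(N) < p
  p_edu <- p_men[ri, "education"]
  p_emp <- p_men[ri, "employment"]
  m <- data.frame(
    respondent_id = sprintf("%s-M%05d", survey_id, seq_len(N)),
    survey_id = survey_id,
    region_id = region_of[admin1$admin1_id[ri]],
    sample_weight = if (cfg$lognormal_weights)
      stats::rlnorm(N, 0, 0.3) else rep(1, N),
    years_schooling = ifelse(bern(p_edu), 8L, 3L),
    literate = bern(p_edu),
    stringsAsFactors = FALSE)
  regp <- three_point_probs(p_emp, mid_cap = 0.4)
  m$work_regularity <- draw_cat(N, regp,
                                c("none", "part_year_or_seasonal",
                                  "all_year"))
  t_pay <- clamp01(ifelse(1 - regp[, "p0"] > 0,
                          p_emp / (1 - regp[, "p0"]), 0))
  pay <- draw_cat(N, payment_probs(t_pay),
                  c("cash", "cash_and_in_kind", "in_kind_only", "unpaid"))
  m$payment_type <- ifelse(m$work_regularity != "none", pay, "unpaid")
  m
}

# question blocks that a survey can omit entirely
omit_block <- function(women, births, men, block) {
  set_na <- function(df, cols) {
    df[cols] <- lapply(df[cols], function(x) { x[] <- NA; x })
    df
  }
  switch(block,
    beating = list(women = set_na(women, BEATING_COLS), births = births,
                   men = men),
    ipv = list(women = set_na(women, c(BEATING_COLS, "age_first_marriage")),
               births = births, men = men),
    decision_making = list(women = set_na(women, DECISION_COLS),
                           births = births, men = men),
    family_planning = list(
      women = set_na(women, c("wants_child_within_2y",
                              "uses_modern_contraception")),
      births = births, men = men),
    education = list(women = set_na(women, c("years_schooling", "literate")),
                     births = births, men = men),
    employment = list(women = set_na(women, c("work_regularity",
                                              "payment_type")),
                      births = births, men = men),
    reproductive_healthcare = list(
      women = set_na(women, "age_first_birth"),
      births = births[0, , drop = FALSE], men = men),
    education_men = list(women = women, births = births,
                         men = set_na(men, c("years_schooling", "literate"))),
    employment_men = list(women = women, births = births,
                          men = set_na(men, c("work_regularity",
                                              "payment_type"))),
    stopf("unknown question block '%s'", block))
}

#' Generate a synthetic multi-survey dataset
#'
#' Draws survey microdata for every configured country and survey year so
#' that the expected respondent-level score of every domain equals the
#' region's latent score, and returns the latent truth alongside, for
#' parameter-recovery testing. With a fixed seed the output is identical
#' across runs.
#'
#' @param config a [sim_config()] object.
#' @return list of class `femi_sim` with elements:
#'   `surveys` (a [femi_surveys()] bundle), `regions` (admin-1 centroids and
#'   population), `crosswalk` (all region schemes used), `covariates`
#'   (country-year development indicators linked to the latent scores),
#'   and `truth` (list: `latent` — admin-1 latent scores by year and domain,
#'   with education/employment already gender-adjusted and the men's raw
#'   latents as `education_men`/`employment_men` rows; `observed` — expected
#'   observed score per survey region, including survey-level latent noise).
#' @export
simulate_surveys <- function(config) {
  stopifnot(inherits(config, "femi_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  doms <- femi_domains()
  ccs <- sprintf("C%02d", seq_len(cfg$n_countries))
  country_shift <- stats::setNames(
    stats::rnorm(cfg$n_countries, 0, cfg$country_effect_sd), ccs)
  R <- cfg$regions_per_country
  regions <- do.call(rbind, lapply(seq_along(ccs), function(ci) {
    data.frame(
      admin1_id = sprintf("%s-R%02d", ccs[ci], seq_len(R)),
      country_code = ccs[ci],
      longitude = 5 * ci + stats::runif(R, -1, 1),
      latitude = 14 - 24 * (seq_len(R) - 0.5) / R + stats::runif(R, -0.4, 0.4),
      stringsAsFactors = FALSE)
  }))
  regions$female_population <- round(stats::rlnorm(nrow(regions), 12, 0.5))
  regions$pop_density <- round(stats::rlnorm(nrow(regions), 4, 0.8), 2)
  lat_ref <- mean(regions$latitude)

  women_l <- list(); men_l <- list(); births_l <- list(); meta_l <- list()
  cw_l <- list(); obs_l <- list()
  for (ci in seq_along(ccs)) {
    cc <- ccs[ci]
    admin1 <- regions[regions$country_code == cc, , drop = FALSE]
    # identity scheme, always defined
    id_scheme <- sprintf("%s-admin1", cc)
    cw_l[[length(cw_l) + 1L]] <- data.frame(
      scheme_id = id_scheme, region_id = admin1$admin1_id,
      admin1_id = admin1$admin1_id, stringsAsFactors = FALSE)
    years <- sim_country_years(cfg, ci)
    for (yi in seq_along(years)) {
      year <- years[[yi]]
      survey_id <- sprintf("%s-%d", cc, year)
      cov_ids <- cfg$coverage[[survey_id]] %||% admin1$admin1_id
      sub <- admin1[admin1$admin1_id %in% cov_ids, , drop = FALSE]
      sch <- sim_survey_scheme(cfg, ci, yi)
      if (sch == "admin1") {
        scheme_id <- id_scheme
        region_of <- stats::setNames(sub$admin1_id, sub$admin1_id)
      } else {
        k <- as.integer(sub("^aggregated:", "", sch))
        scheme_id <- sprintf("%s-agg%d-%d", cc, k, year)
        ord <- order(-sub$latitude)
        grp <- cut(seq_len(nrow(sub)), k, labels = FALSE)
        gid <- sprintf("%s-G%d", cc, grp)
        region_of <- stats::setNames(gid, sub$admin1_id[ord])
        cw_l[[length(cw_l) + 1L]] <- data.frame(
          scheme_id = scheme_id, region_id = unname(region_of),
          admin1_id = names(region_of), stringsAsFactors = FALSE)
      }
      # latent targets with survey-level noise
      p_w <- sapply(doms, function(d)
        clamp01(sim_latent(cfg, d, sub$latitude, year, lat_ref,
                           country_shift[[cc]]) +
                  stats::rnorm(nrow(sub), 0, cfg$noise_sd)))
      p_w <- matrix(p_w, nrow = nrow(sub),
                    dimnames = list(sub$admin1_id, doms))
      p_m <- cbind(
        education = clamp01(p_w[, "education"] / cfg$gap_ratio),
        employment = clamp01(p_w[, "employment"] / cfg$gap_ratio))
      wb <- sim_women_block(cfg, sub, p_w, survey_id, region_of)
      mb <- sim_men_block(cfg, sub, p_m, survey_id, region_of)
      women <- wb$women; births <- wb$births; men <- mb
      blocks <- cfg$missing_plan[[survey_id]] %||% character()
      for (b in blocks) {
        o <- omit_block(women, births, men, b)
        women <- o$women; births <- o$births; men <- o$men
      }
      women_l[[survey_id]] <- women
      men_l[[survey_id]] <- men
      births_l[[survey_id]] <- births
      meta_l[[survey_id]] <- data.frame(
        survey_id = survey_id, country_code = cc, survey_year = year,
        scheme_id = scheme_id,
        omitted_questions = if (length(blocks))
          paste(blocks, collapse = ";") else NA_character_,
        stringsAsFactors = FALSE)
      # expected observed score per survey region (equal-n pooling)
      adj <- clamp01(ifelse(p_m > 0, p_w[, c("education", "employment")]^2 /
                              p_m, 0))
      fin <- p_w
      fin[, "education"] <- adj[, "education"]
      fin[, "employment"] <- adj[, "employment"]
      gids <- region_of[sub$admin1_id]
      obs <- do.call(rbind, lapply(doms, function(d) {
        v <- tapply(fin[, d], gids, mean)
        data.frame(survey_id = survey_id, region_id = names(v), domain = d,
                   expected_score = as.numeric(v), stringsAsFactors = FALSE)
      }))
      obs_l[[length(obs_l) + 1L]] <- obs
    }
  }
  women <- do.call(rbind, women_l); rownames(women) <- NULL
  men <- do.call(rbind, men_l); rownames(men) <- NULL
  births <- do.call(rbind, births_l); rownames(births) <- NULL
  meta <- do.call(rbind, meta_l); rownames(meta) <- NULL
  crosswalk <- do.call(rbind, cw_l); rownames(crosswalk) <- NULL
  surveys <- femi_surveys(women, men, births, meta)

  truth_years <- sort(unique(c(cfg$truth_years,
                               unlist(lapply(seq_along(ccs),
                                             function(ci)
                                               sim_country_years(cfg, ci))))))
  truth_l <- list()
  for (year in truth_years) {
    p_w <- sapply(doms, function(d)
      sim_latent(cfg, d, regions$latitude, year, lat_ref,
                 country_shift[regions$country_code]))
    p_w <- matrix(p_w, nrow = nrow(regions),
                  dimnames = list(regions$admin1_id, doms))
    p_m <- cbind(education = clamp01(p_w[, "education"] / cfg$gap_ratio),
                 employment = clamp01(p_w[, "employment"] / cfg$gap_ratio))
    fin <- p_w
    for (d in c("education", "employment"))
      fin[, d] <- clamp01(ifelse(p_m[, d] > 0, p_w[, d]^2 / p_m[, d], 0))
    long <- expand.grid(admin1_id = regions$admin1_id,
                        domain = c(doms, "education_men", "employment_men"),
                        stringsAsFactors = FALSE)
    long$country_code <- regions$country_code[
      match(long$admin1_id, regions$admin1_id)]
    long$year <- year
    long$latent_score <- NA_real_
    for (d in doms)
      long$latent_score[long$domain == d] <- fin[, d]
    long$latent_score[long$domain == "education_men"] <- p_m[, "education"]
    long$latent_score[long$domain == "employment_men"] <- p_m[, "employment"]
    truth_l[[as.character(year)]] <- long
  }
  latent <- do.call(rbind, truth_l)[, c("admin1_id", "country_code", "year",
                                        "domain", "latent_score")]
  rownames(latent) <- NULL
  observed <- do.call(rbind, obs_l); rownames(observed) <- NULL

  covs <- do.call(rbind, lapply(seq_along(ccs), function(ci) {
    cc <- ccs[ci]
    latv <- regions$latitude[regions$country_code == cc]
    do.call(rbind, lapply(1985:2020, function(year) {
      femi_lat <- mean(sapply(doms, function(d)
        mean(sim_latent(cfg, d, latv, year, lat_ref,
                        country_shift[[cc]]))))
      data.frame(country_code = cc, year = year,
                 hdi = clamp01(0.15 + 0.6 * femi_lat),
                 maternal_mortality = round(1000 - 900 * femi_lat, 1),
                 gdp_per_capita = round(exp(6 + 3 * femi_lat), 2),
                 gdi = clamp01(0.75 + 0.25 * femi_lat),
                 gii = clamp01(0.75 - 0.5 * femi_lat),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(covs) <- NULL

  structure(list(surveys = surveys, regions = regions, crosswalk = crosswalk,
                 covariates = covs,
                 truth = list(latent = latent, observed = observed),
                 config = cfg),
            class = "femi_sim")
}

#' Canned simulation fixtures
#'
#' Small deterministic datasets used throughout the test suite.
#'
#' * `tiny-2country`: 2 countries x 3 regions, surveys 2004 and 2014 on
#'   admin-1 schemes.
#' * `scheme-change`: 1 country x 6 regions, admin-1 surveys in 1998 and 2014
#'   bracketing a 2006 survey on two aggregated super-regions.
#' * `missing-domain`: 2 countries x 4 regions, 2 surveys; the first survey of
#'   country 1 omits the whole IPV question block.
#' * `mali-split-analogue`: 1 country x 4 regions; the early survey covers
#'   only the southern half of the country.
#' * `two-survey-trend`: 1 country x 4 regions, surveys 2000 and 2010, with a
#'   clear annual trend.
#'
#' @param name fixture name.
#' @param seed RNG seed (default 42).
#' @param n_women respondents per region override (fixture default if NULL).
#' @return a `femi_sim` object, see [simulate_surveys()].
#' @export
make_fixture <- function(name, seed = 42L, n_women = NULL) {
  cfg <- switch(
    name,
    "tiny-2country" = sim_config(
      n_countries = 2, regions_per_country = 3,
      survey_years = c(2004, 2014), n_women = n_women %||% 120,
      n_men = 60, seed = seed),
    "scheme-change" = sim_config(
      n_countries = 1, regions_per_country = 6,
      survey_years = c(1998, 2006, 2014),
      schemes = list(c("admin1", "aggregated:2", "admin1")),
      n_women = n_women %||% 250, n_men = 120,
      lat_gradient = -0.03, seed = seed),
    "missing-domain" = sim_config(
      n_countries = 2, regions_per_country = 4,
      survey_years = c(2005, 2015), n_women = n_women %||% 150, n_men = 80,
      lat_gradient = -0.025,
      missing_plan = list("C01-2005" = "ipv"), seed = seed),
    "mali-split-analogue" = sim_config(
      n_countries = 1, regions_per_country = 4,
      survey_years = c(1998, 2012), n_women = n_women %||% 150, n_men = 80,
      coverage = list("C01-1998" = c("C01-R03", "C01-R04")), seed = seed),
    "two-survey-trend" = sim_config(
      n_countries = 1, regions_per_country = 4,
      survey_years = c(2000, 2010), trend = 0.01,
      n_women = n_women %||% 150, n_men = 80, seed = seed),
    stopf("unknown fixture '%s'", name))
  simulate_surveys(cfg)
}

#' Write a simulated dataset to a directory of CSV files
#'
#' Persists a `femi_sim` object in the package's open CSV schemas
#' (microdata, crosswalk, regions, covariates) plus `ground_truth.csv`.
#'
#' @param sim `femi_sim` object from [simulate_surveys()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "femi_sim"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_survey(sim$surveys, dir)
  write_femi_csv(sim$crosswalk, file.path(dir, "crosswalk.csv"), "crosswalk")
  write_femi_csv(sim$regions, file.path(dir, "regions.csv"), "regions")
  write_femi_csv(sim$covariates, file.path(dir, "covariates.csv"),
                 "covariates")
  gt <- sim$truth$latent
  names(gt)[names(gt) == "latent_score"] <- "latent_score"
  write_femi_csv(gt, file.path(dir, "ground_truth.csv"), "ground_truth")
  invisible(dir)
}
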