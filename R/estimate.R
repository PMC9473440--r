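# Reference-year estimation: each (admin-1 region, domain) gets one estimate
# per reference year via a three-way rule — direct reassignment of a nearby
# survey, a linear trend over the region's surveys, or random-forest
# prediction from country/region covariates.

#' Choose the estimation method for a reference year
#'
#' `direct` when a survey lies within 2 years of the reference year,
#' otherwise `linear` when two or more surveys exist, otherwise `rf`.
#'
#' @param survey_years integer vector of available survey years (possibly
#'   empty).
#' @param reference_year the target year.
#' @return `"direct"`, `"linear"` or `"rf"`.
#' @export
select_method <- function(survey_years, reference_year) {
  if (length(survey_years) && any(abs(survey_years - reference_year) <= 2))
    return("direct")
  if (length(survey_years) >= 2) return("linear")
  "rf"
}

# qualifying survey year for direct assignment: nearest; ties go to the
# later survey (more current fieldwork)
direct_year <- function(survey_years, reference_year) {
  cand <- survey_years[abs(survey_years - reference_year) <= 2]
  d <- abs(cand - reference_year)
  cand <- cand[d == min(d)]
  max(cand)
}

#' Direct assignment of a qualifying survey
#'
#' Copies a region's harmonized scores from the survey nearest the reference
#' year (within the 2-year window; equidistant ties pick the later survey).
#'
#' @param years survey years of the region's observations.
#' @param scores scores parallel to `years`.
#' @param reference_year the target year.
#' @return the assigned score.
#' @export
direct_assign <- function(years, scores, reference_year) {
  y <- direct_year(years, reference_year)
  scores[match(y, years)]
}

#' Linear-trend extrapolation for one region and domain
#'
#' Ordinary least-squares line through the region's (year, score) points,
#' evaluated at the reference year and clamped to `[0, 1]`. Degenerate
#' series with a single distinct year fall back to the mean.
#'
#' @param years survey years (>= 2 observations).
#' @param scores scores parallel to `years`.
#' @param reference_year the target year.
#' @return the extrapolated score.
#' @export
extrapolate_linear <- function(years, scores, reference_year) {
  stopifnot(length(years) >= 2, length(years) == length(scores))
  if (length(unique(years)) == 1) return(clamp01(mean(scores)))
  fit <- stats::lsfit(years, scores)
  clamp01(unname(fit$coefficients[1] + fit$coefficients[2] * reference_year))
}

fill_from_train <- function(train, targets) {
  for (col in names(train)) {
    med <- stats::median(train[[col]], na.rm = TRUE)
    train[[col]][is.na(train[[col]])] <- med
    targets[[col]][is.na(targets[[col]])] <- med
  }
  list(train = train, targets = targets)
}

#' Random-forest extrapolation
#'
#' Fits random forests of estimate on HDI, maternal mortality, regional
#' population density and the region's own survey value, using all regions
#' estimated by the direct/linear branches as training rows, then predicts
#' the target regions. Target regions with a survey of their own are
#' predicted with the survey value as a feature; regions with no survey use
#' a forest on the country/region covariates alone (the survey-value
#' feature is unavailable, not fillable). Remaining missing covariates are
#' filled with training-set medians; predictions are clamped to `[0, 1]`.
#'
#' @param train data frame with columns `y`, `hdi`, `maternal_mortality`,
#'   `pop_density`, `survey_value`.
#' @param targets data frame with the same feature columns (`survey_value`
#'   may be `NA`).
#' @param seed integer seed.
#' @param ntree trees (default 500).
#' @return numeric predictions for `targets`.
#' @export
extrapolate_rf <- function(train, targets, seed = 1L, ntree = 500) {
  if (!nrow(train))
    stop("no direct/linear training rows available for RF extrapolation",
         call. = FALSE)
  covs <- c("hdi", "maternal_mortality", "pop_density")
  if (!nrow(targets)) {
    # the training pass still runs; there is just nothing to predict
    set.seed(stage_seed(seed, 0L))
    fit_rf(
      x = fill_from_train(train[covs], train[0, covs])$train,
      y = train$y, ntree = ntree)
    return(numeric(0))
  }
  out <- rep(NA_real_, nrow(targets))
  has_sv <- !is.na(targets$survey_value)
  fit_predict <- function(feats, rows, seed_off) {
    filled <- fill_from_train(train[feats], targets[rows, feats,
                                                    drop = FALSE])
    set.seed(stage_seed(seed, seed_off))
    fit <- fit_rf(x = filled$train, y = train$y, ntree = ntree)
    clamp01(as.numeric(stats::predict(fit, filled$targets)))
  }
  if (any(has_sv))
    out[has_sv] <- fit_predict(c(covs, "survey_value"), has_sv, 0L)
  if (any(!has_sv))
    out[!has_sv] <- fit_predict(covs, !has_sv, 1L)
  out
}

cov_value <- function(covariates, cc, year, field) {
  v <- covariates[[field]][covariates$country_code == cc &
                             covariates$year == year]
  if (!length(v) || is.na(v[1]))
    stopf("covariate '%s' missing for country-year %s/%d", field, cc, year)
  v[1]
}

#' Estimate all regions and domains at the reference years
#'
#' Applies the three-way rule per (region, domain, reference year) on a
#' harmonized score table. Survey availability is assessed per region, so
#' partial-country surveys (a survey covering only part of a country)
#' naturally contribute only to the regions they covered. The RF branch
#' trains one pooled forest per domain on all direct/linear estimates.
#'
#' @param harmonized harmonized admin-1 score table from
#'   [harmonize_scores()].
#' @param covariates country-year covariate table (`hdi`,
#'   `maternal_mortality` required).
#' @param regions admin-1 table with `pop_density`.
#' @param years reference years (default 1995, 2005, 2015).
#' @param seed integer seed for the RF branch.
#' @param ntree trees for the RF branch.
#' @return estimate table: `admin1_id`, `country_code`, `year`, `domain`,
#'   `estimate`, `method` (`direct`/`linear`/`rf`), `n_surveys_used`.
#' @export
estimate_years <- function(harmonized, covariates, regions,
                           years = c(1995, 2005, 2015), seed = 1L,
                           ntree = 500) {
  doms <- sort(unique(harmonized$domain))
  # the estimation frame is every admin-1 unit in the regions table plus any
  # harmonized unit, so never-surveyed countries are covered by the RF branch
  all_regions <- rbind(unique(harmonized[, c("admin1_id", "country_code")]),
                       regions[, c("admin1_id", "country_code")])
  all_regions <- all_regions[!duplicated(all_regions$admin1_id), ]
  all_regions <- all_regions[order(all_regions$admin1_id), ]
  out <- list()
  rf_targets <- list()
  for (ref in years) {
    for (dom in doms) {
      sub <- harmonized[harmonized$domain == dom, , drop = FALSE]
      for (i in seq_len(nrow(all_regions))) {
        rid <- all_regions$admin1_id[i]
        cc <- all_regions$country_code[i]
        rows <- sub[sub$admin1_id == rid, , drop = FALSE]
        yrs <- rows$survey_year
        method <- select_method(yrs, ref)
        key <- length(out) + 1L
        if (method == "direct") {
          est <- direct_assign(yrs, rows$score, ref)
          nsv <- 1L
        } else if (method == "linear") {
          est <- extrapolate_linear(yrs, rows$score, ref)
          nsv <- length(yrs)
        } else {
          est <- NA_real_
          nsv <- length(yrs)
          rf_targets[[length(rf_targets) + 1L]] <- data.frame(
            idx = key, admin1_id = rid, country_code = cc, year = ref,
            domain = dom, stringsAsFactors = FALSE)
        }
        out[[key]] <- data.frame(
          admin1_id = rid, country_code = cc, year = as.integer(ref),
          domain = dom,
          estimate = est, method = method, n_surveys_used = nsv,
          stringsAsFactors = FALSE)
      }
    }
  }
  est <- do.call(rbind, out)
  if (length(rf_targets)) {
    tg <- do.call(rbind, rf_targets)
    feat_for <- function(rid, cc, yr, dom) {
      rows <- harmonized[harmonized$admin1_id == rid &
                           harmonized$domain == dom, , drop = FALSE]
      sv <- if (nrow(rows))
        rows$score[which.min(abs(rows$survey_year - yr))] else NA_real_
      data.frame(
        hdi = cov_value(covariates, cc, yr, "hdi"),
        maternal_mortality = cov_value(covariates, cc, yr,
                                       "maternal_mortality"),
        pop_density = regions$pop_density[match(rid, regions$admin1_id)],
        survey_value = sv)
    }
    for (dom in unique(tg$domain)) {
      ti <- tg[tg$domain == dom, , drop = FALSE]
      tr <- est[est$domain == dom & est$method != "rf" &
                  !is.na(est$estimate), , drop = FALSE]
      if (!nrow(tr))
        stopf("domain '%s': no direct/linear rows to train RF extrapolation",
              dom)
      train <- do.call(rbind, lapply(seq_len(nrow(tr)), function(j)
        feat_for(tr$admin1_id[j], tr$country_code[j], tr$year[j], dom)))
      train$y <- tr$estimate
      targets <- do.call(rbind, lapply(seq_len(nrow(ti)), function(j)
        feat_for(ti$admin1_id[j], ti$country_code[j], ti$year[j], dom)))
      pred <- extrapolate_rf(train, targets,
                             seed = stage_seed(seed, match(dom, doms)),
                             ntree = ntree)
      est$estimate[ti$idx] <- pred
    }
  }
  rownames(est) <- NULL
  est[order(est$admin1_id, est$year, est$domain), , drop = FALSE]
}
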