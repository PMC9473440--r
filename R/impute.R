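# Random-forest imputation of region-level domain scores that are missing
# because a survey did not ask a question block.

FEATURE_COLS <- c("survey_year", "country_code", "mean_age_first_marriage",
                  "mean_age_first_birth", "mean_years_schooling",
                  "longitude", "latitude", "mean_age", "mean_births_5y")

#' Region-level imputation features
#'
#' Builds the per-(survey, region) predictor table used by
#' [impute_missing()]: survey year and country, region means of age at first
#' marriage, age at first birth, years of schooling, respondent age and
#' births in the last five years, and the region centroid (for survey
#' regions that aggregate several admin-1 units, the mean of the member
#' centroids).
#'
#' @param surveys `femi_surveys` bundle.
#' @param regions admin-1 table with `admin1_id`, `longitude`, `latitude`.
#' @param crosswalk region crosswalk covering every scheme in the metadata.
#' @return data frame keyed by `survey_id` + `region_id`.
#' @export
region_features <- function(surveys, regions, crosswalk) {
  w <- surveys$women
  meta <- surveys$meta
  key <- interaction(w$survey_id, w$region_id, drop = TRUE, sep = "\r")
  mean_by <- function(x) as.numeric(tapply(x, key, function(z)
    if (all(is.na(z))) NA_real_ else mean(z, na.rm = TRUE)))
  parts <- strsplit(levels(key), "\r", fixed = TRUE)
  out <- data.frame(
    survey_id = vapply(parts, `[[`, "", 1L),
    region_id = vapply(parts, `[[`, "", 2L),
    mean_age_first_marriage = mean_by(w$age_first_marriage),
    mean_age_first_birth = mean_by(w$age_first_birth),
    mean_years_schooling = mean_by(w$years_schooling),
    mean_age = mean_by(w$age),
    mean_births_5y = mean_by(w$births_last_5y),
    stringsAsFactors = FALSE)
  mi <- match(out$survey_id, meta$survey_id)
  out$survey_year <- meta$survey_year[mi]
  out$country_code <- meta$country_code[mi]
  # centroid of the survey region: mean over its admin-1 members
  scheme <- meta$scheme_id[mi]
  out$longitude <- NA_real_
  out$latitude <- NA_real_
  for (i in seq_len(nrow(out))) {
    members <- crosswalk$admin1_id[crosswalk$scheme_id == scheme[i] &
                                     crosswalk$region_id == out$region_id[i]]
    ri <- match(members, regions$admin1_id)
    out$longitude[i] <- mean(regions$longitude[ri])
    out$latitude[i] <- mean(regions$latitude[ri])
  }
  out
}

impute_predictors <- function(domain) {
  if (domain %in% c("education_men", "employment_men"))
    return(c("survey_year", "longitude", "latitude"))
  preds <- FEATURE_COLS
  if (domain == "education")
    preds <- setdiff(preds, "mean_years_schooling")
  preds
}

#' Impute missing region-level domain scores
#'
#' For each domain with at least one missing and at least `min_obs` observed
#' (survey, region) rows, fits a random-forest regression of the observed
#' scores on the region features and predicts the missing ones. Predictions
#' are clamped to `[0, 1]` and flagged `provenance = "imputed"`; observed
#' rows are never altered. Predictors are the survey year, country, region
#' means of age at first marriage, age at first birth, years of schooling
#' (dropped for the education domain), respondent age and recent fertility,
#' and the region centroid; the men's auxiliary domains use year, longitude
#' and latitude only. Missing feature values are median/mode-filled before
#' fitting.
#'
#' @param scores region score table (see [score_surveys()]).
#' @param features feature table from [region_features()].
#' @param seed integer seed making the forest fits reproducible.
#' @param ntree trees per forest (default 500).
#' @param min_obs minimum observed rows needed to fit a domain's model
#'   (default 20); below it the domain is skipped with a report note.
#' @return list with `scores` (imputed table) and `report` (one row per
#'   domain: `n_imputed`, `proportion_imputed`, out-of-bag `r2`, predictors
#'   used, note).
#' @export
impute_missing <- function(scores, features, seed = 1L, ntree = 500,
                           min_obs = 20) {
  mf <- match(paste(scores$survey_id, scores$region_id),
              paste(features$survey_id, features$region_id))
  if (anyNA(mf))
    stopf("features missing for survey/region '%s'",
          paste(scores$survey_id, scores$region_id)[which(is.na(mf))[1]])
  miss_feat <- setdiff(FEATURE_COLS, names(features))
  if (length(miss_feat))
    stopf("feature table lacks column '%s'", miss_feat[[1]])
  features$country_code <- factor(features$country_code)
  report <- list()
  out <- scores
  for (dom in unique(scores$domain)) {
    di <- which(scores$domain == dom)
    y <- scores$score[di]
    n_missing <- sum(is.na(y))
    preds <- impute_predictors(dom)
    rep_row <- data.frame(domain = dom, n_imputed = 0L,
                          proportion_imputed = n_missing / length(di),
                          r2 = NA_real_,
                          predictors = paste(preds, collapse = ";"),
                          note = "", stringsAsFactors = FALSE)
    if (n_missing > 0) {
      obs <- di[!is.na(y)]
      mis <- di[is.na(y)]
      if (length(obs) < min_obs) {
        rep_row$note <- sprintf(
          "skipped: %d observed rows < min_obs = %d", length(obs), min_obs)
      } else {
        X <- features[mf[di], preds, drop = FALSE]
        X <- randomForest::na.roughfix(X)
        set.seed(stage_seed(seed, match(dom, sort(unique(scores$domain)))))
        fit <- fit_rf(
          x = X[match(obs, di), , drop = FALSE], y = scores$score[obs],
          ntree = ntree)
        pred <- stats::predict(fit, X[match(mis, di), , drop = FALSE])
        out$score[mis] <- clamp01(as.numeric(pred))
        out$provenance[mis] <- "imputed"
        out$women_raw[mis] <- ifelse(grepl("_men$", dom), NA_real_,
                                     out$score[mis])
        out$men_raw[mis] <- ifelse(grepl("_men$", dom), out$score[mis],
                                   NA_real_)
        rep_row$n_imputed <- length(mis)
        rep_row$r2 <- fit$rsq[length(fit$rsq)]
      }
    }
    report[[dom]] <- rep_row
  }
  report <- do.call(rbind, report)
  rownames(report) <- NULL
  list(scores = out, report = report)
}
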