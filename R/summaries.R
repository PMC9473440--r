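# The FEMI composite and the summary statistics reported alongside it:
# population-weighted percentile summaries, within-country subnational
# ranges, cross-domain correlations, national-index regressions, and the
# age-cohort sensitivity check.

#' Compute the FEMI composite
#'
#' Appends one `femi` row per (region, year) to an estimate table: the
#' arithmetic mean of the six domain estimates (a population median variant
#' is available via `combiner`). Every domain must be present for every
#' region-year.
#'
#' @param estimates estimate table from [estimate_years()].
#' @param combiner `"mean"` (default) or `"median"` of the six domains.
#' @return the estimate table with `femi` rows appended
#'   (`method = "composite"`).
#' @export
compute_femi <- function(estimates, combiner = c("mean", "median")) {
  combiner <- match.arg(combiner)
  doms <- femi_domains()
  est <- estimates[estimates$domain %in% doms, , drop = FALSE]
  key <- interaction(est$admin1_id, est$year, drop = TRUE, sep = "\r")
  fn <- if (combiner == "mean") mean else stats::median
  rows <- lapply(levels(key), function(k) {
    sub <- est[key == k, ]
    missing <- setdiff(doms, sub$domain)
    if (length(missing))
      stopf("region %s, year %s: domain '%s' missing, FEMI undefined",
            sub$admin1_id[1], sub$year[1], missing[[1]])
    data.frame(admin1_id = sub$admin1_id[1],
               country_code = sub$country_code[1],
               year = sub$year[1], domain = "femi",
               estimate = fn(sub$estimate[match(doms, sub$domain)]),
               method = "composite",
               n_surveys_used = NA_integer_, stringsAsFactors = FALSE)
  })
  out <- rbind(estimates, do.call(rbind, rows))
  rownames(out) <- NULL
  out[order(out$admin1_id, out$year, out$domain), , drop = FALSE]
}

#' Weighted quantiles
#'
#' Left-continuous cumulative-weight quantiles: the quantile at probability
#' `q` is the smallest value whose normalized cumulative weight (ascending
#' order) reaches `q`. With equal weights this is the inverse empirical CDF
#' (`stats::quantile(type = 1)`).
#'
#' @param values numeric values.
#' @param weights nonnegative weights, not all zero (default equal).
#' @param probs probabilities in `[0, 1]`.
#' @return quantile values, named by probability.
#' @export
weighted_quantile <- function(values, weights = rep(1, length(values)),
                              probs = c(0.1, 0.5, 0.9)) {
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  if (!length(values)) stop("no non-missing values", call. = FALSE)
  if (any(weights < 0) || sum(weights) == 0)
    stop("weights must be nonnegative and not all zero", call. = FALSE)
  ord <- order(values)
  v <- values[ord]
  cw <- cumsum(weights[ord]) / sum(weights)
  out <- vapply(probs, function(q) v[which(cw >= q - 1e-12)[1]], numeric(1))
  stats::setNames(out, paste0("p", probs * 100))
}

#' Population-weighted continental summary
#'
#' Median and percentile band of the regional estimates per domain and year,
#' weighting each admin-1 region by its female population ("for all women"
#' semantics).
#'
#' @param estimates estimate table including `femi` rows
#'   (see [compute_femi()]).
#' @param regions admin-1 table with `female_population`.
#' @param probs percentiles to report (default 10/50/90).
#' @return data frame: `year`, `domain`, one column per percentile.
#' @export
continental_summary <- function(estimates, regions,
                                probs = c(0.1, 0.5, 0.9)) {
  w <- regions$female_population[match(estimates$admin1_id,
                                       regions$admin1_id)]
  out <- list()
  for (yr in sort(unique(estimates$year))) {
    for (dom in unique(estimates$domain)) {
      sel <- estimates$year == yr & estimates$domain == dom
      if (!any(sel)) next
      qs <- weighted_quantile(estimates$estimate[sel], w[sel], probs)
      out[[length(out) + 1L]] <- cbind(
        data.frame(year = yr, domain = dom, stringsAsFactors = FALSE),
        as.data.frame(as.list(qs)))
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Within-country subnational range
#'
#' The population-weighted 90th-minus-10th percentile spread of a country's
#' admin-1 scores, per domain (and FEMI) and year — the measure of
#' subnational inequality. Single-region countries get a 0 range and a
#' diagnostic note.
#'
#' @param estimates estimate table including `femi` rows.
#' @param regions admin-1 table with `female_population`.
#' @param year reference year to summarize.
#' @return data frame `country_code`, `domain`, `p10`, `p90`, `range`;
#'   single-region diagnostics in the `"diagnostics"` attribute.
#' @export
country_subnational_range <- function(estimates, regions, year) {
  sub <- estimates[estimates$year == year, , drop = FALSE]
  w <- regions$female_population[match(sub$admin1_id, regions$admin1_id)]
  out <- list(); diags <- character()
  for (cc in sort(unique(sub$country_code))) {
    for (dom in unique(sub$domain)) {
      sel <- sub$country_code == cc & sub$domain == dom
      n_regions <- sum(sel)
      if (!n_regions) next
      if (n_regions == 1) {
        diags <- c(diags, sprintf(
          "country %s: single region, range 0 by construction", cc))
        qs <- c(p10 = sub$estimate[sel], p90 = sub$estimate[sel])
      } else {
        qs <- weighted_quantile(sub$estimate[sel], w[sel], c(0.1, 0.9))
      }
      out[[length(out) + 1L]] <- data.frame(
        country_code = cc, domain = dom, p10 = unname(qs[1]),
        p90 = unname(qs[2]), range = unname(qs[2] - qs[1]),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "diagnostics") <- unique(diags)
  res
}

#' Cross-domain Pearson correlations
#'
#' Pairwise Pearson correlation between domain scores over admin-1 units,
#' using each country's most recent survey only. Zero-variance domains give
#' `NA` entries, flagged in the `"degenerate"` attribute.
#'
#' @param harmonized harmonized admin-1 score table
#'   (see [harmonize_scores()]).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
domain_correlations <- function(harmonized) {
  latest <- do.call(rbind, lapply(split(harmonized,
                                        harmonized$country_code),
                                  function(sub) {
    sub[sub$survey_year == max(sub$survey_year), , drop = FALSE]
  }))
  doms <- intersect(femi_domains(), unique(latest$domain))
  wide <- sapply(doms, function(d) {
    sub <- latest[latest$domain == d, ]
    sub$score[match(unique(latest$admin1_id), sub$admin1_id)]
  })
  rownames(wide) <- unique(latest$admin1_id)
  if (nrow(wide) < 3)
    stop("need at least 3 admin-1 units for correlations", call. = FALSE)
  degenerate <- doms[apply(wide, 2, function(x)
    stats::sd(x, na.rm = TRUE) == 0)]
  cm <- suppressWarnings(stats::cor(wide, use = "pairwise.complete.obs"))
  diag(cm) <- 1
  attr(cm, "degenerate") <- degenerate
  cm
}

#' National-index regressions
#'
#' Per index and year, an OLS regression of national FEMI on the index (HDI,
#' GDI, GII, or log10 GDP per capita), with Pearson correlation and
#' per-country residuals. Countries lacking an index value are dropped with
#' a diagnostic.
#'
#' @param country_femi data frame `country_code`, `year`, `femi` (national
#'   FEMI, e.g. population-weighted mean of the regional values).
#' @param covariates country-year covariate table with `hdi`, `gdi`, `gii`,
#'   `gdp_per_capita`.
#' @param indices indices to regress on.
#' @return list: `stats` (index, year, slope, intercept, pearson_r, n),
#'   `residuals` (per country), `dropped` (diagnostics).
#' @export
national_regressions <- function(country_femi, covariates,
                                 indices = c("hdi", "gdi", "gii",
                                             "gdp_per_capita")) {
  stats_l <- list(); resid_l <- list(); dropped <- character()
  for (yr in sort(unique(country_femi$year))) {
    cf <- country_femi[country_femi$year == yr, ]
    mi <- match(paste(cf$country_code, yr),
                paste(covariates$country_code, covariates$year))
    for (ix in indices) {
      x <- covariates[[ix]][mi]
      if (ix == "gdp_per_capita") x <- log10(x)
      keep <- !is.na(x) & !is.na(cf$femi)
      if (any(!keep))
        dropped <- c(dropped, sprintf("%s/%d: no %s value",
                                      cf$country_code[!keep], yr, ix))
      if (sum(keep) < 3)
        stopf("index '%s', year %d: fewer than 3 countries with data",
              ix, yr)
      if (stats::sd(x[keep]) == 0)
        stopf("index '%s', year %d: degenerate design (no variance)",
              ix, yr)
      fit <- stats::lm(cf$femi[keep] ~ x[keep])
      stats_l[[length(stats_l) + 1L]] <- data.frame(
        index = ix, year = yr,
        slope = unname(stats::coef(fit)[2]),
        intercept = unname(stats::coef(fit)[1]),
        pearson_r = stats::cor(x[keep], cf$femi[keep]),
        n = sum(keep), stringsAsFactors = FALSE)
      resid_l[[length(resid_l) + 1L]] <- data.frame(
        index = ix, year = yr, country_code = cf$country_code[keep],
        residual = unname(stats::resid(fit)), stringsAsFactors = FALSE)
    }
  }
  list(stats = do.call(rbind, stats_l),
       residuals = do.call(rbind, resid_l),
       dropped = dropped)
}

#' National FEMI from regional estimates
#'
#' Population-weighted mean of the regional FEMI per country and year.
#'
#' @param estimates estimate table including `femi` rows.
#' @param regions admin-1 table with `female_population`.
#' @return data frame `country_code`, `year`, `femi`.
#' @export
national_femi <- function(estimates, regions) {
  sub <- estimates[estimates$domain == "femi", , drop = FALSE]
  w <- regions$female_population[match(sub$admin1_id, regions$admin1_id)]
  key <- interaction(sub$country_code, sub$year, drop = TRUE, sep = "\r")
  v <- tapply(seq_len(nrow(sub)), key, function(i)
    wmean(sub$estimate[i], w[i]))
  parts <- strsplit(names(v), "\r", fixed = TRUE)
  data.frame(country_code = vapply(parts, `[[`, "", 1L),
             year = as.integer(vapply(parts, `[[`, "", 2L)),
             femi = as.numeric(v), stringsAsFactors = FALSE,
             row.names = NULL)
}

# respondent-level values for the cohort check
cohort_domain_value <- function(women, births, domain) {
  switch(domain,
    ipv_sexual = ifelse(!is.na(women$age_first_marriage),
                        as.numeric(women$age_first_marriage >= 18),
                        ifelse(!is.na(women$currently_married) &
                                 !women$currently_married, 1, NA_real_)),
    reproductive_healthcare = score_reproductive_healthcare(women, births),
    education = score_education(women),
    ipv = score_ipv(women),
    stopf("cohort check not defined for domain '%s'", domain))
}

#' Age-cohort sensitivity check
#'
#' Compares the continental weighted score computed on women aged 18-30
#' against the 18-49 sample, per domain — a check that the wide respondent
#' age range does not distort domains with a long recall horizon (child
#' marriage, adolescent childbearing, schooling).
#'
#' @param surveys `femi_surveys` bundle.
#' @param domains domains to check (`ipv_sexual` is the child-marriage
#'   category of IPV alone).
#' @return data frame `domain`, `score_18_30`, `score_18_49`, `difference`.
#' @export
cohort_sensitivity <- function(surveys,
                               domains = c("ipv_sexual",
                                           "reproductive_healthcare",
                                           "education")) {
  w <- surveys$women
  young <- !is.na(w$age) & w$age >= 18 & w$age <= 30
  full <- !is.na(w$age) & w$age >= 18 & w$age <= 49
  if (!any(young) || !any(full))
    stop("empty age subsample", call. = FALSE)
  out <- lapply(domains, function(dom) {
    v <- cohort_domain_value(w, surveys$births, dom)
    s30 <- wmean(v[young], w$sample_weight[young])
    s49 <- wmean(v[full], w$sample_weight[full])
    data.frame(domain = dom, score_18_30 = s30, score_18_49 = s49,
               difference = s30 - s49, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
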