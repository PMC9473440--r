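# Top-level estimator: one call from survey microdata to reference-year
# estimates and the FEMI composite, plus the staged file pipeline.

#' Fit subnational empowerment estimates from survey microdata
#'
#' Runs the full estimation sequence — respondent scoring, regional
#' aggregation, random-forest imputation of missing region scores, the
#' gender-inequality adjustment of Education and Employment, boundary
#' harmonization onto admin-1 units, and reference-year estimation — and
#' appends the FEMI composite. Stages are individually available as
#' [score_surveys()], [impute_missing()], [apply_inequality_adjustment()],
#' [harmonize_scores()], [estimate_years()] and [compute_femi()].
#'
#' @param surveys `femi_surveys` microdata bundle (see [read_survey()] or
#'   [simulate_surveys()]).
#' @param regions admin-1 table: ids, centroids, female population,
#'   population density.
#' @param crosswalk region crosswalk covering every survey scheme.
#' @param covariates country-year covariates (HDI, maternal mortality, GDP,
#'   GDI, GII).
#' @param years reference years (default 1995, 2005, 2015).
#' @param seed integer seed; fanned out to per-stage seeds.
#' @param use_weights apply respondent sampling weights when aggregating.
#' @param combiner FEMI combiner, `"mean"` (default) or `"median"`.
#' @param plan optional harmonization plan overrides
#'   (see [harmonize_scores()]).
#' @param ntree random-forest size for imputation and extrapolation.
#' @param min_obs minimum observed region rows to fit an imputation model.
#' @return an object of class `femi`: list with `estimates` (the annual
#'   estimate table with `femi` rows), `harmonized`, `region_scores`,
#'   `imputation` (per-domain report), plus the inputs needed by the
#'   summary methods.
#' @seealso [summary.femi()], [cohort_sensitivity()], [run_pipeline()]
#' @export
femi <- function(surveys, regions, crosswalk, covariates,
                 years = c(1995, 2005, 2015), seed = 1L,
                 use_weights = TRUE, combiner = c("mean", "median"),
                 plan = NULL, ntree = 500, min_obs = 20) {
  stopifnot(inherits(surveys, "femi_surveys"), length(years) >= 1)
  combiner <- match.arg(combiner)
  validate_crosswalk(crosswalk)
  scores <- score_surveys(surveys, use_weights = use_weights)
  feats <- region_features(surveys, regions, crosswalk)
  imp <- impute_missing(scores, feats, seed = stage_seed(seed, 101L),
                        ntree = ntree, min_obs = min_obs)
  adjusted <- apply_inequality_adjustment(imp$scores)
  harmonized <- harmonize_scores(adjusted, surveys$meta, crosswalk, regions,
                                 plan = plan)
  est <- estimate_years(harmonized, covariates, regions, years = years,
                        seed = stage_seed(seed, 202L), ntree = ntree)
  est <- compute_femi(est, combiner = combiner)
  structure(list(estimates = est, harmonized = harmonized,
                 region_scores = adjusted, imputation = imp$report,
                 meta = surveys$meta, regions = regions,
                 covariates = covariates, years = years, seed = seed,
                 combiner = combiner, call = match.call()),
            class = "femi")
}

#' @export
print.femi <- function(x, ...) {
  est <- x$estimates
  cat("Subnational empowerment estimates (FEMI)\n")
  cat(sprintf("  surveys: %d   admin-1 regions: %d   reference years: %s\n",
              nrow(x$meta), length(unique(est$admin1_id)),
              paste(x$years, collapse = ", ")))
  meth <- table(est$method[est$domain != "femi"])
  cat(sprintf("  estimates by method: %s\n",
              paste(sprintf("%s=%d", names(meth), meth), collapse = "  ")))
  fem <- est[est$domain == "femi", ]
  for (yr in sort(unique(fem$year)))
    cat(sprintf("  FEMI %d: median %.3f across %d regions\n", yr,
                stats::median(fem$estimate[fem$year == yr]),
                sum(fem$year == yr)))
  invisible(x)
}

#' Summarize a fitted estimate table
#'
#' Computes the reporting statistics: the population-weighted continental
#' median and 10th/90th percentiles per domain and year, per-country
#' subnational ranges at the latest reference year, cross-domain Pearson
#' correlations (most recent survey per country), and national regressions
#' of FEMI on HDI, GDI, GII and log GDP.
#'
#' @param object a `femi` fit.
#' @param ... unused.
#' @return object of class `summary.femi`: list with `continental`,
#'   `country_ranges`, `correlations`, `regressions`.
#' @export
summary.femi <- function(object, ...) {
  cont <- continental_summary(object$estimates, object$regions)
  yr <- max(object$years)
  ranges <- country_subnational_range(object$estimates, object$regions, yr)
  corr <- tryCatch(domain_correlations(object$harmonized),
                   error = function(e) NULL)
  regs <- tryCatch(
    national_regressions(national_femi(object$estimates, object$regions),
                         object$covariates),
    error = function(e) NULL)
  structure(list(continental = cont, country_ranges = ranges,
                 correlations = corr, regressions = regs,
                 range_year = yr),
            class = "summary.femi")
}

#' @export
print.summary.femi <- function(x, ...) {
  cat("Population-weighted continental summary (median [p10-p90]):\n")
  cont <- x$continental
  for (yr in sort(unique(cont$year))) {
    cat(sprintf("  %d:\n", yr))
    sub <- cont[cont$year == yr, ]
    for (i in seq_len(nrow(sub)))
      cat(sprintf("    %-24s %.2f (%.2f-%.2f)\n", sub$domain[i],
                  sub$p50[i], sub$p10[i], sub$p90[i]))
  }
  if (!is.null(x$country_ranges)) {
    rng <- x$country_ranges
    med <- tapply(rng$range, rng$domain, stats::median)
    cat(sprintf("Median within-country p10-p90 range in %d:\n",
                x$range_year))
    for (d in names(med)) cat(sprintf("    %-24s %.2f\n", d, med[[d]]))
  }
  if (!is.null(x$regressions)) {
    cat("National FEMI regressions (slope / Pearson r):\n")
    st <- x$regressions$stats
    for (i in seq_len(nrow(st)))
      cat(sprintf("    %-16s %d  %+.3f / %+.2f\n", st$index[i], st$year[i],
                  st$slope[i], st$pearson_r[i]))
  }
  invisible(x)
}

#' Plot continental trends of a fit
#'
#' Base-graphics plot of the population-weighted continental median per
#' domain and FEMI across the reference years.
#'
#' @param x a `femi` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.femi <- function(x, ...) {
  cont <- continental_summary(x$estimates, x$regions)
  doms <- c(femi_domains(), "femi")
  yrs <- sort(unique(cont$year))
  m <- sapply(doms, function(d)
    cont$p50[match(paste(yrs, d), paste(cont$year, cont$domain))])
  graphics::matplot(yrs, m, type = "b", pch = 19, lty = 1,
                    xlab = "year", ylab = "population-weighted median score",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = doms, col = seq_along(doms), pch = 19,
                   cex = 0.7, bty = "n")
  invisible(x)
}

#' @export
as.data.frame.femi <- function(x, ...) x$estimates

# plain CSV writer for report tables without a registered schema
write_plain_csv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  df[num] <- lapply(df[num], function(x) formatC(x, format = "f",
                                                 digits = 6))
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Run the staged file pipeline
#'
#' File-level orchestration of [femi()]: validates the configuration, reads
#' the CSV inputs, executes scoring, imputation, harmonization, estimation
#' and the FEMI composite in order, writes every intermediate table as CSV,
#' and records a manifest (stage, file, md5, seconds) enabling byte-level
#' reproducibility checks. Any stage failure aborts with a stage-named
#' error.
#'
#' @param config named list: `input_dir` (directory with `women.csv`,
#'   `men.csv`, `births.csv`, `survey_meta.csv`, `crosswalk.csv`,
#'   `regions.csv`, `covariates.csv`), `out_dir`, and optionally `years`,
#'   `seed`, `use_weights`, `combiner`, `plan`.
#' @return the manifest data frame, invisibly; outputs land in
#'   `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  need <- c("input_dir", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stopf("pipeline config: missing field '%s'", miss[[1]])
  years <- config$years %||% c(1995, 2005, 2015)
  if (!length(years)) stop("pipeline config: empty years", call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  files <- c("women.csv", "men.csv", "births.csv", "survey_meta.csv",
             "crosswalk.csv", "regions.csv", "covariates.csv")
  for (f in files) {
    p <- file.path(config$input_dir, f)
    if (!file.exists(p))
      stopf("pipeline config validation: required input '%s' not found", p)
  }
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  manifest <- list()
  note <- function(stage, path, t0) {
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, file = basename(path),
      md5 = unname(tools::md5sum(path)),
      seconds = round(as.numeric(Sys.time()) - t0, 3),
      stringsAsFactors = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
  }
  t0 <- as.numeric(Sys.time())
  surveys <- run_stage("read", read_survey(config$input_dir))
  crosswalk <- run_stage("read",
                         read_crosswalk(file.path(config$input_dir,
                                                  "crosswalk.csv")))
  regions <- run_stage("read",
                       read_femi_csv(file.path(config$input_dir,
                                               "regions.csv"), "regions"))
  covariates <- run_stage("read",
                          read_femi_csv(file.path(config$input_dir,
                                                  "covariates.csv"),
                                        "covariates"))
  scores <- run_stage("score",
                      score_surveys(surveys,
                                    use_weights = config$use_weights %||%
                                      TRUE))
  feats <- run_stage("score", region_features(surveys, regions, crosswalk))
  sc_path <- file.path(config$out_dir, "region_scores.csv")
  write_femi_csv(scores, sc_path, "region_scores")
  note("score", sc_path, t0)

  t0 <- as.numeric(Sys.time())
  imp <- run_stage("impute",
                   impute_missing(scores, feats,
                                  seed = stage_seed(seed, 101L)))
  adjusted <- run_stage("impute", apply_inequality_adjustment(imp$scores))
  imp_path <- file.path(config$out_dir, "imputed_scores.csv")
  write_femi_csv(adjusted, imp_path, "region_scores")
  rep_path <- file.path(config$out_dir, "imputation_report.csv")
  write_plain_csv(imp$report, rep_path)
  note("impute", imp_path, t0); note("impute", rep_path, t0)

  t0 <- as.numeric(Sys.time())
  harmonized <- run_stage("harmonize",
                          harmonize_scores(adjusted, surveys$meta,
                                           crosswalk, regions,
                                           plan = config$plan))
  h_path <- file.path(config$out_dir, "harmonized.csv")
  write_plain_csv(harmonized, h_path)
  note("harmonize", h_path, t0)

  t0 <- as.numeric(Sys.time())
  est <- run_stage("estimate",
                   estimate_years(harmonized, covariates, regions,
                                  years = years,
                                  seed = stage_seed(seed, 202L)))
  est <- run_stage("femi",
                   compute_femi(est, combiner = config$combiner %||%
                                  "mean"))
  est_path <- file.path(config$out_dir, "estimates.csv")
  write_femi_csv(est, est_path, "estimates")
  note("estimate", est_path, t0)

  t0 <- as.numeric(Sys.time())
  cont <- run_stage("summarize", continental_summary(est, regions))
  cont_path <- file.path(config$out_dir, "continental_summary.csv")
  write_plain_csv(cont, cont_path)
  rng <- run_stage("summarize",
                   country_subnational_range(est, regions, max(years)))
  rng_path <- file.path(config$out_dir, "country_ranges.csv")
  write_plain_csv(rng, rng_path)
  note("summarize", cont_path, t0); note("summarize", rng_path, t0)

  manifest <- do.call(rbind, manifest)
  manifest$seed <- seed
  man_path <- file.path(config$out_dir, "manifest.csv")
  write_plain_csv(manifest, man_path)
  invisible(manifest)
}
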