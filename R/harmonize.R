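# Boundary harmonization: converting scores reported on historical or
# aggregated survey regions ("super-regions") onto current admin-1 units,
# preserving the observed super-region aggregates.

check_membership <- function(membership, weights) {
  if (is.null(names(membership)) || is.null(names(weights)))
    stop("membership and weights must be named by admin-1 id",
         call. = FALSE)
  for (g in unique(membership)) {
    wg <- weights[names(membership)[membership == g]]
    if (anyNA(wg) || sum(wg) <= 0)
      stopf("super-region '%s' has zero or missing member weights", g)
  }
}

#' Harmonize a bracketed non-standard survey to admin-1 units
#'
#' For a survey reported on super-regions with admin-1 surveys both before
#' and after it: each admin-1 unit gets the year-weighted mean of its scores
#' in the bracketing surveys,
#' `v_hat(r) = ((t1 - t) v0(r) + (t - t0) v1(r)) / (t1 - t0)`,
#' then a per-super-region linear adjustment factor
#' `f(g) = observed(g) / weighted mean of v_hat over g` rescales the members
#' so that the weighted mean over each super-region reproduces the observed
#' value exactly (before clamping). Where the observed value or the
#' interpolated aggregate is 0 the multiplicative factor is undefined and an
#' additive shift `observed - aggregate` is used instead.
#'
#' @param observed named vector: observed super-region scores (one domain).
#' @param before,after named vectors: admin-1 scores of the bracketing
#'   surveys.
#' @param target_year,before_year,after_year survey years,
#'   `before_year < target_year < after_year`.
#' @param membership named character vector mapping each admin-1 id to its
#'   super-region id.
#' @param weights named vector of admin-1 aggregation weights (survey sample
#'   counts or population).
#' @param clamp clamp final scores to `[0, 1]` (default TRUE).
#' @return data frame with `admin1_id`, `score`, and the pre-clamp
#'   `score_unclamped`.
#' @export
harmonize_bracketed <- function(observed, before, after,
                                target_year, before_year, after_year,
                                membership, weights, clamp = TRUE) {
  stopifnot(before_year < target_year, target_year < after_year)
  check_membership(membership, weights)
  units <- names(membership)
  miss <- units[!(units %in% names(before)) | !(units %in% names(after))]
  if (length(miss))
    stopf("admin-1 unit '%s' absent from a bracketing survey", miss[[1]])
  span <- after_year - before_year
  vhat <- ((after_year - target_year) * before[units] +
             (target_year - before_year) * after[units]) / span
  out <- numeric(length(units))
  for (g in unique(membership)) {
    sel <- membership == g
    if (!g %in% names(observed))
      stopf("super-region '%s' absent from the target survey", g)
    agg <- wmean(vhat[sel], weights[units][sel])
    obs <- observed[[g]]
    out[sel] <- if (is.na(agg) || agg == 0 || obs == 0)
      vhat[sel] + (obs - agg) else vhat[sel] * (obs / agg)
  }
  data.frame(admin1_id = units,
             score = if (clamp) clamp01(out) else out,
             score_unclamped = out,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Harmonize a single-predictor non-standard survey to admin-1 units
#'
#' For a survey reported on super-regions when only one admin-1 survey
#' exists for the country: the predictor survey's admin-1 values are
#' aggregated to the super-regions, the per-super-region difference
#' `d(g) = observed(g) - aggregate(g)` is computed, and each admin-1 member
#' is shifted by its super-region's difference (downscaling the larger
#' regions), preserving the observed aggregates exactly before clamping.
#'
#' @param observed named vector: observed super-region scores (one domain).
#' @param predictor named vector: admin-1 scores of the predictor survey.
#' @inheritParams harmonize_bracketed
#' @return data frame with `admin1_id`, `score`, `score_unclamped`.
#' @export
harmonize_single <- function(observed, predictor, membership, weights,
                             clamp = TRUE) {
  check_membership(membership, weights)
  units <- names(membership)
  miss <- units[!(units %in% names(predictor))]
  if (length(miss))
    stopf("admin-1 unit '%s' absent from the predictor survey", miss[[1]])
  out <- numeric(length(units))
  for (g in unique(membership)) {
    sel <- membership == g
    if (!g %in% names(observed))
      stopf("super-region '%s' absent from the target survey", g)
    agg <- wmean(predictor[units][sel], weights[units][sel])
    out[sel] <- predictor[units][sel] + (observed[[g]] - agg)
  }
  data.frame(admin1_id = units,
             score = if (clamp) clamp01(out) else out,
             score_unclamped = out,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Aggregate admin-2 scores to admin-1 units
#'
#' Weighted mean of the member admin-2 scores per admin-1 unit, used for the
#' few surveys reported below the first administrative level.
#'
#' @param scores named vector of admin-2 scores.
#' @param mapping named character vector mapping admin-2 id to admin-1 id.
#' @param weights named vector of admin-2 weights (default equal).
#' @return named vector of admin-1 scores.
#' @export
aggregate_admin2 <- function(scores, mapping,
                             weights = stats::setNames(
                               rep(1, length(scores)), names(scores))) {
  unmapped <- names(scores)[!names(scores) %in% names(mapping)]
  if (length(unmapped))
    stopf("admin-2 unit '%s' not mapped to an admin-1 unit", unmapped[[1]])
  g <- mapping[names(scores)]
  vapply(split(seq_along(scores), g), function(i)
    wmean(scores[i], weights[names(scores)[i]]), numeric(1))
}

scheme_is_identity <- function(crosswalk, scheme_id) {
  sub <- crosswalk[crosswalk$scheme_id == scheme_id, , drop = FALSE]
  !anyDuplicated(sub$region_id) && !anyDuplicated(sub$admin1_id)
}

# per-admin1 aggregation weights for one domain: survey sample counts from
# the given admin-1 survey rows, falling back to regional population
admin1_weights <- function(source_rows, units, regions) {
  w <- stats::setNames(rep(NA_real_, length(units)), units)
  if (nrow(source_rows)) {
    got <- tapply(source_rows$effective_n, source_rows$admin1_id, sum,
                  na.rm = TRUE)
    w[names(got)] <- as.numeric(got)
  }
  bad <- is.na(w) | w <= 0
  if (any(bad))
    w[bad] <- regions$female_population[match(units[bad],
                                              regions$admin1_id)]
  w
}

#' Harmonize a region score table onto admin-1 units
#'
#' Drives the two interpolation procedures over all surveys of a score
#' table. Surveys already on a one-to-one (admin-1) scheme pass through with
#' their region ids translated; surveys on aggregated schemes are harmonized
#' with [harmonize_bracketed()] when admin-1 surveys exist both before and
#' after them in the same country, and with [harmonize_single()] against the
#' nearest admin-1 survey otherwise. Aggregation weights are the bracketing
#' (or predictor) survey's per-domain sample counts, falling back to female
#' population. The automatic plan can be overridden per survey.
#'
#' @param region_scores region score table restricted to the six domains
#'   (after imputation and inequality adjustment).
#' @param meta survey metadata table.
#' @param crosswalk region crosswalk covering every scheme in `meta`.
#' @param regions admin-1 table (for population fallback weights).
#' @param plan optional named list of per-survey overrides, each a list with
#'   `method` (`"bracketed"` or `"single"`) and survey ids `before`/`after`
#'   or `predictor`.
#' @param clamp clamp harmonized scores to `[0, 1]` (default TRUE).
#' @return harmonized table: `survey_id`, `admin1_id`, `country_code`,
#'   `survey_year`, `domain`, `score`, `score_unclamped`, `effective_n`,
#'   `provenance` (`interpolated` for harmonized rows).
#' @export
harmonize_scores <- function(region_scores, meta, crosswalk, regions,
                             plan = NULL, clamp = TRUE) {
  validate_crosswalk(crosswalk)
  out <- list()
  meta_i <- match(region_scores$survey_id, meta$survey_id)
  if (anyNA(meta_i))
    stopf("survey '%s' missing from metadata",
          region_scores$survey_id[which(is.na(meta_i))[1]])
  # pass 1: surveys already on one-to-one schemes
  std <- list()
  for (sid in unique(meta$survey_id)) {
    scheme <- meta$scheme_id[meta$survey_id == sid]
    rows <- region_scores[region_scores$survey_id == sid, , drop = FALSE]
    if (!nrow(rows)) next
    if (scheme_is_identity(crosswalk, scheme)) {
      cw <- crosswalk[crosswalk$scheme_id == scheme, , drop = FALSE]
      rows$admin1_id <- cw$admin1_id[match(rows$region_id, cw$region_id)]
      if (anyNA(rows$admin1_id))
        stopf("survey '%s': region '%s' missing from crosswalk scheme '%s'",
              sid, rows$region_id[which(is.na(rows$admin1_id))[1]], scheme)
      rows$score_unclamped <- rows$score
      std[[sid]] <- rows
    }
  }
  admin1_surveys <- names(std)
  for (sid in unique(meta$survey_id)) {
    rows <- region_scores[region_scores$survey_id == sid, , drop = FALSE]
    if (!nrow(rows)) next
    mrow <- meta[meta$survey_id == sid, ]
    if (sid %in% admin1_surveys) {
      out[[sid]] <- std[[sid]]
      next
    }
    scheme <- mrow$scheme_id
    cw <- crosswalk[crosswalk$scheme_id == scheme, , drop = FALSE]
    membership <- stats::setNames(cw$region_id, cw$admin1_id)
    cc_meta <- meta[meta$country_code == mrow$country_code &
                      meta$survey_id %in% admin1_surveys, , drop = FALSE]
    ov <- plan[[sid]]
    if (!is.null(ov) && ov$method == "bracketed") {
      before_id <- ov$before; after_id <- ov$after
    } else if (!is.null(ov) && ov$method == "single") {
      before_id <- after_id <- NULL; pred_id <- ov$predictor
    } else {
      earlier <- cc_meta[cc_meta$survey_year < mrow$survey_year, ]
      later <- cc_meta[cc_meta$survey_year > mrow$survey_year, ]
      before_id <- if (nrow(earlier))
        earlier$survey_id[which.max(earlier$survey_year)] else NULL
      after_id <- if (nrow(later))
        later$survey_id[which.min(later$survey_year)] else NULL
    }
    bracketed <- (!is.null(before_id) && !is.null(after_id)) &&
      (is.null(ov) || ov$method == "bracketed")
    harm <- list()
    for (dom in unique(rows$domain)) {
      drow <- rows[rows$domain == dom, ]
      observed <- stats::setNames(drow$score, drow$region_id)
      if (bracketed) {
        b <- std[[before_id]]; a <- std[[after_id]]
        bs <- b[b$domain == dom, ]; as_ <- a[a$domain == dom, ]
        wts <- admin1_weights(rbind(bs, as_), names(membership), regions)
        hv <- harmonize_bracketed(
          observed,
          stats::setNames(bs$score, bs$admin1_id),
          stats::setNames(as_$score, as_$admin1_id),
          mrow$survey_year,
          meta$survey_year[meta$survey_id == before_id],
          meta$survey_year[meta$survey_id == after_id],
          membership, wts, clamp = clamp)
      } else {
        if (is.null(ov) || is.null(ov$predictor)) {
          if (!nrow(cc_meta))
            stopf("survey '%s': no admin-1 survey available in country '%s' to harmonize against",
                  sid, mrow$country_code)
          pred_id <- cc_meta$survey_id[
            which.min(abs(cc_meta$survey_year - mrow$survey_year))]
        }
        p <- std[[pred_id]]
        ps <- p[p$domain == dom, ]
        wts <- admin1_weights(ps, names(membership), regions)
        hv <- harmonize_single(observed,
                               stats::setNames(ps$score, ps$admin1_id),
                               membership, wts, clamp = clamp)
      }
      hv$domain <- dom
      harm[[dom]] <- hv
    }
    harm <- do.call(rbind, harm)
    harm$survey_id <- sid
    harm$region_id <- NA_character_
    harm$effective_n <- NA_real_
    harm$women_raw <- NA_real_
    harm$men_raw <- NA_real_
    harm$provenance <- "interpolated"
    out[[sid]] <- harm[, c("survey_id", "region_id", "admin1_id", "domain",
                           "score", "score_unclamped", "effective_n",
                           "women_raw", "men_raw", "provenance")]
  }
  res <- do.call(rbind, lapply(out, function(d)
    d[, c("survey_id", "admin1_id", "domain", "score", "score_unclamped",
          "effective_n", "provenance")]))
  res$country_code <- meta$country_code[match(res$survey_id,
                                              meta$survey_id)]
  res$survey_year <- meta$survey_year[match(res$survey_id, meta$survey_id)]
  rownames(res) <- NULL
  res[order(res$survey_id, res$admin1_id, res$domain), , drop = FALSE]
}
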