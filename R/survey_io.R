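# Open tabular schemas for all pipeline inputs and outputs, and
# deterministic CSV readers/writers with row-level validation.
#
# Files are plain CSV (UTF-8, RFC 4180 quoting) whose first line is a
# versioned schema marker, e.g. "# femi women v1". Missing values are
# empty fields on disk and NA in memory.

SCHEMA_VERSION <- "v1"

# Categorical answer domains (DHS-style coded answers).
LEVELS_WORK <- c("all_year", "part_year_or_seasonal", "none")
LEVELS_PAY <- c("cash", "cash_and_in_kind", "in_kind_only", "unpaid")
LEVELS_DECISION <- c("self", "self_and_partner", "partner_only", "other")
LEVELS_YESNO <- c("yes", "no")

DECISION_COLS <- c("decision_health", "decision_purchases", "decision_visits",
                   "decision_food", "decision_money")
BEATING_COLS <- c("beat_goes_out", "beat_neglect", "beat_argues",
                  "beat_refuses_sex", "beat_burns_food")

# type codes: chr, int, num, lgl, or cat:<levelset>
femi_schemas <- function() {
  woman_cols <- c(
    respondent_id = "chr", survey_id = "chr", region_id = "chr",
    sample_weight = "num", age = "int", currently_married = "lgl",
    age_first_marriage = "int", age_first_birth = "int",
    wants_child_within_2y = "lgl", uses_modern_contraception = "lgl",
    stats::setNames(rep("cat:decision", 5), DECISION_COLS),
    stats::setNames(rep("cat:yesno", 5), BEATING_COLS),
    years_schooling = "int", literate = "lgl",
    work_regularity = "cat:work", payment_type = "cat:pay",
    births_last_5y = "int")
  list(
    women = woman_cols,
    men = c(respondent_id = "chr", survey_id = "chr", region_id = "chr",
            sample_weight = "num", years_schooling = "int", literate = "lgl",
            work_regularity = "cat:work", payment_type = "cat:pay"),
    births = c(respondent_id = "chr", survey_id = "chr",
               antenatal_visits = "int", professional_delivery = "lgl",
               postnatal_within_2mo = "lgl"),
    survey_meta = c(survey_id = "chr", country_code = "chr",
                    survey_year = "int", scheme_id = "chr",
                    omitted_questions = "chr"),
    crosswalk = c(scheme_id = "chr", region_id = "chr", admin1_id = "chr"),
    regions = c(admin1_id = "chr", country_code = "chr", longitude = "num",
                latitude = "num", female_population = "num",
                pop_density = "num"),
    covariates = c(country_code = "chr", year = "int", hdi = "num",
                   maternal_mortality = "num", gdp_per_capita = "num",
                   gdi = "num", gii = "num"),
    region_scores = c(survey_id = "chr", region_id = "chr", domain = "chr",
                      score = "num", effective_n = "num", women_raw = "num",
                      men_raw = "num", provenance = "chr"),
    estimates = c(admin1_id = "chr", country_code = "chr", year = "int",
                  domain = "chr", estimate = "num", method = "chr",
                  n_surveys_used = "int"),
    ground_truth = c(admin1_id = "chr", country_code = "chr", year = "int",
                     domain = "chr", latent_score = "num"))
}

cat_levels <- function(code) {
  switch(sub("^cat:", "", code),
         work = LEVELS_WORK, pay = LEVELS_PAY,
         decision = LEVELS_DECISION, yesno = LEVELS_YESNO,
         stopf("unknown categorical set '%s'", code))
}

#' Write a pipeline table to CSV
#'
#' Writes a table in one of the package's published CSV schemas with the
#' versioned header line, stable column order, empty-field missing markers and
#' six-decimal fixed formatting for real-valued columns.
#'
#' @param df data frame matching the schema (extra columns are an error).
#' @param path output file path.
#' @param table schema name, e.g. `"women"`, `"crosswalk"`, `"estimates"`.
#' @return `path`, invisibly.
#' @export
write_femi_csv <- function(df, path, table) {
  sch <- femi_schemas()[[table]]
  if (is.null(sch)) stopf("unknown table '%s'", table)
  missing_cols <- setdiff(names(sch), names(df))
  if (length(missing_cols))
    stopf("table '%s': missing column '%s'", table, missing_cols[[1]])
  df <- df[names(sch)]
  out <- df
  for (col in names(sch)) {
    code <- sch[[col]]
    x <- df[[col]]
    out[[col]] <- if (code == "num") {
      ifelse(is.na(x), "", formatC(as.numeric(x), format = "f", digits = 6))
    } else if (code == "lgl") {
      ifelse(is.na(x), "", ifelse(as.logical(x), "TRUE", "FALSE"))
    } else {
      ifelse(is.na(x), "", as.character(x))
    }
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# femi %s %s", table, SCHEMA_VERSION), con)
  utils::write.csv(out, con, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

coerce_column <- function(x, code, col) {
  x[!is.na(x) & x == ""] <- NA
  if (code == "chr") return(as.character(x))
  if (code == "int") {
    v <- suppressWarnings(as.integer(x))
    bad <- !is.na(x) & is.na(v)
    return(list(value = v, bad = bad))
  }
  if (code == "num") {
    v <- suppressWarnings(as.numeric(x))
    bad <- !is.na(x) & is.na(v)
    return(list(value = v, bad = bad))
  }
  if (code == "lgl") {
    v <- rep(NA, length(x))
    v[x %in% c("TRUE", "true", "T", "1")] <- TRUE
    v[x %in% c("FALSE", "false", "F", "0")] <- FALSE
    bad <- !is.na(x) & is.na(v)
    return(list(value = v, bad = bad))
  }
  lev <- cat_levels(code)
  bad <- !is.na(x) & !(x %in% lev)
  list(value = as.character(x), bad = bad)
}

#' Read a pipeline table from CSV
#'
#' Reads a CSV written by [write_femi_csv()], checking the schema version line
#' and the header. Type or value-domain violations are reported per row: the
#' offending rows are dropped and described in the `"diagnostics"` attribute
#' (a data frame with `table`, `row`, `field`, `problem`), so that
#' `nrow(result) + nrow(diagnostics-rows-dropped)` always equals the file's
#' row count.
#'
#' @param path CSV file path.
#' @param table schema name.
#' @return data frame with typed columns and a `diagnostics` attribute.
#' @export
read_femi_csv <- function(path, table) {
  sch <- femi_schemas()[[table]]
  if (is.null(sch)) stopf("unknown table '%s'", table)
  if (!file.exists(path)) stopf("file not found: %s", path)
  first <- readLines(path, n = 1L)
  expected <- sprintf("# femi %s %s", table, SCHEMA_VERSION)
  if (!identical(first, expected))
    stopf("schema mismatch in %s: expected header line '%s', found '%s'",
          path, expected, first)
  raw <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                         check.names = FALSE, na.strings = NULL,
                         fileEncoding = "UTF-8")
  if (!identical(names(raw), names(sch))) {
    off <- which(names(raw) != names(sch)[seq_along(names(raw))])
    bad <- if (length(off)) names(raw)[off[1]] else
      names(sch)[length(names(raw)) + 1L]
    stopf("schema mismatch in %s: unexpected or missing column '%s'",
          path, bad)
  }
  n <- nrow(raw)
  bad_row <- rep(FALSE, n)
  diags <- list()
  out <- raw
  for (col in names(sch)) {
    res <- coerce_column(raw[[col]], sch[[col]], col)
    if (is.list(res)) {
      out[[col]] <- res$value
      if (any(res$bad)) {
        rows <- which(res$bad)
        diags[[length(diags) + 1L]] <- data.frame(
          table = table, row = rows, field = col,
          problem = sprintf("value '%s' outside the %s domain",
                            raw[[col]][rows], sch[[col]]),
          stringsAsFactors = FALSE)
        bad_row[rows] <- TRUE
      }
    } else {
      out[[col]] <- res
    }
  }
  # semantic range checks
  add_diag <- function(rows, field, problem) {
    if (!length(rows)) return()
    diags[[length(diags) + 1L]] <<- data.frame(
      table = table, row = rows, field = field, problem = problem,
      stringsAsFactors = FALSE)
    bad_row[rows] <<- TRUE
  }
  if (table %in% c("women", "men")) {
    add_diag(which(!is.na(out$sample_weight) & out$sample_weight < 0),
             "sample_weight", "negative sample weight")
  }
  if (table == "women") {
    add_diag(which(!is.na(out$age) & (out$age < 15 | out$age > 49)),
             "age", "age outside [15, 49]")
    add_diag(which(!is.na(out$births_last_5y) & out$births_last_5y < 0),
             "births_last_5y", "negative birth count")
  }
  if (table == "survey_meta") {
    add_diag(which(!is.na(out$survey_year) &
                     (out$survey_year < 1985 | out$survey_year > 2020)),
             "survey_year", "survey year outside [1985, 2020]")
  }
  if (table == "births") {
    add_diag(which(!is.na(out$antenatal_visits) & out$antenatal_visits < 0),
             "antenatal_visits", "negative visit count")
  }
  diagnostics <- if (length(diags)) do.call(rbind, diags) else
    data.frame(table = character(), row = integer(), field = character(),
               problem = character(), stringsAsFactors = FALSE)
  kept <- out[!bad_row, , drop = FALSE]
  rownames(kept) <- NULL
  attr(kept, "diagnostics") <- diagnostics
  kept
}

#' Bundle survey microdata tables
#'
#' Collects the women's, men's and birth-event tables together with survey
#' metadata into a `femi_surveys` object, the unit the scoring and pipeline
#' functions operate on. All tables may span multiple surveys; rows are keyed
#' by `survey_id`.
#'
#' @param women women's respondent table (see the `women` schema).
#' @param men men's respondent table.
#' @param births one row per birth in the last three years, keyed by
#'   `respondent_id` + `survey_id`.
#' @param meta survey-level metadata (country, year, region scheme,
#'   omitted question blocks).
#' @return object of class `femi_surveys`.
#' @export
femi_surveys <- function(women, men, births, meta) {
  for (sid in unique(women$survey_id))
    if (!sid %in% meta$survey_id)
      stopf("survey '%s' present in microdata but absent from metadata", sid)
  structure(list(women = women, men = men, births = births, meta = meta),
            class = "femi_surveys")
}

#' @export
print.femi_surveys <- function(x, ...) {
  cat(sprintf(
    "femi survey bundle: %d surveys, %d women, %d men, %d birth records\n",
    nrow(x$meta), nrow(x$women), nrow(x$men), nrow(x$births)))
  invisible(x)
}

#' Read a survey bundle from a directory
#'
#' Reads `women.csv`, `men.csv`, `births.csv` and `survey_meta.csv` from a
#' directory. Rows violating a value domain are dropped with row-numbered
#' diagnostics; no violation is silent.
#'
#' @param microdata_path directory holding the CSV files.
#' @param meta_path path to the survey metadata CSV; defaults to
#'   `survey_meta.csv` inside `microdata_path`.
#' @return `femi_surveys` object; combined row diagnostics are in the
#'   `diagnostics` attribute.
#' @export
read_survey <- function(microdata_path,
                        meta_path = file.path(microdata_path,
                                              "survey_meta.csv")) {
  women <- read_femi_csv(file.path(microdata_path, "women.csv"), "women")
  men <- read_femi_csv(file.path(microdata_path, "men.csv"), "men")
  births <- read_femi_csv(file.path(microdata_path, "births.csv"), "births")
  meta <- read_femi_csv(meta_path, "survey_meta")
  diagnostics <- rbind(attr(women, "diagnostics"), attr(men, "diagnostics"),
                       attr(births, "diagnostics"), attr(meta, "diagnostics"))
  out <- femi_surveys(women, men, births, meta)
  attr(out, "diagnostics") <- diagnostics
  out
}

#' Write a survey bundle to a directory
#'
#' Inverse of [read_survey()]: writes the four microdata CSVs with stable
#' column order so that a write/read round trip preserves every field.
#'
#' @param surveys `femi_surveys` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_survey <- function(surveys, dir) {
  stopifnot(inherits(surveys, "femi_surveys"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_femi_csv(surveys$women, file.path(dir, "women.csv"), "women")
  write_femi_csv(surveys$men, file.path(dir, "men.csv"), "men")
  write_femi_csv(surveys$births, file.path(dir, "births.csv"), "births")
  write_femi_csv(surveys$meta, file.path(dir, "survey_meta.csv"),
                 "survey_meta")
  invisible(dir)
}

#' Validate a region crosswalk
#'
#' Checks the partition invariant: within one region scheme, every admin-1
#' unit belongs to exactly one survey region. Overlaps are errors, never
#' warnings.
#'
#' @param crosswalk data frame with columns `scheme_id`, `region_id`,
#'   `admin1_id`.
#' @return the crosswalk, invisibly, if valid.
#' @export
validate_crosswalk <- function(crosswalk) {
  need <- c("scheme_id", "region_id", "admin1_id")
  miss <- setdiff(need, names(crosswalk))
  if (length(miss)) stopf("crosswalk: missing column '%s'", miss[[1]])
  for (sid in unique(crosswalk$scheme_id)) {
    sub <- crosswalk[crosswalk$scheme_id == sid, ]
    dup <- sub$admin1_id[duplicated(sub$admin1_id)]
    if (length(dup))
      stopf("crosswalk scheme '%s': admin-1 unit(s) %s mapped to more than one survey region",
            sid, paste(unique(dup), collapse = ", "))
  }
  invisible(crosswalk)
}

#' Read a region crosswalk CSV
#'
#' @param path crosswalk CSV path.
#' @return validated crosswalk data frame.
#' @export
read_crosswalk <- function(path) {
  cw <- read_femi_csv(path, "crosswalk")
  validate_crosswalk(cw)
  cw
}
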