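# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Domains of the composite, in canonical order.
femi_domains <- function() {
  c("ipv", "family_planning", "reproductive_healthcare",
    "employment", "education", "decision_making")
}

# Men's auxiliary domains carried through imputation for the
# gender-inequality adjustment.
femi_men_domains <- function() c("education_men", "employment_men")

clamp01 <- function(x) pmax(pmin(x, 1), 0)  # keeps dim attributes of x

`%||%` <- function(a, b) if (is.null(a)) b else a

# Weighted mean over non-missing values; NA when nothing contributes.
wmean <- function(x, w = NULL) {
  if (is.null(w)) w <- rep(1, length(x))
  keep <- !is.na(x) & !is.na(w)
  if (!any(keep) || sum(w[keep]) <= 0) return(NA_real_)
  sum(x[keep] * w[keep]) / sum(w[keep])
}

# Derive a stage seed from the run seed; keeps the result a valid 32-bit int.
stage_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2147483600L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# randomForest warns when a regression response has few unique values;
# bounded [0,1] scores on small fixtures trigger it spuriously
fit_rf <- function(...) {
  withCallingHandlers(
    randomForest::randomForest(...),
    warning = function(w) {
      if (grepl("five or fewer unique values", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}
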