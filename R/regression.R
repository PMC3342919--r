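#' Ordinary least squares fit with collinearity checking
#'
#' Fits mortality-rate OLS via \code{stats::lm} with an intercept, after an
#' explicit rank check that names the aliased columns instead of silently
#' dropping them. Returns classical (non-robust) standard errors and
#' two-sided t-test p-values, plus residuals keyed by county for spatial
#' diagnostics.
#'
#' @param design A data.frame or matrix of regressors (no intercept column).
#' @param outcome Numeric outcome vector (age-adjusted rate per 100,000).
#' @param ids Optional observation ids (e.g. county ids) naming residuals.
#' @return An object of class \code{ols_fit}: coefficient table,
#'   \code{r.squared}, \code{n}, residuals, fitted values.
#' @export
fit_ols <- function(design, outcome, ids = NULL) {
  X <- as.matrix(design)
  if (!is.numeric(X)) stop("design must be numeric", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (length(outcome) != nrow(X))
    stop("outcome length does not match design rows", call. = FALSE)
  keep <- stats::complete.cases(X) & is.finite(outcome)
  X <- X[keep, , drop = FALSE]
  y <- outcome[keep]
  if (!is.null(ids)) ids <- ids[keep]
  M <- cbind(`(Intercept)` = 1, X)
  if (nrow(M) <= ncol(M))
    stop("fewer observations than model terms", call. = FALSE)
  q <- qr(M)
  if (q$rank < ncol(M)) {
    aliased <- colnames(M)[q$pivot[(q$rank + 1):ncol(M)]]
    stop("collinear design; dependent column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(y ~ X)
  sm <- summary(fit)
  ct <- sm$coefficients
  rownames(ct) <- colnames(M)
  colnames(ct) <- c("estimate", "se", "t", "p")
  res <- stats::residuals(fit)
  if (!is.null(ids)) names(res) <- ids
  out <- list(coefficients = ct, r.squared = sm$r.squared, n = length(y),
              residuals = res, fitted = stats::fitted(fit),
              sigma = sm$sigma, terms = colnames(M))
  class(out) <- "ols_fit"
  out
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf("OLS fit: n = %d, R-squared = %.4f\n", x$n, x$r.squared))
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
coef.ols_fit <- function(object, ...) object$coefficients[, "estimate"]

#' @export
residuals.ols_fit <- function(object, ...) object$residuals

#' @export
summary.ols_fit <- function(object, ...) object

covariate_names <- function() {
  c("pct_college", "smoking_rate", "obesity_rate", "physicians_per_1000",
    "poverty_rate", "pct_black", "pct_native", "pct_hispanic", "pct_asian",
    "pct_other")
}

# release-variable pairing per analysis set: carcinogen discharges model
# cancer mortality and non-carcinogen discharges model the non-cancer
# outcomes, except in the cross-validation set where the pairing is swapped
set_variants <- function(set_id) {
  pair <- function(carc, nonc)
    c(all_cancer = carc, kidney = nonc, total_non_cancer = nonc)
  switch(as.character(set_id),
    "1" = pair("log_carcinogen_raw_onsite", "log_non_carcinogen_raw_onsite"),
    "2" = pair("log_carcinogen_tox_onsite", "log_non_carcinogen_tox_onsite"),
    "3" = pair("log_carcinogen_tox_area", "log_non_carcinogen_tox_area"),
    "4" = pair("log_non_carcinogen_tox_area", "log_carcinogen_tox_area"),
    "5" = pair("log_carcinogen_tox_area", "log_non_carcinogen_tox_area"),
    stop("unknown set_id: ", set_id, call. = FALSE))
}

#' Run the five staged regression analysis sets
#'
#' Fits OLS models of each age-adjusted mortality outcome (all-cancer,
#' kidney, total non-cancer) on one discharge exposure variant plus the
#' fixed covariate list and metro indicators, across five sets: (1) onsite
#' unweighted, (2) onsite toxicity-weighted, (3) upstream area-weighted and
#' toxicity-weighted, (4) set 3 with the carcinogen/non-carcinogen pairing
#' swapped (cross-validation), (5) set 3 run separately within each
#' metro class (metro indicators dropped inside strata). Counties with
#' undefined exposure or a suppressed outcome are dropped listwise per
#' model.
#'
#' @param exposures A \code{county_exposure_table}.
#' @param health A \code{county_health} table.
#' @param sets Integer vector of set ids to run (default 1:5).
#' @return A list with \code{results} (long data.frame: set, outcome,
#'   stratum, release variant, release-term estimate/se/t/p, n, r.squared)
#'   and \code{fits} (nested list of \code{ols_fit} objects).
#' @export
run_analysis_sets <- function(exposures, health, sets = 1:5) {
  df <- merge(health, exposures, by = "county_id")
  covs <- covariate_names()
  outcomes <- c("all_cancer", "kidney", "total_non_cancer")
  rows <- list(); fits <- list()
  for (set_id in sets) {
    variants <- set_variants(set_id)
    strata <- if (set_id == 5)
      c("metro", "adjacent_nonmetro", "nonadjacent_nonmetro") else NA_character_
    for (stratum in strata) {
      sub <- if (is.na(stratum)) df else df[df$metro_class == stratum, ]
      if (!nrow(sub)) { warning("empty stratum: ", stratum); next }
      for (oc in outcomes) {
        release <- variants[[oc]]
        y <- sub[[paste0("rate_", oc)]]
        supp_col <- paste0("suppressed_", oc)
        if (supp_col %in% names(sub)) y[sub[[supp_col]]] <- NA_real_
        X <- sub[, covs, drop = FALSE]
        X$release <- sub[[release]]
        if (is.na(stratum)) {
          X$metro <- as.numeric(sub$metro_class == "metro")
          X$adjacent <- as.numeric(sub$metro_class == "adjacent_nonmetro")
        }
        fit <- fit_ols(X, y, ids = sub$county_id)
        key <- paste(set_id, if (is.na(stratum)) "all" else stratum, oc,
                     sep = ".")
        fits[[key]] <- fit
        ct <- fit$coefficients["release", ]
        rows[[key]] <- data.frame(
          set = set_id, outcome = oc,
          stratum = if (is.na(stratum)) "all" else stratum,
          release_variable = release,
          estimate = ct["estimate"], se = ct["se"], t = ct["t"], p = ct["p"],
          n = fit$n, r.squared = fit$r.squared)
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results, fits = fits)
}
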