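#' Age-adjusted rate by direct standardization
#'
#' \deqn{\mathrm{rate} = \sum_k w_k \, (d_k / p_k) \times 100{,}000}
#' where \eqn{w_k} are standard-population weights summing to one. A stratum
#' with zero population and zero deaths contributes nothing; deaths in an
#' empty stratum are a domain error.
#'
#' @param deaths Deaths per age stratum (expected counts allowed).
#' @param pop Population per age stratum.
#' @param standard_weights Standard population weights; must sum to 1.
#' @return The age-adjusted rate per 100,000.
#' @export
age_adjust <- function(deaths, pop, standard_weights) {
  if (length(deaths) != length(pop) ||
      length(deaths) != length(standard_weights))
    stop("strata do not align", call. = FALSE)
  if (abs(sum(standard_weights) - 1) > 1e-8)
    stop("standard weights must sum to 1", call. = FALSE)
  if (any(pop == 0 & deaths != 0))
    stop("deaths in a stratum with zero population", call. = FALSE)
  r <- ifelse(pop > 0, deaths / pop, 0)
  sum(standard_weights * r) * 1e5
}

#' Classify a USDA urban-influence code
#'
#' Maps codes 1-12 to the three analysis classes: metropolitan (codes 1-2),
#' non-metropolitan adjacent to a metro area (codes 3-7, 9, 10), and
#' non-metropolitan not adjacent (codes 8, 11, 12).
#'
#' @param uic_code Integer vector of codes in 1..12.
#' @return Character vector in \code{\{"metro", "adjacent_nonmetro",
#'   "nonadjacent_nonmetro"\}}.
#' @export
classify_uic <- function(uic_code) {
  if (any(!uic_code %in% 1:12))
    stop("urban-influence codes must be integers in 1..12", call. = FALSE)
  out <- rep("adjacent_nonmetro", length(uic_code))
  out[uic_code %in% c(1, 2)] <- "metro"
  out[uic_code %in% c(8, 11, 12)] <- "nonadjacent_nonmetro"
  out
}

#' Apply small-count suppression to a cause's rates
#'
#' Flags counties whose total deaths for the cause fall below
#' \code{min_count} and removes their rate, emulating the small-cell
#' suppression applied to public mortality files.
#'
#' @param health A \code{county_health} table (with a \code{strata}
#'   attribute holding stratified deaths).
#' @param cause One of \code{"all_cancer"}, \code{"kidney"},
#'   \code{"total_non_cancer"}.
#' @param min_count Suppress when total deaths < this threshold (default 10,
#'   the usual public-data convention).
#' @return The health table with \code{suppressed_<cause>} and the rate
#'   column updated.
#' @export
apply_suppression <- function(health, cause, min_count = 10) {
  stopifnot(min_count >= 0)
  strata <- attr(health, "strata")
  if (is.null(strata)) stop("health table has no strata attribute", call. = FALSE)
  tot <- stats::aggregate(deaths ~ county_id,
                          data = strata[strata$cause == cause, ], FUN = sum)
  low <- tot$county_id[tot$deaths < min_count]
  flag_col <- paste0("suppressed_", cause)
  rate_col <- paste0("rate_", cause)
  if (!flag_col %in% names(health)) health[[flag_col]] <- FALSE
  hit <- health$county_id %in% low
  health[[flag_col]] <- health[[flag_col]] | hit
  health[[rate_col]][health[[flag_col]]] <- NA_real_
  health
}
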