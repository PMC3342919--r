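#' Estimate population in every watershed-by-county intersection
#'
#' Assigns each population grid cell, by its center, to exactly one
#' watershed and one county (nearest Voronoi seed, smaller id on ties) and
#' sums cell populations within each intersection. Total population is
#' conserved: every cell lands in exactly one (watershed, county) pair.
#'
#' @param grid A \code{population_grid}.
#' @param network A \code{\link{watershed_network}} with seed geometry.
#' @param counties A \code{county_partition}.
#' @return A data.frame with columns \code{shed_id}, \code{county_id},
#'   \code{pop}.
#' @export
intersect_population <- function(grid, network, counties) {
  stopifnot(inherits(network, "watershed_network"))
  if (!all(c("seed_x", "seed_y") %in% names(network)))
    stop("network carries no geometry (seed_x/seed_y)", call. = FALSE)
  shed <- network$shed_id[nearest_seed(grid$x, grid$y,
                                       network$seed_x, network$seed_y)]
  cty <- counties$county_id[nearest_seed(grid$x, grid$y,
                                         counties$seed_x, counties$seed_y)]
  agg <- stats::aggregate(grid$pop,
                          by = list(shed_id = shed, county_id = cty),
                          FUN = sum)
  names(agg)[3] <- "pop"
  agg <- agg[order(agg$county_id, agg$shed_id), ]
  rownames(agg) <- NULL
  agg
}

#' Population-weighted county exposure
#'
#' Interpolates per-watershed scores to counties:
#' \deqn{e_c = \sum_{s \cap c} \mathrm{score}_s \, pop_{s,c} \Big/
#'       \sum_{s \cap c} pop_{s,c}}
#' a population-weighted average over the county's watershed intersections,
#' so a county is scored by the watersheds its residents actually live in.
#' Counties whose intersections hold zero total population have no defined
#' exposure and are returned with \code{NA} and flagged.
#'
#' @param scores Named numeric vector of per-watershed scores (names are
#'   shed ids) — the accumulated score for the upstream variant or the raw
#'   release sum for the onsite variant.
#' @param pops Intersection table from \code{\link{intersect_population}}.
#' @return A data.frame with \code{county_id}, \code{exposure} (linear
#'   scale), \code{log_exposure} (\code{log1p}), \code{zero_pop} flag.
#' @export
county_exposure <- function(scores, pops) {
  sc <- scores[as.character(pops$shed_id)]
  if (anyNA(sc))
    stop("missing score for shed(s): ",
         paste(unique(pops$shed_id[is.na(sc)]), collapse = ", "),
         call. = FALSE)
  ids <- sort(unique(pops$county_id))
  num <- vapply(ids, function(c_)
    sum(sc[pops$county_id == c_] * pops$pop[pops$county_id == c_]),
    numeric(1))
  den <- vapply(ids, function(c_)
    sum(pops$pop[pops$county_id == c_]), numeric(1))
  e <- ifelse(den > 0, num / den, NA_real_)
  data.frame(county_id = ids, exposure = e,
             log_exposure = ifelse(is.na(e), NA_real_, log1p(e)),
             zero_pop = den == 0)
}

#' Build the eight-variant county exposure table
#'
#' Runs the full exposure chain for every combination of chemical class
#' (carcinogen / non-carcinogen), toxicity weighting (weighted / raw) and
#' accumulation (onsite release sum \eqn{\rho_s} / upstream area-weighted
#' score \eqn{\pi_s}), yielding one linear and one log column per variant.
#' Variant columns are named \code{<class>_<tox|raw>_<onsite|area>}.
#'
#' @param shed_sums Per-(watershed, chemical) sums from
#'   \code{\link{assign_watersheds}}.
#' @param network A \code{\link{watershed_network}}.
#' @param pops Intersection table from \code{\link{intersect_population}}.
#' @param chemicals A \code{weight_table}.
#' @return A data.frame (class \code{county_exposure_table}): one row per
#'   county, 8 linear and 8 \code{log_} columns.
#' @export
build_exposure_table <- function(shed_sums, network, pops,
                                 chemicals = load_weight_table()) {
  out <- NULL
  for (wt in c(TRUE, FALSE)) {
    cls_sums <- apply_weights(shed_sums, chemicals, weighted = wt)
    for (cls in c("carcinogen", "non_carcinogen")) {
      rho <- stats::setNames(numeric(nrow(network)),
                             as.character(network$shed_id))
      if (nrow(cls_sums))
        rho[as.character(cls_sums$shed_id)] <- cls_sums[[cls]]
      acc <- accumulate(network, data.frame(shed_id = network$shed_id,
                                            release = as.numeric(rho)))
      pi_s <- stats::setNames(acc$pi, as.character(acc$shed_id))
      for (mode in c("onsite", "area")) {
        sc <- if (mode == "onsite") rho else pi_s
        ec <- county_exposure(sc, pops)
        nm <- paste(cls, if (wt) "tox" else "raw", mode, sep = "_")
        if (is.null(out))
          out <- data.frame(county_id = ec$county_id, zero_pop = ec$zero_pop)
        out[[nm]] <- ec$exposure
        out[[paste0("log_", nm)]] <- ec$log_exposure
      }
    }
  }
  class(out) <- c("county_exposure_table", "data.frame")
  out
}
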