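#' Simulation configuration
#'
#' Bundles every knob of the synthetic study generator. The defaults describe
#' a mid-sized planar study region: a 150 x 150 km extent tiled by 1 km
#' population cells, 60 watersheds forming a drainage forest, 150 counties
#' whose boundaries cut across watershed boundaries, and 500 discharging
#' facilities reporting releases of the 38 packaged chemicals. Mortality is
#' generated from a linear model with known coefficients so that downstream
#' regression stages have a recoverable ground truth.
#'
#' @param n_watersheds Number of watersheds (>= 1).
#' @param branching_factor Target mean number of upstream children per
#'   watershed; caps how bushy the drainage tree may grow.
#' @param extent Study region \code{c(xmin, xmax, ymin, ymax)} in planar km.
#' @param n_counties Number of counties (>= 1, at most the number of grid
#'   cells).
#' @param n_facilities Number of discharging facilities.
#' @param grid_cell_km Population grid cell edge in km (default 1, mirroring
#'   a ~1 km gridded population surface).
#' @param zero_release_fraction Fraction of records injected with a zero
#'   release value (an invalid class the cleaning stage must remove).
#' @param invalid_coord_fraction Fraction of facilities injected with
#'   zero/anomalous coordinates.
#' @param outside_region_fraction Fraction of facilities placed outside the
#'   study region.
#' @param identical_value_fraction Fraction of multi-record facilities whose
#'   releases are all set to one identical value (the copy-paste error class).
#' @param beta_exposure True mortality effect per unit log-exposure.
#' @param beta_covariates Named numeric vector of true covariate effects on
#'   the age-adjusted rate (per 100,000).
#' @param beta_metro Length-2 named vector: true effects of the metro and
#'   adjacent non-metro indicators.
#' @param noise_sd Residual SD of the all-cancer age-adjusted rate; other
#'   causes scale this by their relative dispersion.
#' @param spatial_beta Optional function \code{f(x, y)} returning a local
#'   exposure effect, replacing the constant \code{beta_exposure}.
#' @param kidney_suppression_fraction Share of counties flagged as suppressed
#'   for the kidney outcome (default 0.22, so that roughly 78% of counties
#'   remain analyzable, as in national county mortality files).
#' @param seed Integer random seed; identical configurations give
#'   bit-identical outputs.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_watersheds = 60L,
                              branching_factor = 2,
                              extent = c(0, 150, 0, 150),
                              n_counties = 150L,
                              n_facilities = 500L,
                              grid_cell_km = 1,
                              zero_release_fraction = 0.05,
                              invalid_coord_fraction = 0.02,
                              outside_region_fraction = 0.02,
                              identical_value_fraction = 0.02,
                              beta_exposure = 2,
                              beta_covariates = c(
                                pct_college = -0.78, smoking_rate = 1.24,
                                obesity_rate = 0.43, physicians_per_1000 = 1.83,
                                poverty_rate = 1.11, pct_black = 0.20,
                                pct_native = -0.22, pct_hispanic = -0.91,
                                pct_asian = 0.65, pct_other = 0.76),
                              beta_metro = c(metro = 10, adjacent = 2),
                              noise_sd = 20,
                              spatial_beta = NULL,
                              kidney_suppression_fraction = 0.22,
                              seed = 1L) {
  fr <- c(zero_release_fraction, invalid_coord_fraction,
          outside_region_fraction, identical_value_fraction,
          kidney_suppression_fraction)
  if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1))
    stop("all fractions must lie in [0, 1]", call. = FALSE)
  if (n_watersheds < 1 || n_counties < 1 || n_facilities < 1)
    stop("counts must be positive", call. = FALSE)
  if (grid_cell_km <= 0) stop("grid_cell_km must be > 0", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (length(extent) != 4 || extent[2] <= extent[1] || extent[4] <= extent[3])
    stop("extent must be c(xmin, xmax, ymin, ymax) with positive spans",
         call. = FALSE)
  if (!is.null(spatial_beta) && !is.function(spatial_beta))
    stop("spatial_beta must be NULL or a function(x, y)", call. = FALSE)
  cfg <- list(n_watersheds = as.integer(n_watersheds),
              branching_factor = branching_factor, extent = extent,
              n_counties = as.integer(n_counties),
              n_facilities = as.integer(n_facilities),
              grid_cell_km = grid_cell_km,
              zero_release_fraction = zero_release_fraction,
              invalid_coord_fraction = invalid_coord_fraction,
              outside_region_fraction = outside_region_fraction,
              identical_value_fraction = identical_value_fraction,
              beta_exposure = beta_exposure,
              beta_covariates = beta_covariates, beta_metro = beta_metro,
              noise_sd = noise_sd, spatial_beta = spatial_beta,
              kidney_suppression_fraction = kidney_suppression_fraction,
              seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  cfg
}

# cell-center lattice for the configured extent
grid_centers <- function(config) {
  h <- config$grid_cell_km
  xs <- seq(config$extent[1] + h / 2, config$extent[2], by = h)
  ys <- seq(config$extent[3] + h / 2, config$extent[4], by = h)
  expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
}

#' Generate a synthetic watershed network
#'
#' Watersheds are Voronoi regions of seed points placed at distinct
#' population-grid cell centers, so every watershed has strictly positive
#' area. Drainage links form a random recursive forest with spatial locality:
#' each new watershed drains into a nearby earlier one (probability
#' proportional to inverse squared seed distance), with the number of
#' upstream children capped by the branching factor. Areas are the Voronoi
#' cell areas measured on the grid lattice and converted to acres.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A \code{\link{watershed_network}} with extra columns
#'   \code{seed_x}, \code{seed_y} carrying the implicit Voronoi geometry.
#' @export
generate_watershed_network <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_watersheds
  cells <- grid_centers(config)
  if (n > nrow(cells))
    stop("n_watersheds exceeds the number of grid cells", call. = FALSE)
  with_seed(config$seed + 101L, {
    pick <- sample.int(nrow(cells), n)
    sx <- cells$x[pick]; sy <- cells$y[pick]
    down <- rep(NA_integer_, n)
    children <- integer(n)
    cap <- max(1L, ceiling(2 * config$branching_factor))
    if (n > 1) {
      for (i in 2:n) {
        if (stats::runif(1) < 0.05) next # occasional extra outlet -> a forest
        elig <- which(children[seq_len(i - 1L)] < cap)
        if (!length(elig)) elig <- seq_len(i - 1L)
        d2 <- (sx[elig] - sx[i])^2 + (sy[elig] - sy[i])^2
        j <- if (length(elig) == 1L) elig else
          sample(elig, 1L, prob = 1 / pmax(d2, 1e-9))
        down[i] <- j
        children[j] <- children[j] + 1L
      }
    }
    member <- nearest_seed(cells$x, cells$y, sx, sy)
    cell_area_acres <- config$grid_cell_km^2 * KM2_TO_ACRES
    counts <- tabulate(member, nbins = n)
    # each seed sits on a cell center, so counts are >= 1 by construction
    net <- data.frame(shed_id = seq_len(n),
                      area_acres = counts * cell_area_acres,
                      downstream_id = down,
                      seed_x = sx, seed_y = sy)
    watershed_network(net)
  })
}

#' Generate a clustered synthetic population grid
#'
#' Cell populations are Poisson draws from a log-normal intensity surface
#' built from a handful of Gaussian "city" bumps, so population clusters and
#' the watershed-by-county intersections receive unequal weight.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A data.frame (class \code{population_grid}) with columns
#'   \code{cell_id}, \code{x}, \code{y}, \code{pop}; the grand total is in
#'   \code{attr(, "total_pop")}.
#' @export
generate_population_grid <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- grid_centers(config)
  with_seed(config$seed + 102L, {
    n_bump <- max(3L, config$n_counties %/% 8L)
    bx <- stats::runif(n_bump, config$extent[1], config$extent[2])
    by <- stats::runif(n_bump, config$extent[3], config$extent[4])
    amp <- stats::rnorm(n_bump, 3, 1)
    sc <- stats::runif(n_bump, 0.05, 0.15) * (config$extent[2] - config$extent[1])
    log_int <- rep(2, nrow(cells))
    for (b in seq_len(n_bump)) {
      d2 <- (cells$x - bx[b])^2 + (cells$y - by[b])^2
      log_int <- log_int + amp[b] * exp(-d2 / (2 * sc[b]^2))
    }
    log_int <- log_int + stats::rnorm(nrow(cells), 0, 0.5)
    pop <- stats::rpois(nrow(cells), exp(log_int))
    out <- data.frame(cell_id = seq_len(nrow(cells)),
                      x = cells$x, y = cells$y, pop = pop)
    attr(out, "total_pop") <- sum(pop)
    attr(out, "cell_km") <- config$grid_cell_km
    class(out) <- c("population_grid", "data.frame")
    out
  })
}

#' Generate a synthetic county partition
#'
#' Counties are Voronoi regions of seed points placed at distinct grid cell
#' centers, independent of the watershed seeds, so county boundaries cut
#' across watershed boundaries. Each county receives a USDA urban-influence
#' code in 1..12, drawn so that the metro / adjacent / non-adjacent class
#' shares are roughly 35% / 47% / 18%.
#'
#' @param config A \code{\link{simulation_config}}.
#' @return A data.frame (class \code{county_partition}) with columns
#'   \code{county_id}, \code{seed_x}, \code{seed_y}, \code{uic_code}.
#' @export
generate_counties <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cells <- grid_centers(config)
  if (config$n_counties > nrow(cells))
    stop("n_counties exceeds the number of grid cells", call. = FALSE)
  with_seed(config$seed + 103L, {
    pick <- sample.int(nrow(cells), config$n_counties)
    cls <- sample(c("metro", "adjacent", "nonadjacent"), config$n_counties,
                  replace = TRUE, prob = c(0.352, 0.467, 0.181))
    code_pool <- list(metro = c(1L, 2L),
                      adjacent = c(3L, 4L, 5L, 6L, 7L, 9L, 10L),
                      nonadjacent = c(8L, 11L, 12L))
    uic <- vapply(cls, function(cl) {
      p <- code_pool[[cl]]
      p[sample.int(length(p), 1L)]
    }, integer(1))
    out <- data.frame(county_id = seq_len(config$n_counties),
                      seed_x = cells$x[pick], seed_y = cells$y[pick],
                      uic_code = uic)
    attr(out, "extent") <- config$extent
    class(out) <- c("county_partition", "data.frame")
    out
  })
}

#' Generate synthetic permitted discharge records
#'
#' Creates facilities inside the study region, each reporting log-normal
#' kg/yr releases for a random subset of the packaged chemicals, and injects
#' the invalid record classes that the cleaning stage must remove: zero
#' releases, facilities placed outside the region, zero ("anomalous")
#' coordinates, and facilities whose releases are all one identical value.
#' Every injected record carries exactly one hidden truth label in the
#' \code{truth_invalid} column (\code{NA} for valid records) so filter output
#' can be audited exactly.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param network A \code{\link{watershed_network}} (unused for placement but
#'   kept so callers can guarantee a shared frame).
#' @param chemicals A \code{weight_table}; defaults to the packaged table.
#' @return A data.frame (class \code{discharge_records}) with columns
#'   \code{facility_id}, \code{cas_number}, \code{chemical_name}, \code{lon},
#'   \code{lat}, \code{release_kg_yr}, \code{truth_invalid}.
#' @export
generate_discharges <- function(config, network = NULL,
                                chemicals = load_weight_table()) {
  stopifnot(inherits(config, "simulation_config"))
  if (!nrow(chemicals)) stop("chemical table is empty", call. = FALSE)
  ex <- config$extent
  with_seed(config$seed + 104L, {
    nf <- config$n_facilities
    fx <- stats::runif(nf, ex[1], ex[2])
    fy <- stats::runif(nf, ex[3], ex[4])
    n_chem <- 1L + stats::rpois(nf, 1)
    n_chem <- pmin(n_chem, nrow(chemicals))
    rec <- do.call(rbind, lapply(seq_len(nf), function(i) {
      ch <- chemicals[sample.int(nrow(chemicals), n_chem[i]), ]
      data.frame(facility_id = sprintf("F%05d", i),
                 cas_number = ch$cas_number,
                 chemical_name = ch$chemical_name,
                 lon = fx[i], lat = fy[i],
                 release_kg_yr = stats::rlnorm(n_chem[i], meanlog = 4, sdlog = 2))
    }))
    rec$truth_invalid <- NA_character_
    fac_ids <- sprintf("F%05d", seq_len(nf))
    multi <- fac_ids[n_chem >= 2L]

    # facility-level injections on disjoint facility sets
    n_ident <- round(config$identical_value_fraction * length(multi))
    ident_fac <- if (n_ident) sample(multi, n_ident) else character(0)
    rest <- setdiff(fac_ids, ident_fac)
    n_out <- round(config$outside_region_fraction * nf)
    out_fac <- if (n_out) sample(rest, min(n_out, length(rest))) else character(0)
    rest <- setdiff(rest, out_fac)
    n_bad <- round(config$invalid_coord_fraction * nf)
    bad_fac <- if (n_bad) sample(rest, min(n_bad, length(rest))) else character(0)
    rest <- setdiff(rest, bad_fac)

    for (f in ident_fac) {
      rows <- which(rec$facility_id == f)
      rec$release_kg_yr[rows] <- rec$release_kg_yr[rows[1]]
      rec$truth_invalid[rows] <- "identical_values_facility"
    }
    for (f in out_fac) {
      rows <- which(rec$facility_id == f)
      rec$lon[rows] <- ex[2] + stats::runif(1, 5, 25)
      rec$lat[rows] <- ex[4] + stats::runif(1, 5, 25)
      rec$truth_invalid[rows] <- "outside_region"
    }
    for (f in bad_fac) {
      rows <- which(rec$facility_id == f)
      rec$lon[rows] <- 0; rec$lat[rows] <- 0
      rec$truth_invalid[rows] <- "anomalous_coordinates"
    }
    # record-level zero-release injection among untouched facilities
    cand <- which(rec$facility_id %in% rest)
    n_zero <- round(config$zero_release_fraction * nrow(rec))
    if (n_zero) {
      z <- sample(cand, min(n_zero, length(cand)))
      rec$release_kg_yr[z] <- 0
      rec$truth_invalid[z] <- "zero_release"
    }
    rownames(rec) <- NULL
    class(rec) <- c("discharge_records", "data.frame")
    rec
  })
}

# age pattern: stratum rate multipliers scaled so the standard-weighted sum
# is exactly 1, making direct standardization return the target rate exactly
age_rate_multipliers <- function(weights) {
  m <- c(0.08, 0.25, 1.0, NA)
  m[4] <- (1 - sum(weights[1:3] * m[1:3])) / weights[4]
  m
}

#' Generate synthetic county mortality and covariates
#'
#' Draws county covariates from a multivariate normal with the packaged
#' correlation matrix and marginal means/SDs typical of US county data, then
#' generates age-stratified deaths and populations such that the directly
#' standardized (age-adjusted) rate for each cause equals
#' \deqn{b_0 + \beta \cdot \log(1+e_c) + X\gamma + \epsilon}
#' with known coefficients. Deaths are expected counts (possibly fractional)
#' so that standardization is exact and noiseless runs are exactly
#' recoverable by OLS. Kidney rates are suppressed for the configured share
#' of smallest-population counties.
#'
#' @param exposures A county exposure table from
#'   \code{\link{build_exposure_table}} (columns \code{log_*} per variant).
#' @param counties A \code{county_partition}.
#' @param config A \code{\link{simulation_config}}.
#' @return A data.frame (class \code{county_health}) with rates per cause,
#'   covariates, UIC codes and suppression flags; stratified deaths and
#'   populations are in \code{attr(, "strata")}, the true coefficients in
#'   \code{attr(, "truth")}.
#' @export
generate_mortality <- function(exposures, counties, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  ids <- counties$county_id
  if (!all(ids %in% exposures$county_id))
    stop("exposure table must cover every county", call. = FALSE)
  ex <- exposures[match(ids, exposures$county_id), ]
  n <- length(ids)
  corr <- load_covariate_correlation()
  mu <- c(pct_college = 16.5, smoking_rate = 21.8, obesity_rate = 28.9,
          physicians_per_1000 = 0.4, poverty_rate = 15.1, pct_black = 8.9,
          pct_native = 1.6, pct_hispanic = 6.2, pct_asian = 0.8,
          pct_other = 2.6)
  sd_ <- c(7.8, 4.3, 3.7, 0.3, 6.2, 14.6, 6.4, 12.0, 1.6, 4.8)
  with_seed(config$seed + 105L, {
    Z <- MASS::mvrnorm(n, mu = rep(0, 10), Sigma = corr)
    X <- sweep(Z, 2, sd_, `*`)
    X <- sweep(X, 2, mu, `+`)
    colnames(X) <- names(mu)
    pct <- setdiff(names(mu), "physicians_per_1000")
    X[, pct] <- pmin(pmax(X[, pct], 0), 100)
    X[, "physicians_per_1000"] <- pmax(X[, "physicians_per_1000"], 0)

    metro_class <- classify_uic(counties$uic_code)
    metro <- as.numeric(metro_class == "metro")
    adjacent <- as.numeric(metro_class == "adjacent_nonmetro")

    beta_x <- config$beta_covariates[names(mu)]
    if (anyNA(beta_x))
      stop("beta_covariates must name all ten covariates", call. = FALSE)
    bexp <- if (is.null(config$spatial_beta)) rep(config$beta_exposure, n) else
      config$spatial_beta(counties$seed_x, counties$seed_y)

    base <- c(all_cancer = 197.6, kidney = 17.6, total_non_cancer = 658.3)
    noise_scale <- c(all_cancer = 1, kidney = 0.25, total_non_cancer = 3.8)
    drive <- c(all_cancer = "log_carcinogen_tox_area",
               kidney = "log_non_carcinogen_tox_area",
               total_non_cancer = "log_non_carcinogen_tox_area")

    lin <- drop(X %*% beta_x) + config$beta_metro["metro"] * metro +
      config$beta_metro["adjacent"] * adjacent
    rates <- sapply(names(base), function(cause) {
      base[cause] + bexp * ex[[drive[cause]]] + lin +
        stats::rnorm(n, 0, config$noise_sd * noise_scale[cause])
    })
    colnames(rates) <- names(base)

    w <- load_standard_weights()
    m <- age_rate_multipliers(w$weight)
    total_pop <- round(stats::rlnorm(n, meanlog = 10, sdlog = 1.2)) + 100L
    pop_mat <- vapply(w$weight, function(wk) pmax(1, round(total_pop * wk)),
                      numeric(n))
    strata <- do.call(rbind, lapply(names(base), function(cause) {
      do.call(rbind, lapply(seq_len(nrow(w)), function(k)
        data.frame(county_id = ids, cause = cause, stratum = w$stratum[k],
                   pop = pop_mat[, k],
                   deaths = rates[, cause] * m[k] / 1e5 * pop_mat[, k])))
    }))
    # direct standardization, vectorized: stratum rate_k = rate * m_k by
    # construction, so sum_k w_k rate_k recovers the target rate exactly
    adj <- vapply(names(base), function(cause) {
      d_mat <- outer(rates[, cause], m) / 1e5 * pop_mat
      drop((d_mat / pop_mat) %*% w$weight) * 1e5
    }, numeric(n))

    health <- data.frame(county_id = ids, uic_code = counties$uic_code,
                         metro_class = metro_class, total_pop = total_pop,
                         X,
                         rate_all_cancer = adj[, "all_cancer"],
                         rate_kidney = adj[, "kidney"],
                         rate_total_non_cancer = adj[, "total_non_cancer"],
                         suppressed_kidney = FALSE)
    if (config$kidney_suppression_fraction > 0) {
      k_small <- floor(config$kidney_suppression_fraction * n)
      if (k_small > 0) {
        small <- order(total_pop)[seq_len(k_small)]
        health$suppressed_kidney[small] <- TRUE
        health$rate_kidney[small] <- NA_real_
      }
    }
    attr(health, "strata") <- strata
    attr(health, "truth") <- list(beta_exposure = bexp, beta_covariates = beta_x,
                                  beta_metro = config$beta_metro, base = base,
                                  drive = drive, noise_scale = noise_scale)
    class(health) <- c("county_health", "data.frame")
    health
  })
}

#' Run the full synthetic study pipeline
#'
#' Generates every input (network, population grid, counties, discharges),
#' cleans and assigns the discharge records, builds the eight county exposure
#' variants, and generates mortality from them — one call that yields a
#' complete, internally consistent synthetic study.
#'
#' @param config A \code{\link{simulation_config}}.
#' @param chemicals A \code{weight_table}.
#' @return A list with components \code{config}, \code{network}, \code{grid},
#'   \code{counties}, \code{discharges}, \code{clean}, \code{rejections},
#'   \code{shed_sums}, \code{pops}, \code{exposures}, \code{health}.
#' @export
simulate_study <- function(config = simulation_config(),
                           chemicals = load_weight_table()) {
  network <- generate_watershed_network(config)
  grid <- generate_population_grid(config)
  counties <- generate_counties(config)
  discharges <- generate_discharges(config, network, chemicals)
  filt <- filter_records(discharges, chemicals, region = config$extent)
  shed_sums <- assign_watersheds(filt$clean, network)
  pops <- intersect_population(grid, network, counties)
  exposures <- build_exposure_table(shed_sums, network, pops, chemicals)
  health <- generate_mortality(exposures, counties, config)
  list(config = config, network = network, grid = grid, counties = counties,
       discharges = discharges, clean = filt$clean,
       rejections = filt$rejections, shed_sums = shed_sums, pops = pops,
       exposures = exposures, health = health)
}

load_standard_weights <- function() {
  path <- system.file("extdata", "standard_population_weights.csv",
                      package = "toxsheds", mustWork = TRUE)
  w <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(abs(sum(w$weight) - 1) < 1e-8)
  w
}

load_covariate_correlation <- function() {
  path <- system.file("extdata", "covariate_correlation.csv",
                      package = "toxsheds", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$variable
  m
}
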