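dist_matrix <- function(coords) {
  as.matrix(stats::dist(coords))
}

#' k-nearest-neighbor spatial weights
#'
#' For each location, its k nearest other locations by centroid distance
#' (Euclidean in the planar frame). Ties break deterministically toward the
#' smaller index. k-NN neighborhoods are directed: i being a neighbor of j
#' does not imply the converse, and nothing downstream assumes symmetry.
#'
#' @param coords Two-column matrix/data.frame of centroid coordinates.
#' @param k Neighbor count (default 30); must satisfy \code{k < n}.
#' @return An object of class \code{spatial_weights} (scheme \code{"knn"}):
#'   a row-standardized n x n weight matrix plus the neighbor index matrix.
#' @export
knn_weights <- function(coords, k = 30) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of locations",
                   call. = FALSE)
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  D <- dist_matrix(coords)
  nb <- matrix(0L, n, k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))     # secondary key: index (determinism)
    ord <- ord[ord != i][seq_len(k)]
    nb[i, ] <- ord
    W[i, ord] <- 1 / k
  }
  structure(list(W = W, neighbors = nb, scheme = "knn", k = k, n = n),
            class = "spatial_weights")
}

#' Inverse-distance spatial weights
#'
#' Weight \eqn{1/d_{ij}} between every pair of distinct locations, with no
#' distance cutoff, row-standardized. This is the weighting used for the
#' residual autocorrelation diagnostic.
#'
#' @param coords Two-column matrix/data.frame of centroid coordinates.
#' @return A \code{spatial_weights} object (scheme
#'   \code{"inverse_distance"}).
#' @export
inverse_distance_weights <- function(coords) {
  coords <- as.matrix(coords)
  D <- dist_matrix(coords)
  if (any(D[upper.tri(D)] == 0))
    stop("duplicate coordinates give infinite inverse-distance weights",
         call. = FALSE)
  W <- 1 / D
  diag(W) <- 0
  W <- W / rowSums(W)
  structure(list(W = W, scheme = "inverse_distance", n = nrow(W)),
            class = "spatial_weights")
}

#' Moran's I with permutation and normal-approximation inference
#'
#' Global spatial autocorrelation of a variable (typically OLS residuals)
#' under a given spatial weight matrix:
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with \eqn{z} the centered variable. The null expectation is
#' \eqn{-1/(n-1)}. P-values are reported both by random permutation of the
#' values across locations (default 999 permutations) and by the normal
#' approximation under the normality assumption.
#'
#' @param x Numeric vector (e.g. residuals keyed by county).
#' @param weights A \code{spatial_weights} object, or \code{NULL} to build
#'   inverse-distance weights from \code{coords}.
#' @param coords Centroid coordinates, used when \code{weights} is NULL.
#' @param nperm Number of permutations (default 999).
#' @param alternative \code{"greater"} (clustering, default),
#'   \code{"less"}, or \code{"two.sided"}.
#' @param seed Optional seed for the permutation draw.
#' @return A list of class \code{morans_test}: \code{I}, \code{expected},
#'   \code{sd_norm}, \code{p_norm}, \code{p_perm}, \code{perm} (the
#'   permutation distribution).
#' @export
morans_i <- function(x, weights = NULL, coords = NULL, nperm = 999,
                     alternative = c("greater", "less", "two.sided"),
                     seed = NULL) {
  alternative <- match.arg(alternative)
  if (is.null(weights)) {
    if (is.null(coords)) stop("need weights or coords", call. = FALSE)
    weights <- inverse_distance_weights(coords)
  }
  W <- weights$W
  n <- length(x)
  if (n < 3) stop("need at least 3 locations", call. = FALSE)
  if (nrow(W) != n) stop("weights do not match x", call. = FALSE)
  z <- x - mean(x)
  if (sum(z^2) == 0) stop("constant input has no spatial structure",
                          call. = FALSE)
  S0 <- sum(W)
  stat <- function(z) (n / S0) * sum(W * tcrossprod(z)) / sum(z^2)
  I <- stat(z)
  EI <- -1 / (n - 1)
  # normal approximation variance (normality assumption)
  S1 <- 0.5 * sum((W + t(W))^2)
  S2 <- sum((rowSums(W) + colSums(W))^2)
  VI <- (n^2 * S1 - n * S2 + 3 * S0^2) / (S0^2 * (n^2 - 1)) - EI^2
  zscore <- (I - EI) / sqrt(VI)
  p_norm <- switch(alternative,
                   greater = stats::pnorm(zscore, lower.tail = FALSE),
                   less = stats::pnorm(zscore),
                   two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE))
  do_perm <- function() {
    perm <- vapply(seq_len(nperm), function(i) stat(z[sample.int(n)]),
                   numeric(1))
    cnt <- switch(alternative,
                  greater = sum(perm >= I),
                  less = sum(perm <= I),
                  two.sided = sum(abs(perm - EI) >= abs(I - EI)))
    list(perm = perm, p = (cnt + 1) / (nperm + 1))
  }
  pr <- if (is.null(seed)) do_perm() else with_seed(seed, do_perm())
  structure(list(I = I, expected = EI, sd_norm = sqrt(VI), z = zscore,
                 p_norm = p_norm, p_perm = pr$p, perm = pr$perm,
                 nperm = nperm, alternative = alternative,
                 scheme = weights$scheme),
            class = "morans_test")
}

#' @export
print.morans_test <- function(x, ...) {
  cat(sprintf(
    "Moran's I = %.4f (expected %.4f under the null), %s weights\n",
    x$I, x$expected, x$scheme))
  cat(sprintf("permutation p = %.4g (%d perms), normal-approx p = %.4g\n",
              x$p_perm, x$nperm, x$p_norm))
  invisible(x)
}

#' Geographically weighted regression over k nearest neighbors
#'
#' Cycles through every location and fits a weighted least-squares
#' regression using that location and its k nearest neighbors, giving local
#' coefficients, local pseudo-t values (coefficient over local classical
#' SE), and a local weighted R-squared. The adaptive bisquare kernel
#' \eqn{(1 - (d/b)^2)^2} with bandwidth \eqn{b} the distance to the k-th
#' nearest neighbor is the default; the uniform kernel gives every
#' neighbor weight 1, so with \code{k = n} (all locations) it reproduces
#' the global OLS fit exactly.
#'
#' @param design Data.frame/matrix of regressors (no intercept column).
#' @param outcome Numeric outcome vector.
#' @param coords Two-column matrix of location coordinates.
#' @param k Neighbor count (default 30); \code{k = n} means all locations.
#' @param kernel \code{"bisquare"} (default) or \code{"uniform"}.
#' @param ids Optional location ids.
#' @return An object of class \code{gwr_fit}: matrices \code{coefficients},
#'   \code{se}, \code{t} (locations x terms) and vector \code{local_r2}.
#' @export
fit_gwr <- function(design, outcome, coords, k = 30,
                    kernel = c("bisquare", "uniform"), ids = NULL) {
  kernel <- match.arg(kernel)
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  coords <- as.matrix(coords)
  n <- nrow(X)
  if (length(outcome) != n || nrow(coords) != n)
    stop("design, outcome and coords must align", call. = FALSE)
  if (k < 1 || k > n) stop("k must be in [1, n]", call. = FALSE)
  if (is.null(ids)) ids <- seq_len(n)
  M <- cbind(`(Intercept)` = 1, X)
  p <- ncol(M)
  D <- dist_matrix(coords)
  B <- matrix(NA_real_, n, p, dimnames = list(ids, colnames(M)))
  SE <- B; Tv <- B
  r2 <- numeric(n)
  bad <- character(0)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i]
    nn <- ord[seq_len(min(k, n - 1L))]
    use <- c(i, nn)
    d <- D[i, use]
    if (kernel == "uniform") {
      w <- rep(1, length(use))
    } else {
      b <- max(d)
      w <- (1 - (d / b)^2)^2
      w[1] <- 1                       # the focal location itself
      w[w < .Machine$double.eps] <- .Machine$double.eps
    }
    Mi <- M[use, , drop = FALSE]
    yi <- outcome[use]
    q <- qr(Mi * sqrt(w))
    if (q$rank < p) { bad <- c(bad, as.character(ids[i])); next }
    f <- stats::lm.wfit(Mi, yi, w)
    e <- f$residuals
    dfree <- length(use) - p
    s2 <- sum(w * e^2) / dfree
    XtWX_inv <- chol2inv(chol(crossprod(Mi, Mi * w)))
    se <- sqrt(s2 * diag(XtWX_inv))
    B[i, ] <- f$coefficients
    SE[i, ] <- se
    Tv[i, ] <- f$coefficients / se
    ybar <- sum(w * yi) / sum(w)
    r2[i] <- 1 - sum(w * e^2) / sum(w * (yi - ybar)^2)
  }
  if (length(bad))
    stop("local design rank-deficient at location(s): ",
         paste(utils::head(bad, 10), collapse = ", "),
         if (length(bad) > 10) " ..." else "",
         "; consider raising k", call. = FALSE)
  structure(list(coefficients = B, se = SE, t = Tv, local_r2 = r2,
                 terms = colnames(M), k = k, kernel = kernel, ids = ids,
                 n = n),
            class = "gwr_fit")
}

#' @export
print.gwr_fit <- function(x, ...) {
  cat(sprintf("GWR fit: n = %d, k = %d, %s kernel\n", x$n, x$k, x$kernel))
  cat(sprintf("local R-squared: min %.3f / median %.3f / max %.3f\n",
              min(x$local_r2), stats::median(x$local_r2), max(x$local_r2)))
  invisible(x)
}

#' @export
coef.gwr_fit <- function(object, ...) object$coefficients

#' Release-variant metadata for the lettered GWR analyses
#'
#' The enumeration of discharge variants A-G fitted against cancer
#' mortality (plus the eighth, H, which is attempted but prone to local
#' collinearity), with each variant's chemical class, toxicity weighting
#' and accumulation mode.
#'
#' @return A data.frame with columns \code{variant}, \code{column},
#'   \code{class}, \code{tox_weighted}, \code{accumulation}.
#' @export
gwr_variant_table <- function() {
  data.frame(
    variant = c("A", "B", "C", "D", "E", "F", "G", "H"),
    column = c("log_carcinogen_tox_area", "log_carcinogen_raw_area",
               "log_non_carcinogen_tox_area", "log_carcinogen_tox_onsite",
               "log_carcinogen_raw_onsite", "log_non_carcinogen_tox_onsite",
               "log_non_carcinogen_raw_onsite", "log_non_carcinogen_raw_area"),
    class = c("carcinogen", "carcinogen", "non_carcinogen", "carcinogen",
              "carcinogen", "non_carcinogen", "non_carcinogen",
              "non_carcinogen"),
    tox_weighted = c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE),
    accumulation = c("area", "area", "area", "onsite", "onsite", "onsite",
                     "onsite", "area"),
    stringsAsFactors = FALSE)
}

#' Run the lettered GWR release-variant analyses
#'
#' Fits one GWR per release variant (A-G) of the cancer-mortality model —
#' every combination of carcinogen/non-carcinogen class, toxicity weighting
#' and onsite/area accumulation that the design enumerates — plus a
#' covariate-only baseline with identical weights. The eighth combination
#' (area-weighted, non-carcinogen, unweighted) is attempted and reported
#' with a failure reason if local collinearity defeats it, rather than
#' silently omitted.
#'
#' @param exposures A \code{county_exposure_table}.
#' @param health A \code{county_health} table.
#' @param counties A \code{county_partition} (for centroid coordinates).
#' @param outcome Outcome name (default \code{"all_cancer"}).
#' @param k Neighbor count (default 30).
#' @param kernel Kernel passed to \code{\link{fit_gwr}}.
#' @return A list: \code{fits} (named list of \code{gwr_fit}), \code{baseline},
#'   \code{failed} (named character vector of failure reasons),
#'   \code{variants} (the variant metadata table).
#' @export
run_gwr_variants <- function(exposures, health, counties,
                             outcome = "all_cancer", k = 30,
                             kernel = "bisquare") {
  df <- merge(merge(health, exposures, by = "county_id"),
              counties[, c("county_id", "seed_x", "seed_y")], by = "county_id")
  y <- df[[paste0("rate_", outcome)]]
  supp <- paste0("suppressed_", outcome)
  if (supp %in% names(df)) y[df[[supp]]] <- NA_real_
  keep <- is.finite(y)
  df <- df[keep, ]; y <- y[keep]
  coords <- as.matrix(df[, c("seed_x", "seed_y")])
  covs <- covariate_names()
  base_X <- df[, covs, drop = FALSE]
  base_X$metro <- as.numeric(df$metro_class == "metro")
  base_X$adjacent <- as.numeric(df$metro_class == "adjacent_nonmetro")
  baseline <- fit_gwr(base_X, y, coords, k = k, kernel = kernel,
                      ids = df$county_id)
  vt <- gwr_variant_table()
  fits <- list(); failed <- character(0)
  for (i in seq_len(nrow(vt))) {
    X <- base_X
    X$release <- df[[vt$column[i]]]
    res <- tryCatch(
      fit_gwr(X, y, coords, k = k, kernel = kernel, ids = df$county_id),
      error = function(e) conditionMessage(e))
    if (inherits(res, "gwr_fit")) fits[[vt$variant[i]]] <- res
    else failed[vt$variant[i]] <- res
  }
  list(fits = fits, baseline = baseline, failed = failed, variants = vt,
       county_id = df$county_id, coords = coords)
}

#' Compare GWR release variants county by county
#'
#' For each county: the variant with the highest local R-squared, its three
#' attribute labels (chemical class, toxicity weighting, onsite vs
#' area-weighted accumulation), the maximum local R-squared, the improvement
#' over the covariate-only baseline fit with identical weights, and the
#' significance class of the winning variant's release coefficient at
#' \eqn{|t| \ge 1.96}. Also tallies how many counties a non-carcinogen
#' variant wins over all carcinogen variants.
#'
#' @param fits Named list of \code{gwr_fit} objects (names are variant ids).
#' @param baseline Covariate-only \code{gwr_fit} with the same counties and
#'   weights.
#' @param variants Variant metadata (default \code{gwr_variant_table()}).
#' @return A list of class \code{gwr_comparison}: per-county data.frame
#'   \code{table} and summary tallies.
#' @export
compare_models <- function(fits, baseline, variants = gwr_variant_table()) {
  if (!length(fits)) stop("no variant fits supplied", call. = FALSE)
  ids <- baseline$ids
  for (f in fits)
    if (!identical(f$ids, ids))
      stop("variant and baseline county sets do not match", call. = FALSE)
  vnames <- names(fits)
  R2 <- sapply(fits, function(f) f$local_r2)
  best_j <- apply(R2, 1, which.max)
  best <- vnames[best_j]
  max_r2 <- R2[cbind(seq_along(best_j), best_j)]
  tstat <- vapply(seq_along(best_j), function(i)
    fits[[best_j[i]]]$t[i, "release"], numeric(1))
  sig <- ifelse(abs(tstat) < 1.96, "nonsignificant",
                ifelse(tstat > 0, "positive", "negative"))
  meta <- variants[match(best, variants$variant), ]
  tab <- data.frame(county_id = ids, best_variant = best,
                    best_class = meta$class,
                    best_tox_weighted = meta$tox_weighted,
                    best_accumulation = meta$accumulation,
                    max_local_r2 = max_r2,
                    baseline_local_r2 = baseline$local_r2,
                    improvement = max_r2 - baseline$local_r2,
                    release_t = tstat, significance = sig)
  n_nonc <- sum(tab$best_class == "non_carcinogen")
  structure(list(table = tab,
                 tally = c(non_carcinogen_best = n_nonc,
                           carcinogen_best = nrow(tab) - n_nonc),
                 n = nrow(tab)),
            class = "gwr_comparison")
}

#' @export
print.gwr_comparison <- function(x, ...) {
  cat(sprintf(
    "GWR model comparison over %d counties: non-carcinogen variant best in %d, carcinogen in %d\n",
    x$n, x$tally["non_carcinogen_best"], x$tally["carcinogen_best"]))
  cat(sprintf("median max local R-squared %.3f, median improvement %.4f\n",
              stats::median(x$table$max_local_r2),
              stats::median(x$table$improvement)))
  invisible(x)
}
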