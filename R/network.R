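#' Construct and validate a watershed network
#'
#' A watershed network is a forest: every watershed drains into at most one
#' downstream watershed, links are acyclic, and areas (in acres) are strictly
#' positive. Braided topologies (more than one downstream link) cannot be
#' represented and malformed inputs (cycles, unknown downstream ids,
#' non-positive areas) are rejected at construction.
#'
#' @param sheds A data.frame with columns \code{shed_id} (unique integer ids),
#'   \code{area_acres} (positive), \code{downstream_id} (integer or \code{NA}
#'   for outlets). Extra columns (e.g. generator seed coordinates) are kept.
#' @return The validated data.frame with class \code{watershed_network}.
#' @export
watershed_network <- function(sheds) {
  stopifnot(is.data.frame(sheds))
  need <- c("shed_id", "area_acres", "downstream_id")
  missing <- setdiff(need, names(sheds))
  if (length(missing))
    stop("network is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheds$shed_id))
    stop("duplicate shed_id values", call. = FALSE)
  if (any(!is.finite(sheds$area_acres)) || any(sheds$area_acres <= 0))
    stop("all watershed areas must be strictly positive", call. = FALSE)
  down <- sheds$downstream_id
  known <- !is.na(down)
  if (any(!(down[known] %in% sheds$shed_id)))
    stop("downstream_id refers to unknown shed(s)", call. = FALSE)
  if (any(down[known] == sheds$shed_id[known]))
    stop("a watershed cannot drain into itself", call. = FALSE)
  # cycle check: follow every downstream path; in a forest of n sheds no
  # path can exceed n hops
  pos <- match(down, sheds$shed_id)
  n <- nrow(sheds)
  for (i in seq_len(n)) {
    j <- i; hops <- 0L
    while (!is.na(pos[j])) {
      j <- pos[j]; hops <- hops + 1L
      if (hops > n) stop("downstream links contain a cycle", call. = FALSE)
    }
  }
  class(sheds) <- c("watershed_network", "data.frame")
  sheds
}

#' @export
print.watershed_network <- function(x, ...) {
  cat(sprintf("watershed network: %d sheds, %d outlet(s), total area %.0f acres\n",
              nrow(x), sum(is.na(x$downstream_id)), sum(x$area_acres)))
  invisible(x)
}

shed_index <- function(network, s) {
  i <- match(s, network$shed_id)
  if (is.na(i)) stop("unknown shed_id: ", s, call. = FALSE)
  i
}

#' Upstream watershed set
#'
#' All watersheds whose downstream path reaches \code{s}, including \code{s}
#' itself (the index set \eqn{w \ge s} of the accumulation formula).
#'
#' @param network A \code{watershed_network}.
#' @param s A shed id present in the network.
#' @return Integer vector of shed ids.
#' @export
upstream_set <- function(network, s) {
  shed_index(network, s)
  pos <- match(network$downstream_id, network$shed_id)
  ids <- network$shed_id
  # reachability by repeated frontier expansion over the reversed links
  in_set <- ids == s
  repeat {
    grew <- !in_set & !is.na(pos) & in_set[pos]
    if (!any(grew)) break
    in_set <- in_set | grew
  }
  ids[in_set]
}

#' Area of the downstream path between two watersheds
#'
#' The sum of areas (acres) over every watershed on the unique downstream
#' path from \code{w} to \code{s}, inclusive of both endpoints. When
#' \code{w == s} this reduces to the area of that single watershed.
#'
#' @param network A \code{watershed_network}.
#' @param w,s Shed ids; \code{s} must lie on \code{w}'s downstream path.
#' @return Path area in acres.
#' @export
path_area <- function(network, w, s) {
  i <- shed_index(network, w)
  shed_index(network, s)
  pos <- match(network$downstream_id, network$shed_id)
  total <- 0
  j <- i
  repeat {
    total <- total + network$area_acres[j]
    if (network$shed_id[j] == s) return(total)
    j <- pos[j]
    if (is.na(j))
      stop(sprintf("shed %s is not downstream of shed %s", s, w), call. = FALSE)
  }
}

#' Accumulate upstream area-weighted pollution scores
#'
#' Computes for every watershed the pollution score
#' \deqn{\pi_s = \sum_{w \ge s} \rho_w / \mathrm{area}_{w \to s}}
#' where \eqn{\rho_w} is the (optionally toxicity-weighted) release sum in
#' watershed \eqn{w} and \eqn{\mathrm{area}_{w \to s}} is the area in acres
#' of all watersheds on the path from \eqn{w} down to \eqn{s}, both ends
#' included. Each release is therefore diluted by the cumulative drainage
#' area it crosses, so far-upstream releases contribute less than local ones.
#'
#' Implemented as one downstream walk per releasing watershed, carrying the
#' running path area; the result is independent of traversal order.
#'
#' @param network A \code{watershed_network}.
#' @param releases Either a named numeric vector (names are shed ids) or a
#'   data.frame with columns \code{shed_id} and \code{release}; sheds not
#'   mentioned default to zero release. Releases must be non-negative.
#' @return A data.frame with columns \code{shed_id}, \code{rho} (the release
#'   sum in the shed) and \code{pi} (the accumulated score).
#' @export
accumulate <- function(network, releases) {
  ids <- network$shed_id
  rho <- numeric(length(ids))
  if (is.data.frame(releases)) {
    idx <- match(releases$shed_id, ids)
    if (anyNA(idx)) stop("release for unknown shed_id", call. = FALSE)
    rho[idx] <- rho[idx] + releases$release
  } else if (length(releases)) {
    idx <- match(as.integer(names(releases)), ids)
    if (anyNA(idx)) stop("release for unknown shed_id", call. = FALSE)
    rho[idx] <- rho[idx] + as.numeric(releases)
  }
  if (any(!is.finite(rho)) || any(rho < 0))
    stop("releases must be finite and non-negative", call. = FALSE)
  pos <- match(network$downstream_id, ids)
  pi_s <- numeric(length(ids))
  for (i in seq_along(ids)) {
    if (rho[i] == 0) next
    j <- i; cum_area <- 0
    repeat {
      cum_area <- cum_area + network$area_acres[j]
      pi_s[j] <- pi_s[j] + rho[i] / cum_area
      j <- pos[j]
      if (is.na(j)) break
    }
  }
  data.frame(shed_id = ids, rho = rho, pi = pi_s)
}
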