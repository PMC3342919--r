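#' Read a discharge record table from CSV
#'
#' Expects columns \code{facility_id}, \code{cas_number},
#' \code{chemical_name}, \code{lon}, \code{lat}, \code{release_kg_yr}.
#' Rows whose coordinates or release fail numeric parsing are reported in
#' \code{attr(, "malformed")} rather than silently dropped.
#'
#' @param path Path to the CSV file.
#' @return A \code{discharge_records} data.frame.
#' @export
read_discharge_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("facility_id", "cas_number", "chemical_name", "lon", "lat",
            "release_kg_yr")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("discharge table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  num <- function(v) suppressWarnings(as.numeric(v))
  lon <- num(raw$lon); lat <- num(raw$lat); rel <- num(raw$release_kg_yr)
  bad <- is.na(lon) | is.na(lat) | is.na(rel)
  rec <- data.frame(facility_id = raw$facility_id[!bad],
                    cas_number = raw$cas_number[!bad],
                    chemical_name = raw$chemical_name[!bad],
                    lon = lon[!bad], lat = lat[!bad],
                    release_kg_yr = rel[!bad])
  malformed <- cbind(row = which(bad), raw[bad, , drop = FALSE])
  attr(rec, "malformed") <- malformed
  if (nrow(malformed))
    warning(nrow(malformed), " malformed row(s); see attr(x, 'malformed')",
            call. = FALSE)
  class(rec) <- c("discharge_records", "data.frame")
  rec
}

filter_reasons <- c("not_in_chemical_subset", "zero_release", "outside_region",
                    "anomalous_coordinates", "identical_values_facility")

#' Filter discharge records by the staged cleaning rules
#'
#' Applies, in order: (1) restrict to chemicals in the weight table; (2) drop
#' zero-release records; (3) drop records outside the study region; (4) drop
#' records with zero or non-finite coordinates; (5) drop every record of any
#' facility with two or more remaining records whose release values are all
#' identical to one another (a copy-paste reporting error). Each removed
#' record is logged once, under the first rule it violates, so the clean set
#' and the rejection log always partition the input and filtering is
#' idempotent.
#'
#' @param records A \code{discharge_records} data.frame.
#' @param chemicals A \code{weight_table}; records of other chemicals are
#'   removed at stage 1.
#' @param region Study region rectangle \code{c(xmin, xmax, ymin, ymax)}
#'   (bounds inclusive).
#' @return A list with \code{clean} (surviving records) and
#'   \code{rejections} (data.frame: \code{row}, \code{facility_id},
#'   \code{reason}, \code{stage}).
#' @export
filter_records <- function(records, chemicals = load_weight_table(),
                           region) {
  stopifnot(is.data.frame(records))
  if (length(region) != 4 || region[2] <= region[1] || region[4] <= region[3])
    stop("region must be c(xmin, xmax, ymin, ymax)", call. = FALSE)
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  stage <- rep(NA_integer_, n)
  mark <- function(idx, r, s) {
    new <- idx[is.na(reason[idx])]
    reason[new] <<- r; stage[new] <<- s
  }
  mark(which(!(records$chemical_name %in% chemicals$chemical_name)),
       "not_in_chemical_subset", 1L)
  mark(which(is.na(reason) & records$release_kg_yr == 0), "zero_release", 2L)
  out <- records$lon < region[1] | records$lon > region[2] |
    records$lat < region[3] | records$lat > region[4]
  mark(which(is.na(reason) & out), "outside_region", 3L)
  anom <- !is.finite(records$lon) | !is.finite(records$lat) |
    records$lon == 0 | records$lat == 0
  mark(which(is.na(reason) & anom), "anomalous_coordinates", 4L)
  # stage 5 on the survivors of stages 1-4: multi-record facilities whose
  # remaining releases are all equal
  alive <- which(is.na(reason))
  if (length(alive)) {
    split_rel <- split(records$release_kg_yr[alive], records$facility_id[alive])
    ident <- names(split_rel)[vapply(split_rel, function(v)
      length(v) >= 2L && length(unique(v)) == 1L, logical(1))]
    mark(alive[records$facility_id[alive] %in% ident],
         "identical_values_facility", 5L)
  }
  keep <- is.na(reason)
  clean <- records[keep, , drop = FALSE]
  rownames(clean) <- NULL
  class(clean) <- c("discharge_records", "data.frame")
  rejections <- data.frame(row = which(!keep),
                           facility_id = records$facility_id[!keep],
                           reason = reason[!keep], stage = stage[!keep])
  list(clean = clean, rejections = rejections)
}

#' Assign clean discharge records to watersheds and sum per chemical
#'
#' Each record is assigned to exactly one watershed by containment in the
#' network's Voronoi regions (nearest seed; boundary ties resolve to the
#' smaller shed id), then release masses are summed per (watershed,
#' chemical). Total mass is conserved.
#'
#' @param records Filtered \code{discharge_records}.
#' @param network A \code{\link{watershed_network}} carrying \code{seed_x},
#'   \code{seed_y} geometry columns.
#' @return A data.frame with columns \code{shed_id}, \code{chemical_name},
#'   \code{release_kg_yr}.
#' @export
assign_watersheds <- function(records, network) {
  stopifnot(inherits(network, "watershed_network"))
  if (!all(c("seed_x", "seed_y") %in% names(network)))
    stop("network carries no geometry (seed_x/seed_y) for assignment",
         call. = FALSE)
  if (!nrow(records))
    return(data.frame(shed_id = integer(0), chemical_name = character(0),
                      release_kg_yr = numeric(0)))
  if (any(!is.finite(records$lon)) || any(!is.finite(records$lat)))
    stop("cannot assign records with non-finite coordinates; rows: ",
         paste(utils::head(which(!is.finite(records$lon) |
                                   !is.finite(records$lat)), 10),
               collapse = ", "), call. = FALSE)
  idx <- nearest_seed(records$lon, records$lat, network$seed_x, network$seed_y)
  shed <- network$shed_id[idx]
  agg <- stats::aggregate(records$release_kg_yr,
                          by = list(shed_id = shed,
                                    chemical_name = records$chemical_name),
                          FUN = sum)
  names(agg)[3] <- "release_kg_yr"
  agg <- agg[order(agg$shed_id, agg$chemical_name), ]
  rownames(agg) <- NULL
  agg
}
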