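#' Load the chemical toxicity weight table
#'
#' Reads and validates the ingestion toxicity weight table used to scale
#' discharge masses. With no argument the packaged default table is returned:
#' 38 chemicals with EPA ingestion toxicity weights, of which 30 are treated
#' as non-carcinogens and 8 as carcinogens (IARC class 1/2a/2b or NTP
#' Known/Probable). Weights are dimensionless multipliers applied to kg/yr
#' release masses.
#'
#' @param path Optional path to a CSV with columns \code{chemical_name},
#'   \code{cas_number}, \code{toxicity_weight}, \code{carcinogen_class}.
#'   Defaults to the packaged table.
#' @return A \code{data.frame} of class \code{weight_table}.
#' @examples
#' wt <- load_weight_table()
#' nrow(wt)                        # 38
#' wt[wt$chemical_name == "Lead", "toxicity_weight"]
#' @export
load_weight_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "toxicity_weights.csv", package = "toxsheds",
                        mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("chemical_name", "cas_number", "toxicity_weight", "carcinogen_class")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop("weight table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(tab$chemical_name))
    stop("duplicate chemical name(s): ",
         paste(unique(tab$chemical_name[duplicated(tab$chemical_name)]),
               collapse = ", "), call. = FALSE)
  if (!is.numeric(tab$toxicity_weight) || any(!is.finite(tab$toxicity_weight)) ||
      any(tab$toxicity_weight <= 0))
    stop("toxicity weights must all be positive finite numbers", call. = FALSE)
  bad_class <- setdiff(unique(tab$carcinogen_class), c("carcinogen", "non_carcinogen"))
  if (length(bad_class))
    stop("unknown carcinogen_class value(s): ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  class(tab) <- c("weight_table", "data.frame")
  tab
}

#' Toxicity-weight and class-sum per-watershed chemical releases
#'
#' Multiplies each chemical's summed release mass by its toxicity weight
#' (when \code{weighted = TRUE}) and sums within each watershed separately
#' over carcinogens and non-carcinogens. Output stays on the linear kg/yr
#' scale; the log transform is applied later, at the county-variable level.
#'
#' @param sums A data.frame with columns \code{shed_id}, \code{chemical_name},
#'   \code{release_kg_yr} (per-shed, per-chemical summed releases, as produced
#'   by \code{\link{assign_watersheds}}).
#' @param table A \code{weight_table}; defaults to the packaged table.
#' @param weighted Logical; multiply by toxicity weights before summing?
#' @return A data.frame with columns \code{shed_id}, \code{carcinogen},
#'   \code{non_carcinogen}: class sums per watershed.
#' @examples
#' s <- data.frame(shed_id = 1L,
#'                 chemical_name = "Polychlorinated biphenyls",
#'                 release_kg_yr = 1)
#' apply_weights(s, weighted = TRUE)$carcinogen  # 2e6
#' @export
apply_weights <- function(sums, table = load_weight_table(), weighted = TRUE) {
  stopifnot(is.data.frame(sums))
  need <- c("shed_id", "chemical_name", "release_kg_yr")
  missing <- setdiff(need, names(sums))
  if (length(missing))
    stop("'sums' is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  idx <- match(sums$chemical_name, table$chemical_name)
  if (anyNA(idx))
    stop("chemical(s) not in weight table: ",
         paste(unique(sums$chemical_name[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  amount <- sums$release_kg_yr
  if (any(amount < 0)) stop("negative release mass", call. = FALSE)
  if (weighted) amount <- amount * table$toxicity_weight[idx]
  cls <- table$carcinogen_class[idx]
  sheds <- sort(unique(sums$shed_id))
  carc <- vapply(sheds, function(s)
    sum(amount[sums$shed_id == s & cls == "carcinogen"]), numeric(1))
  nonc <- vapply(sheds, function(s)
    sum(amount[sums$shed_id == s & cls == "non_carcinogen"]), numeric(1))
  data.frame(shed_id = sheds, carcinogen = carc, non_carcinogen = nonc)
}

#' Log transform for discharge scores
#'
#' The shifted natural log \eqn{\ln(1 + x)} used for all discharge analysis
#' variables: strictly monotone, continuous at zero, and maps a zero score to
#' zero so that watersheds and counties with no discharge remain finite.
#'
#' @param x Non-negative numeric vector of linear-scale scores.
#' @return \code{log1p(x)}.
#' @export
log_score <- function(x) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("log_score requires finite non-negative input", call. = FALSE)
  log1p(x)
}
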