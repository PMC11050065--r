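# Presence records: container, uncertainty filtering, spatial thinning, CSV I/O.

#' Construct a set of presence records
#'
#' @param species Species name.
#' @param lon,lat Coordinates in decimal degrees.
#' @param uncertainty_km Optional per-point coordinate uncertainty in km
#'   (`NA` allowed for unknown).
#' @return An `occurrence_set` (a data frame with columns `lon`, `lat` and
#'   optionally `uncertainty_km`, plus a `species` attribute).
#' @export
occurrence_set <- function(species, lon, lat, uncertainty_km = NULL) {
  stopifnot(length(lon) == length(lat))
  if (length(lon) && (any(abs(lat) > 90) || any(abs(lon) > 180)))
    stop("coordinates out of bounds")
  df <- data.frame(lon = as.numeric(lon), lat = as.numeric(lat))
  if (!is.null(uncertainty_km)) df$uncertainty_km <- as.numeric(uncertainty_km)
  structure(df, species = species, class = c("occurrence_set", "data.frame"))
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("occurrence_set '%s': %d records%s\n", attr(x, "species"), nrow(x),
              if ("uncertainty_km" %in% names(x)) " (with uncertainty)" else ""))
  invisible(x)
}

#' Drop records with large coordinate uncertainty
#'
#' Keeps records whose uncertainty is unknown or at most `max_km`; the rule
#' is strictly greater-than, so a record at exactly `max_km` is retained.
#'
#' @param occ An [occurrence_set()].
#' @param max_km Threshold in km (default 5).
#' @return The filtered `occurrence_set`.
#' @export
filter_uncertainty <- function(occ, max_km = 5) {
  if (!"uncertainty_km" %in% names(occ)) return(occ)
  keep <- is.na(occ$uncertainty_km) | occ$uncertainty_km <= max_km
  if (!any(keep)) warning("all records exceed the uncertainty threshold")
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, species = attr(occ, "species"),
            class = c("occurrence_set", "data.frame"))
}

# pairwise haversine distances in km (R = 6371 km)
haversine_km <- function(pts) {
  geosphere::distm(as.matrix(pts[, c("lon", "lat")]),
                   fun = function(p1, p2)
                     geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
}

#' Spatially thin presence records to a minimum separation
#'
#' Greedy thinning: records are visited in a seeded random order and kept if
#' at least `min_km` (great-circle, haversine on a 6371-km sphere) from every
#' record already kept. The result is maximal: no dropped record could be
#' added back without violating the separation.
#'
#' @param occ An [occurrence_set()].
#' @param min_km Minimum pairwise separation in km (default 10).
#' @param seed Integer seed for the visiting order.
#' @return The thinned `occurrence_set`.
#' @export
spatial_thin <- function(occ, min_km = 10, seed = 1) {
  stopifnot(min_km > 0)
  n <- nrow(occ)
  if (n <= 1) return(occ)
  set.seed(seed)
  ord <- sample.int(n)
  d <- haversine_km(occ)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(d[i, kept] >= min_km)) kept <- c(kept, i)
  }
  out <- occ[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, species = attr(occ, "species"),
            class = c("occurrence_set", "data.frame"))
}

#' Read presence records from CSV
#'
#' Expects a header with columns `species`, `lon`, `lat` and optionally
#' `uncertainty_km`. Out-of-bounds coordinates are rejected with their row
#' numbers.
#'
#' @param path CSV file path.
#' @return An [occurrence_set()].
#' @export
read_occurrences <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("lon", "lat"))
    if (!col %in% names(df)) stop("missing required column '", col, "' in ", path)
  bad <- which(abs(df$lat) > 90 | abs(df$lon) > 180 | is.na(df$lon) | is.na(df$lat))
  if (length(bad)) stop("out-of-bounds or missing coordinates at row(s): ",
                        paste(bad, collapse = ", "))
  species <- if ("species" %in% names(df) && nrow(df)) df$species[1] else "unknown"
  occurrence_set(species, df$lon, df$lat,
                 uncertainty_km = if ("uncertainty_km" %in% names(df)) df$uncertainty_km)
}

#' Write presence records to CSV
#'
#' @param occ An [occurrence_set()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(occ, path) {
  df <- cbind(species = attr(occ, "species"), as.data.frame(occ))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
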