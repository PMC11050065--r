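# Per-cell map containers: continuous suitability and binary ranges.

#' Habitat-suitability map
#'
#' Per-cell occurrence probability in \[0, 1\] for one species under one
#' scenario; `NA` off land.
#'
#' @param grid A [grid_spec()].
#' @param values Numeric matrix `n_rows x n_cols`.
#' @param species,scenario_label Identifiers.
#' @return A `suitability_map` object.
#' @export
suitability_map <- function(grid, values, species = "", scenario_label = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values),
            nrow(values) == grid$n_rows, ncol(values) == grid$n_cols)
  v <- values[is.finite(values)]
  if (length(v) && (min(v) < -1e-9 || max(v) > 1 + 1e-9))
    stop("suitability values must lie in [0, 1]")
  structure(list(grid = grid, values = values, species = species,
                 scenario_label = scenario_label), class = "suitability_map")
}

#' @export
print.suitability_map <- function(x, ...) {
  cat(sprintf("suitability_map %s/%s: %d x %d, mean %.3f on land\n",
              x$species, x$scenario_label, x$grid$n_rows, x$grid$n_cols,
              mean(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Binary range map
#'
#' Presence/absence per cell after thresholding a suitability map; the
#' threshold used is recorded.
#'
#' @param grid A [grid_spec()].
#' @param presence Logical matrix (`NA` off land).
#' @param threshold_used The threshold that produced the map.
#' @param species,scenario_label Identifiers.
#' @return A `binary_range_map` object.
#' @export
binary_range_map <- function(grid, presence, threshold_used = NA_real_,
                             species = "", scenario_label = "") {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(presence),
            nrow(presence) == grid$n_rows, ncol(presence) == grid$n_cols)
  structure(list(grid = grid, presence = presence, threshold_used = threshold_used,
                 species = species, scenario_label = scenario_label),
            class = "binary_range_map")
}

#' @export
print.binary_range_map <- function(x, ...) {
  cat(sprintf("binary_range_map %s/%s: %d presence cells (threshold %.3g)\n",
              x$species, x$scenario_label, sum(x$presence, na.rm = TRUE),
              x$threshold_used))
  invisible(x)
}

#' Threshold a suitability map into a binary range
#'
#' A land cell is predicted present iff its suitability is `>= tau`.
#'
#' @param map A [suitability_map()].
#' @param tau Threshold in \[0, 1\] (values slightly above 1 give an empty map).
#' @return A [binary_range_map()] with `threshold_used = tau`.
#' @export
binarize <- function(map, tau) {
  stopifnot(inherits(map, "suitability_map"), tau >= 0)
  presence <- map$values >= tau
  binary_range_map(map$grid, presence, threshold_used = tau,
                   species = map$species, scenario_label = map$scenario_label)
}
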