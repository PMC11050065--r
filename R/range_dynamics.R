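# Range dynamics between scenarios: expansion/contraction/stable areas,
# range ratio index (RRI) and range similarity index (RSI), additive
# overlays, total-suitability differencing, and scenario summaries.

#' Range change between a current and a future binary range
#'
#' Decomposes the union of the two ranges into stable (`SR`, present in
#' both), expansion (future only) and contraction (current only) areas using
#' latitude-aware spherical cell areas, and derives
#' `RCS = SR + contraction` (current range), `RFS = SR + expansion` (future
#' range), `RRI = RFS / RCS` (> 1 means net expansion) and the
#' Sorensen-type `RSI = 2 SR / (RCS + RFS)` in \[0, 1\] (low values mean the
#' range moved).
#'
#' @param current,future [binary_range_map()]s on the same grid.
#' @return A `range_dynamics_result`: areas in km^2 (`SR`, `expansion`,
#'   `contraction`, `RCS`, `RFS`) and indices (`RRI`, `RSI`; `NA` with a
#'   warning when undefined).
#' @export
range_dynamics <- function(current, future) {
  if (!grid_equal(current$grid, future$grid)) stop("maps are on different grids")
  areas <- cell_area_matrix(current$grid)
  cur <- current$presence & !is.na(current$presence)
  fut <- future$presence & !is.na(future$presence)
  SR <- sum(areas[cur & fut])
  expansion <- sum(areas[fut & !cur])
  contraction <- sum(areas[cur & !fut])
  RCS <- SR + contraction
  RFS <- SR + expansion
  RRI <- if (RCS > 0) RFS / RCS else { warning("RCS = 0: RRI undefined"); NA_real_ }
  RSI <- if (RCS + RFS > 0) 2 * SR / (RCS + RFS) else {
    warning("empty ranges in both scenarios: RSI undefined"); NA_real_ }
  structure(list(species = current$species,
                 scenario_pair = c(current$scenario_label, future$scenario_label),
                 SR = SR, expansion = expansion, contraction = contraction,
                 RCS = RCS, RFS = RFS, RRI = RRI, RSI = RSI),
            class = "range_dynamics_result")
}

#' @export
print.range_dynamics_result <- function(x, ...) {
  cat(sprintf(
    "range_dynamics %s (%s -> %s): RCS %.3g, RFS %.3g km^2; RRI %.3f, RSI %.3f\n",
    x$species, x$scenario_pair[1], x$scenario_pair[2], x$RCS, x$RFS, x$RRI, x$RSI))
  invisible(x)
}

#' Additive overlay of binary range maps
#'
#' @param maps List of [binary_range_map()]s on a shared grid.
#' @return An `overlay_map`: integer counts per cell (0..n maps).
#' @export
overlay_counts <- function(maps) {
  stopifnot(length(maps) >= 1)
  grid <- maps[[1]]$grid
  counts <- matrix(0L, grid$n_rows, grid$n_cols)
  for (m in maps) {
    if (!grid_equal(m$grid, grid)) stop("overlayed maps must share one grid")
    counts <- counts + ifelse(is.na(m$presence), 0L, as.integer(m$presence))
  }
  structure(list(grid = grid, counts = counts,
                 scenario_label = maps[[1]]$scenario_label,
                 n_maps = length(maps)), class = "overlay_map")
}

#' Total habitat suitability across species
#'
#' Per-cell sum of suitability maps; range \[0, n species\].
#'
#' @param maps List of [suitability_map()]s on a shared grid.
#' @return A list with `grid`, `values` (matrix), `scenario_label`.
#' @export
total_suitability <- function(maps) {
  stopifnot(length(maps) >= 1)
  grid <- maps[[1]]$grid
  total <- matrix(0, grid$n_rows, grid$n_cols)
  for (m in maps) {
    if (!grid_equal(m$grid, grid)) stop("suitability maps must share one grid")
    total <- total + m$values
  }
  list(grid = grid, values = total, scenario_label = maps[[1]]$scenario_label)
}

#' Difference two total-suitability surfaces
#'
#' `delta = future - current` per cell; cells with positive delta contribute
#' to `increased_area`, negative to `decreased_area` (spherical km^2);
#' zero-delta cells count to neither.
#'
#' @param total_future,total_current Results of [total_suitability()].
#' @return A `suitability_change`: `delta` matrix plus the two areas.
#' @export
suitability_change <- function(total_future, total_current) {
  if (!grid_equal(total_future$grid, total_current$grid))
    stop("totals are on different grids")
  delta <- total_future$values - total_current$values
  areas <- cell_area_matrix(total_future$grid)
  inc <- sum(areas[!is.na(delta) & delta > 0])
  dec <- sum(areas[!is.na(delta) & delta < 0])
  structure(list(grid = total_future$grid, delta = delta,
                 increased_area = inc, decreased_area = dec),
            class = "suitability_change")
}

#' Summarize range dynamics across species and scenarios
#'
#' Computes per-scenario arithmetic means of RRI and RSI, top-k rankings
#' (largest future ranges, largest RRI = biggest expansions, smallest RSI =
#' biggest range shifts), and two-sided paired t-tests on per-species values
#' for requested scenario contrasts.
#'
#' @param dynamics Data frame with columns `species`, `scenario`, `RRI`,
#'   `RSI` and optionally `RFS` (future range area). One row per species x
#'   scenario; a list of `range_dynamics_result`s is also accepted.
#' @param contrasts List of scenario pairs to test, e.g.
#'   `list(c("F126", "F585"))`; species missing from either side of a pair
#'   are excluded pairwise with a warning.
#' @param top_k Ranking depth (default 5).
#' @return A `scenario_summary`: `means` (per-scenario mean RRI/RSI, with
#'   2-decimal report columns), `rankings`, and `tests` (paired t statistic,
#'   df, p-value per contrast and index).
#' @export
summarize_scenarios <- function(dynamics, contrasts = list(), top_k = 5) {
  if (!is.data.frame(dynamics))
    dynamics <- do.call(rbind, lapply(dynamics, function(d)
      data.frame(species = d$species, scenario = d$scenario_pair[2],
                 RRI = d$RRI, RSI = d$RSI, RFS = d$RFS)))
  stopifnot(all(c("species", "scenario", "RRI", "RSI") %in% names(dynamics)))

  means <- do.call(rbind, lapply(split(dynamics, dynamics$scenario), function(d)
    data.frame(scenario = d$scenario[1], n = nrow(d),
               mean_RRI = mean(d$RRI, na.rm = TRUE),
               mean_RSI = mean(d$RSI, na.rm = TRUE))))
  means$report_RRI <- round(means$mean_RRI, 2)
  means$report_RSI <- round(means$mean_RSI, 2)
  rownames(means) <- NULL

  rank_top <- function(d, col, decreasing) {
    d <- d[!is.na(d[[col]]), ]
    d[order(d[[col]], decreasing = decreasing)[seq_len(min(top_k, nrow(d)))],
      c("species", col)]
  }
  rankings <- lapply(split(dynamics, dynamics$scenario), function(d) {
    out <- list(largest_rri = rank_top(d, "RRI", TRUE),
                smallest_rsi = rank_top(d, "RSI", FALSE))
    if ("RFS" %in% names(d) && !all(is.na(d$RFS)))
      out$largest_range <- rank_top(d, "RFS", TRUE)
    out
  })

  tests <- list()
  for (ct in contrasts) {
    a <- dynamics[dynamics$scenario == ct[1], ]
    b <- dynamics[dynamics$scenario == ct[2], ]
    common <- intersect(a$species, b$species)
    if (length(common) < length(union(a$species, b$species)))
      warning("contrast ", ct[1], " vs ", ct[2],
              ": species missing on one side excluded pairwise")
    if (length(common) < 2) { warning("contrast skipped: fewer than 2 paired species"); next }
    a <- a[match(common, a$species), ]; b <- b[match(common, b$species), ]
    for (index in c("RRI", "RSI")) {
      d <- a[[index]] - b[[index]]
      if (stats::sd(d) == 0) { # degenerate: constant paired differences
        t_stat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
        df <- length(d) - 1
        p <- if (mean(d) == 0) 1 else 0
      } else {
        tt <- stats::t.test(a[[index]], b[[index]], paired = TRUE)
        t_stat <- unname(tt$statistic); df <- unname(tt$parameter); p <- tt$p.value
      }
      tests[[paste(ct[1], ct[2], index, sep = "_")]] <-
        data.frame(contrast = paste(ct[1], "vs", ct[2]), index = index,
                   n_pairs = length(common), t = t_stat, df = df, p_value = p)
    }
  }
  tests <- if (length(tests)) do.call(rbind, c(tests, make.row.names = FALSE)) else NULL

  structure(list(means = means, rankings = rankings, tests = tests),
            class = "scenario_summary")
}

#' @export
print.scenario_summary <- function(x, ...) {
  cat("scenario_summary\n")
  print(x$means[c("scenario", "n", "report_RRI", "report_RSI")])
  if (!is.null(x$tests)) { cat("paired t-tests:\n"); print(x$tests) }
  invisible(x)
}
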