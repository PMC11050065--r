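# Geographic grid: cell-center registration, row 1 = northernmost row,
# row-major storage (matrices are n_rows x n_cols).

EARTH_RADIUS_KM <- 6371

#' Define a regular longitude/latitude grid
#'
#' Cells are registered on their centers; row 1 is the northernmost row and
#' columns run west to east. The bounds are the outer edges of the grid, so a
#' grid from 0 to 10 degrees at 1-degree resolution has 10 cells per axis with
#' centers at 0.5, 1.5, ..., 9.5.
#'
#' @param lon_min,lon_max,lat_min,lat_max Outer grid edges in decimal degrees.
#' @param resolution Cell size in degrees (default 2.5/60, i.e. 2.5 arc-min).
#' @return A `grid_spec` object with `n_rows`/`n_cols` derived from the
#'   bounds and resolution.
#' @examples
#' g <- grid_spec(-10, 10, 0, 20, resolution = 1)
#' g$n_rows # 20
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, resolution = 2.5 / 60) {
  stopifnot(resolution > 0, lon_max > lon_min, lat_max > lat_min)
  if (lat_min < -90 || lat_max > 90) stop("latitude bounds must lie in [-90, 90]")
  if (lon_min < -180 || lon_max > 180) stop("longitude bounds must lie in [-180, 180]")
  n_cols <- round((lon_max - lon_min) / resolution)
  n_rows <- round((lat_max - lat_min) / resolution)
  if (n_rows * n_cols <= 0) stop("grid must contain at least one cell")
  structure(
    list(lon_min = lon_min, lon_max = lon_min + n_cols * resolution,
         lat_min = lat_max - n_rows * resolution, lat_max = lat_max,
         resolution = resolution, n_rows = n_rows, n_cols = n_cols),
    class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d rows x %d cols at %.6g deg, lon [%.4g, %.4g], lat [%.4g, %.4g]\n",
              x$n_rows, x$n_cols, x$resolution, x$lon_min, x$lon_max, x$lat_min, x$lat_max))
  invisible(x)
}

n_cells <- function(grid) grid$n_rows * grid$n_cols

grid_equal <- function(a, b) {
  isTRUE(all.equal(unclass(a)[c("lon_min", "lat_max", "resolution", "n_rows", "n_cols")],
                   unclass(b)[c("lon_min", "lat_max", "resolution", "n_rows", "n_cols")]))
}

#' Cell-center coordinates of a grid
#'
#' @param grid A [grid_spec()].
#' @return List with `lon` (length `n_cols`) and `lat` (length `n_rows`,
#'   north to south) cell-center vectors.
#' @export
cell_centers <- function(grid) {
  list(
    lon = grid$lon_min + (seq_len(grid$n_cols) - 0.5) * grid$resolution,
    lat = grid$lat_max - (seq_len(grid$n_rows) - 0.5) * grid$resolution)
}

#' Locate grid cells containing coordinates
#'
#' @param grid A [grid_spec()].
#' @param lon,lat Coordinate vectors in degrees.
#' @return List with integer vectors `row`, `col` and `linear` (column-major
#'   matrix index); coordinates outside the grid clamp to the border cell.
#' @export
cell_index <- function(grid, lon, lat) {
  col <- floor((lon - grid$lon_min) / grid$resolution) + 1
  row <- floor((grid$lat_max - lat) / grid$resolution) + 1
  col <- pmin(pmax(col, 1L), grid$n_cols)
  row <- pmin(pmax(row, 1L), grid$n_rows)
  list(row = as.integer(row), col = as.integer(col),
       linear = as.integer((col - 1L) * grid$n_rows + row))
}

#' Spherical cell areas by grid row
#'
#' The area of a lon/lat cell on a sphere of radius R is
#' `R^2 * dlambda * (sin(phi_top) - sin(phi_bottom))` with angles in radians;
#' it is constant along a row and shrinks toward the poles. R = 6371 km.
#'
#' @param grid A [grid_spec()].
#' @return Numeric vector of length `n_rows`: the area in km^2 of one cell in
#'   each row, ordered north to south.
#' @examples
#' g <- grid_spec(0, 2.5 / 60, 0, 2.5 / 60) # one 2.5 arc-min cell at the equator
#' cell_areas(g) # ~ 21.47 km^2
#' @export
cell_areas <- function(grid) {
  d2r <- pi / 180
  lat_top <- grid$lat_max - (seq_len(grid$n_rows) - 1) * grid$resolution
  lat_bot <- lat_top - grid$resolution
  EARTH_RADIUS_KM^2 * (grid$resolution * d2r) *
    (sin(lat_top * d2r) - sin(lat_bot * d2r))
}

# per-cell area matrix (n_rows x n_cols)
cell_area_matrix <- function(grid) {
  matrix(cell_areas(grid), nrow = grid$n_rows, ncol = grid$n_cols)
}
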