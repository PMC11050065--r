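# Monthly climate container and bioclimatic variables B1-B19.

#' Monthly climate series on a grid
#'
#' @param grid A [grid_spec()].
#' @param tmean,tmin,tmax Arrays `n_rows x n_cols x 12` of monthly mean,
#'   minimum and maximum temperature (deg C).
#' @param prec Array `n_rows x n_cols x 12` of monthly precipitation (mm).
#' @return A `monthly_climate` object. Requires `tmin <= tmean <= tmax`
#'   per month and `prec >= 0`.
#' @export
monthly_climate <- function(grid, tmean, tmin, tmax, prec) {
  stopifnot(inherits(grid, "grid_spec"))
  dims <- c(grid$n_rows, grid$n_cols, 12)
  for (nm in c("tmean", "tmin", "tmax", "prec")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), as.integer(dims)))
      stop(nm, " must be an n_rows x n_cols x 12 array (12 months required)")
  }
  if (any(tmin > tmean + 1e-9) || any(tmean > tmax + 1e-9))
    stop("monthly temperatures must satisfy tmin <= tmean <= tmax")
  if (any(prec < 0)) stop("precipitation must be non-negative")
  structure(list(grid = grid, tmean = tmean, tmin = tmin, tmax = tmax,
                 prec = prec), class = "monthly_climate")
}

#' Generate a synthetic seasonal monthly climate
#'
#' Sinusoidal seasonal cycle on top of smoothed spatial fields; amplitude
#' grows with latitude as on a real planet. Convenience generator for
#' exercising [bioclim_from_monthly()].
#'
#' @param grid A [grid_spec()].
#' @param seed Integer seed.
#' @param autocorr_length Spatial autocorrelation length in degrees.
#' @return A [monthly_climate()].
#' @export
make_monthly_climate <- function(grid, seed = 1, autocorr_length = 5) {
  set.seed(seed)
  sigma <- autocorr_length / grid$resolution
  rf <- function() smooth_field(
    matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols), sigma)
  lat <- matrix(cell_centers(grid)$lat, grid$n_rows, grid$n_cols)
  base_t <- 25 - 0.4 * abs(lat) + 4 * rf()           # annual mean temperature
  amp <- 2 + 0.25 * abs(lat) + abs(rf())             # seasonal amplitude
  base_p <- pmax(0, 80 + 30 * rf())                  # mean monthly precipitation
  dims <- c(grid$n_rows, grid$n_cols, 12)
  tmean <- array(0, dims); prec <- array(0, dims)
  for (m in 1:12) {
    phase <- cos(2 * pi * (m - 1) / 12) * sign(lat + 1e-9) # opposite hemispheres
    tmean[, , m] <- base_t - amp * phase
    prec[, , m] <- pmax(0, base_p * (1 + 0.5 * sin(2 * pi * (m - 1) / 12)))
  }
  drange <- 3 + abs(rf())                            # diurnal half-range
  tmin <- tmean - array(drange, dims)
  tmax <- tmean + array(drange, dims)
  monthly_climate(grid, tmean, tmin, tmax, prec)
}

# mean over the 3-month wrap-around window starting at month w, per cell
quarter_stat <- function(mat12, w, fun_sum = FALSE) {
  idx <- ((w - 1 + 0:2) %% 12) + 1
  s <- mat12[, idx[1]] + mat12[, idx[2]] + mat12[, idx[3]]
  if (fun_sum) s else s / 3
}

#' Bioclimatic variables B1-B19 from monthly climate
#'
#' Standard definitions: B1 annual mean temperature; B2 mean diurnal range;
#' B3 isothermality (100 * B2/B7); B4 temperature seasonality (100 * sd of
#' monthly means); B5/B6 max of monthly tmax / min of monthly tmin; B7 annual
#' range (B5 - B6); B8-B11 mean temperature of the wettest/driest/warmest/
#' coldest quarter; B12 annual precipitation; B13/B14 wettest/driest month;
#' B15 precipitation seasonality (100 * sd / (1 + mean)); B16-B19
#' precipitation of the wettest/driest/warmest/coldest quarter. Quarters are
#' the 12 wrap-around consecutive 3-month windows, selected by precipitation
#' sum (wettest/driest) or mean temperature (warmest/coldest); ties go to the
#' earliest start month. Standard deviations use the sample (n-1) formula.
#'
#' @param mc A [monthly_climate()].
#' @return An [env_stack()] with 19 climate layers `B1`-`B19`.
#' @export
bioclim_from_monthly <- function(mc) {
  stopifnot(inherits(mc, "monthly_climate"))
  grid <- mc$grid
  nc <- n_cells(grid)
  flat <- function(a) matrix(a, nrow = nc, ncol = 12) # cells x months
  tm <- flat(mc$tmean); tn <- flat(mc$tmin); tx <- flat(mc$tmax); pr <- flat(mc$prec)

  b <- list()
  b$B1 <- rowMeans(tm)
  b$B2 <- rowMeans(tx - tn)
  b$B4 <- 100 * apply(tm, 1, stats::sd)
  b$B5 <- apply(tx, 1, max)
  b$B6 <- apply(tn, 1, min)
  b$B7 <- b$B5 - b$B6
  b$B3 <- ifelse(b$B7 == 0, 0, 100 * b$B2 / b$B7)
  b$B12 <- rowSums(pr)
  b$B13 <- apply(pr, 1, max)
  b$B14 <- apply(pr, 1, min)
  pbar <- rowMeans(pr)
  b$B15 <- 100 * apply(pr, 1, stats::sd) / (1 + pbar)

  q_prec <- sapply(1:12, function(w) quarter_stat(pr, w, fun_sum = TRUE)) # cells x 12
  q_temp <- sapply(1:12, function(w) quarter_stat(tm, w))
  if (nc == 1) { q_prec <- matrix(q_prec, 1); q_temp <- matrix(q_temp, 1) }
  wettest <- max.col(q_prec, ties.method = "first")
  driest  <- max.col(-q_prec, ties.method = "first")
  warmest <- max.col(q_temp, ties.method = "first")
  coldest <- max.col(-q_temp, ties.method = "first")
  pick <- function(m, w) m[cbind(seq_len(nc), w)]
  b$B8  <- pick(q_temp, wettest)
  b$B9  <- pick(q_temp, driest)
  b$B10 <- pick(q_temp, warmest)
  b$B11 <- pick(q_temp, coldest)
  b$B16 <- pick(q_prec, wettest)
  b$B17 <- pick(q_prec, driest)
  b$B18 <- pick(q_prec, warmest)
  b$B19 <- pick(q_prec, coldest)

  codes <- paste0("B", 1:19)
  layers <- lapply(b[codes], function(v) matrix(v, grid$n_rows, grid$n_cols))
  env_stack(grid, layers, stats::setNames(rep("climate", 19), codes),
            scenario_label = "current")
}
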