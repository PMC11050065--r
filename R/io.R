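# Raster and configuration I/O. Rasters use the ESRI ASCII grid format
# (plain text: 6-line header + rows of values, northernmost row first),
# which round-trips the cell-center grid convention exactly.

#' Write a single layer as an ESRI ASCII grid
#'
#' @param values Numeric matrix (row 1 = northernmost row).
#' @param grid A [grid_spec()].
#' @param path Output path (conventionally `.asc`).
#' @param nodata Value standing in for `NA` (default -9999).
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(values, grid, path, nodata = -9999) {
  stopifnot(is.matrix(values), nrow(values) == grid$n_rows,
            ncol(values) == grid$n_cols)
  header <- c(
    sprintf("ncols %d", grid$n_cols),
    sprintf("nrows %d", grid$n_rows),
    sprintf("xllcorner %.10g", grid$lon_min),
    sprintf("yllcorner %.10g", grid$lat_min),
    sprintf("cellsize %.10g", grid$resolution),
    sprintf("NODATA_value %.10g", nodata))
  v <- values
  v[is.na(v)] <- nodata
  rows <- apply(v, 1, function(r) paste(formatC(r, format = "g", digits = 9),
                                        collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read an ESRI ASCII grid
#'
#' @param path File path.
#' @return List with `values` (matrix, `NA` at NODATA cells) and `grid`.
#' @export
read_ascii_grid <- function(path) {
  lines <- readLines(path)
  header <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    header[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize"))
    if (is.null(header[[key]])) stop("malformed ESRI ASCII header in ", path,
                                     ": missing ", key)
  n_rows <- header$nrows; n_cols <- header$ncols
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  if (length(vals) != n_rows * n_cols)
    stop("expected ", n_rows * n_cols, " values, found ", length(vals), " in ", path)
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  if (!is.null(header$nodata_value)) m[m == header$nodata_value] <- NA
  grid <- grid_spec(header$xllcorner, header$xllcorner + n_cols * header$cellsize,
                    header$yllcorner, header$yllcorner + n_rows * header$cellsize,
                    resolution = header$cellsize)
  list(values = m, grid = grid)
}

#' Write an environmental stack as one ASCII grid per layer
#'
#' Layer files are named `<code>.asc`; a `stack.yml` sidecar records the
#' scenario label and group tags. Off-land cells are written as NODATA.
#'
#' @param env An [env_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_rasters <- function(env, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (code in names(env$layers)) {
    v <- env$layers[[code]]
    v[!env$land_mask] <- NA
    write_ascii_grid(v, env$grid, file.path(dir, paste0(code, ".asc")))
  }
  yaml::write_yaml(list(scenario_label = env$scenario_label,
                        group = as.list(env$group)),
                   file.path(dir, "stack.yml"))
  invisible(dir)
}

#' Read an environmental stack from ASCII grid files
#'
#' All layers must share one grid; a mismatch aborts listing the offending
#' files. NODATA cells (shared across layers) become the off-land mask.
#'
#' @param paths Character vector of `.asc` paths, or a directory written by
#'   [write_rasters()].
#' @param group Named group vector; inferred from `stack.yml` when reading a
#'   directory, otherwise required.
#' @param scenario_label Scenario label (default from `stack.yml` or
#'   `"current"`).
#' @return An [env_stack()].
#' @export
read_rasters <- function(paths, group = NULL, scenario_label = NULL) {
  if (length(paths) == 1 && dir.exists(paths)) {
    meta_path <- file.path(paths, "stack.yml")
    if (file.exists(meta_path)) {
      meta <- yaml::read_yaml(meta_path)
      if (is.null(group)) group <- unlist(meta$group)
      if (is.null(scenario_label)) scenario_label <- meta$scenario_label
    }
    paths <- sort(list.files(paths, pattern = "\\.asc$", full.names = TRUE))
  }
  if (!length(paths)) stop("no raster files to read")
  codes <- sub("\\.asc$", "", basename(paths))
  rasters <- lapply(paths, read_ascii_grid)
  grid <- rasters[[1]]$grid
  bad <- codes[!vapply(rasters, function(r) grid_equal(r$grid, grid), logical(1))]
  if (length(bad)) stop("grid mismatch across layers: ", paste(bad, collapse = ", "))
  layers <- lapply(rasters, `[[`, "values")
  names(layers) <- codes
  land <- Reduce(`&`, lapply(layers, function(m) !is.na(m)))
  if (is.null(group))
    stop("group tags required (none supplied and no stack.yml found)")
  env_stack(grid, layers, group, scenario_label = scenario_label %||% "current",
            land_mask = land)
}

#' Read a pipeline configuration file
#'
#' YAML file mirroring the argument list of [run_pipeline()]; see the
#' package vignette for the schema. Thresholds default to the standard
#' settings (0.7 collinearity, TSS 0.6 / AUC 0.8 screening, 70/30 splits,
#' 1000-pseudo-absence rule, 10 km thinning, 5 km uncertainty).
#'
#' @param path YAML file path.
#' @return A named list suitable for `do.call(run_pipeline, ...)`.
#' @export
read_run_config <- function(path) yaml::read_yaml(path)
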