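# Environmental predictor stacks: named layers on a shared grid, each tagged
# with a predictor group (climate / anthropogenic / topographic).

PREDICTOR_GROUPS <- c("climate", "anthropogenic", "topographic")

# Default predictor codes mirroring the standard 31-predictor layout:
# 19 bioclimatic variables, 9 anthropogenic-disturbance layers (8 land-use
# fractions + population density), 3 topographic layers.
default_codes <- function() {
  list(
    climate = paste0("B", 1:19),
    anthropogenic = c("CR", "PA", "PN", "PO", "PR", "RA", "SF", "SN", "UR"),
    topographic = c("AS", "EL", "SL"))
}

#' Construct an environmental predictor stack
#'
#' @param grid A [grid_spec()].
#' @param layers Named list of `n_rows x n_cols` matrices, one per predictor.
#' @param group Named character vector mapping each predictor code to one of
#'   `"climate"`, `"anthropogenic"`, `"topographic"`.
#' @param scenario_label Scenario name (e.g. `"current"`).
#' @param land_mask Logical matrix; `TRUE` marks land cells. Default all land.
#' @return An `env_stack` object.
#' @export
env_stack <- function(grid, layers, group, scenario_label = "current",
                      land_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.list(layers), length(layers) > 0)
  codes <- names(layers)
  if (is.null(codes) || anyDuplicated(codes)) stop("layers must have unique names")
  if (!all(codes %in% names(group))) stop("every layer needs a group tag")
  if (!all(group[codes] %in% PREDICTOR_GROUPS))
    stop("groups must be climate/anthropogenic/topographic")
  if (is.null(land_mask)) land_mask <- matrix(TRUE, grid$n_rows, grid$n_cols)
  for (code in codes) {
    m <- layers[[code]]
    if (!is.matrix(m) || nrow(m) != grid$n_rows || ncol(m) != grid$n_cols)
      stop("layer '", code, "' does not match the grid")
    if (any(!is.finite(m[land_mask]))) stop("layer '", code, "' has non-finite land values")
  }
  structure(
    list(grid = grid, layers = layers, group = group[codes],
         scenario_label = scenario_label, land_mask = land_mask),
    class = "env_stack")
}

#' @export
print.env_stack <- function(x, ...) {
  tab <- table(factor(x$group, levels = PREDICTOR_GROUPS))
  cat(sprintf("env_stack '%s': %d layers (%s) on %d x %d grid, %d land cells\n",
              x$scenario_label, length(x$layers),
              paste(sprintf("%d %s", tab, names(tab)), collapse = ", "),
              x$grid$n_rows, x$grid$n_cols, sum(x$land_mask)))
  invisible(x)
}

#' Extract predictor values at grid cells
#'
#' @param env An [env_stack()].
#' @param linear Column-major cell indices (see [cell_index()]).
#' @param codes Predictor codes to extract (default all layers).
#' @return Data frame with one column per code, one row per cell.
#' @export
extract_cells <- function(env, linear, codes = names(env$layers)) {
  out <- lapply(env$layers[codes], function(m) m[linear])
  as.data.frame(out, optional = TRUE, check.names = FALSE)
}

# predictor table over all land cells, plus the linear indices used
land_table <- function(env, codes = names(env$layers)) {
  linear <- which(env$land_mask)
  list(values = extract_cells(env, linear, codes), linear = linear)
}

#' Derive a future scenario by shifting predictor layers
#'
#' Applies additive and/or multiplicative deltas to selected layers of a
#' stack, leaving every other layer, the grid and the land mask untouched.
#' This emulates a future climate/land-use scenario (e.g. a uniform +2 degree
#' warming of a temperature layer).
#'
#' @param env An [env_stack()].
#' @param shifts Named list: for each predictor code either a single number
#'   (additive shift) or a list with elements `add` and/or `mul`
#'   (`x' = x * mul + add`).
#' @param label Scenario label for the derived stack.
#' @return A new `env_stack` with `scenario_label = label`.
#' @examples
#' # +2 on layer B1, 10% increase of B12:
#' # make_future_scenario(env, list(B1 = 2, B12 = list(mul = 1.1)), "F585")
#' @export
make_future_scenario <- function(env, shifts, label) {
  stopifnot(inherits(env, "env_stack"), is.character(label))
  if (length(shifts)) {
    missing <- setdiff(names(shifts), names(env$layers))
    if (length(missing)) stop("shifted predictors not in stack: ",
                              paste(missing, collapse = ", "))
  }
  layers <- env$layers
  for (code in names(shifts)) {
    s <- shifts[[code]]
    if (is.numeric(s) && length(s) == 1) s <- list(add = s)
    add <- if (is.null(s$add)) 0 else s$add
    mul <- if (is.null(s$mul)) 1 else s$mul
    layers[[code]] <- layers[[code]] * mul + add
  }
  env_stack(env$grid, layers, env$group, scenario_label = label,
            land_mask = env$land_mask)
}
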