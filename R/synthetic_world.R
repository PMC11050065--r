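# Synthetic virtual world: spatially autocorrelated predictor fields,
# virtual species with known Gaussian niches, presence sampling, and
# shifted future scenarios. Everything is a pure function of (args, seed).

# Separable Gaussian smoothing of a matrix, sigma in cells. Edge effects are
# handled by renormalizing the truncated kernel, so means are preserved.
smooth_field <- function(m, sigma) {
  if (sigma <= 0) return(m)
  band <- function(n) {
    idx <- seq_len(n)
    w <- exp(-outer(idx, idx, "-")^2 / (2 * sigma^2))
    w[abs(outer(idx, idx, "-")) > ceiling(3 * sigma)] <- 0
    w / rowSums(w)
  }
  band(nrow(m)) %*% m %*% t(band(ncol(m)))
}

standardize_land <- function(m, land) {
  v <- m[land]
  s <- stats::sd(v)
  if (s == 0) return(m - mean(v))
  (m - mean(v)) / s
}

#' Generate a synthetic environmental predictor stack
#'
#' Each layer is white noise convolved with an isotropic Gaussian kernel of
#' length `autocorr_length` (degrees), then standardized to mean 0 and unit
#' standard deviation over land cells. Requested predictor pairs are given an
#' exact sample Pearson correlation by orthogonalizing and remixing the two
#' fields. Layer codes follow the standard 31-predictor layout: bioclimatic
#' B1-B19 (climate), land-use fractions and population density
#' CR/PA/PN/PO/PR/RA/SF/SN/UR (anthropogenic), and AS/EL/SL (topographic).
#'
#' @param grid A [grid_spec()].
#' @param n_per_group Integer vector `c(climate, anthropogenic, topographic)`
#'   giving layer counts per group; default `c(19, 9, 3)`.
#' @param autocorr_length Spatial autocorrelation length in degrees (> 0).
#' @param corr_pairs Optional list of `list(a = codeA, b = codeB, r = target)`
#'   entries; layer `b` is remixed so that `cor(a, b)` over land equals `r`.
#' @param seed Integer seed; the stack is a pure function of arguments + seed.
#' @param land_mask Optional logical matrix; default all land.
#' @return An [env_stack()] labelled `"current"`.
#' @export
make_env_stack <- function(grid, n_per_group = c(19, 9, 3),
                           autocorr_length = 5, corr_pairs = list(),
                           seed = 1, land_mask = NULL) {
  stopifnot(inherits(grid, "grid_spec"), length(n_per_group) == 3)
  if (autocorr_length <= 0) stop("autocorr_length must be > 0")
  defaults <- default_codes()
  codes <- character(0); group <- character(0)
  prefixes <- c(climate = "B", anthropogenic = "H", topographic = "T")
  for (i in seq_along(PREDICTOR_GROUPS)) {
    g <- PREDICTOR_GROUPS[i]; n <- n_per_group[i]
    if (n == 0) next
    base <- defaults[[g]]
    code_g <- if (n <= length(base)) base[seq_len(n)] else
      c(base, paste0(prefixes[g], seq.int(length(base) + 1, n)))
    codes <- c(codes, code_g)
    group <- c(group, stats::setNames(rep(g, n), code_g))
  }
  if (anyDuplicated(codes)) stop("duplicate predictor codes")
  if (is.null(land_mask)) land_mask <- matrix(TRUE, grid$n_rows, grid$n_cols)

  set.seed(seed)
  sigma <- autocorr_length / grid$resolution
  layers <- lapply(codes, function(code) {
    f <- smooth_field(matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols),
                      sigma)
    standardize_land(f, land_mask)
  })
  names(layers) <- codes

  for (p in corr_pairs) {
    if (!all(c(p$a, p$b) %in% codes))
      stop("corr_pairs names a predictor not in the stack")
    if (abs(p$r) >= 1) stop("|target_r| must be < 1")
    a <- layers[[p$a]]; b <- layers[[p$b]]
    c_ab <- stats::cor(a[land_mask], b[land_mask])
    b_res <- standardize_land(b - c_ab * a, land_mask)
    layers[[p$b]] <- p$r * a + sqrt(1 - p$r^2) * b_res
  }

  env_stack(grid, layers, group, scenario_label = "current", land_mask = land_mask)
}

#' Generate a blobby land mask for masked-arithmetic tests
#'
#' Thresholds a smoothed Gaussian field so that roughly `fraction` of cells
#' are land.
#'
#' @inheritParams make_env_stack
#' @param fraction Target land fraction in (0, 1].
#' @return Logical matrix (`TRUE` = land).
#' @export
make_land_mask <- function(grid, fraction = 0.7, autocorr_length = 5, seed = 1) {
  stopifnot(fraction > 0, fraction <= 1)
  if (fraction == 1) return(matrix(TRUE, grid$n_rows, grid$n_cols))
  set.seed(seed)
  f <- smooth_field(matrix(stats::rnorm(n_cells(grid)), grid$n_rows, grid$n_cols),
                    autocorr_length / grid$resolution)
  f >= stats::quantile(f, 1 - fraction)
}

#' Define a virtual species by its environmental niche
#'
#' The species responds to each niche predictor with a Gaussian
#' (bell-shaped) curve `exp(-(x - opt)^2 / (2 * breadth^2))`; per-cell
#' responses are multiplied and passed through a monotone link to give an
#' occurrence probability in \[0, 1\].
#'
#' @param name Species name.
#' @param niche Data frame with columns `code`, `opt`, `breadth` (breadth > 0).
#' @param link `"identity"` or `"logistic"`. The logistic link
#'   `plogis(slope * (raw - midpoint))` sharpens the raw product into a more
#'   binary suitability surface, the usual virtual-species convention.
#' @param slope,midpoint Logistic link parameters.
#' @param prevalence_target Optional fraction; see [calibrate_species()].
#' @return A `virtual_species` object.
#' @export
virtual_species <- function(name, niche, link = c("logistic", "identity"),
                            slope = 10, midpoint = 0.5, prevalence_target = NULL) {
  link <- match.arg(link)
  stopifnot(is.data.frame(niche), all(c("code", "opt", "breadth") %in% names(niche)))
  if (any(niche$breadth <= 0)) stop("niche breadth must be > 0")
  structure(list(name = name, niche = niche, link = link, slope = slope,
                 midpoint = midpoint, prevalence_target = prevalence_target),
            class = "virtual_species")
}

#' Calibrate a species' logistic midpoint to a target prevalence
#'
#' Sets the logistic midpoint to the `(1 - prevalence)` quantile of the raw
#' niche response over land cells of a reference stack, so that roughly
#' `prevalence` of the landscape has suitability above 0.5. The link then
#' stays fixed across scenarios.
#'
#' @param sp A [virtual_species()].
#' @param env Reference [env_stack()] (normally the current scenario).
#' @param prevalence Target fraction; defaults to `sp$prevalence_target`.
#' @return The species with an updated `midpoint`.
#' @export
calibrate_species <- function(sp, env, prevalence = sp$prevalence_target) {
  stopifnot(!is.null(prevalence), prevalence > 0, prevalence < 1)
  raw <- raw_niche_response(sp, env)
  sp$midpoint <- as.numeric(stats::quantile(raw[env$land_mask], 1 - prevalence))
  sp
}

raw_niche_response <- function(sp, env) {
  missing <- setdiff(sp$niche$code, names(env$layers))
  if (length(missing)) stop("niche predictors absent from stack: ",
                            paste(missing, collapse = ", "))
  raw <- matrix(1, env$grid$n_rows, env$grid$n_cols)
  for (i in seq_len(nrow(sp$niche))) {
    x <- env$layers[[sp$niche$code[i]]]
    raw <- raw * exp(-(x - sp$niche$opt[i])^2 / (2 * sp$niche$breadth[i]^2))
  }
  raw
}

#' True occurrence probability of a virtual species on a stack
#'
#' @param sp A [virtual_species()].
#' @param env An [env_stack()] containing the niche predictors.
#' @return A [suitability_map()] of the known (noise-free) suitability.
#' @export
true_suitability <- function(sp, env) {
  raw <- raw_niche_response(sp, env)
  vals <- switch(sp$link,
    identity = raw,
    logistic = stats::plogis(sp$slope * (raw - sp$midpoint)))
  vals[!env$land_mask] <- NA_real_
  suitability_map(env$grid, vals, species = sp$name,
                  scenario_label = env$scenario_label)
}

#' Sample presence records of a virtual species
#'
#' Cells are drawn (with replacement) with probability proportional to
#' true suitability times an optional sampling-effort layer; each record is
#' placed at its cell center.
#'
#' @param sp A [virtual_species()].
#' @param env An [env_stack()].
#' @param n Number of presence records (>= 1).
#' @param effort_bias Optional non-negative effort matrix.
#' @param seed Integer seed.
#' @return An [occurrence_set()].
#' @export
sample_occurrences <- function(sp, env, n, effort_bias = NULL, seed = 1) {
  stopifnot(n >= 1)
  suit <- true_suitability(sp, env)$values
  w <- suit
  if (!is.null(effort_bias)) w <- w * effort_bias
  land <- which(env$land_mask)
  pw <- w[land]
  pw[!is.finite(pw)] <- 0
  if (all(pw <= 0)) stop("suitability (x effort) is zero everywhere on land")
  set.seed(seed)
  cells <- sample(land, n, replace = TRUE, prob = pw)
  ctr <- cell_centers(env$grid)
  row <- ((cells - 1L) %% env$grid$n_rows) + 1L
  col <- ((cells - 1L) %/% env$grid$n_rows) + 1L
  occurrence_set(species = sp$name, lon = ctr$lon[col], lat = ctr$lat[row])
}
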