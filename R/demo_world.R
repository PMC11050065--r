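# A canonical synthetic experiment: one current predictor stack, four
# future scenarios (two forcing levels x two GCM-like shift patterns), and
# a community of virtual species with Gaussian niches. These defaults are
# the package's reference study conditions; the vignette discusses them.

# Scenario shift patterns. Layers are on a standardized (z-score) scale, so
# a shift of 1 is one landscape standard deviation. Warming moves the
# temperature-linked bioclim layers coherently; the pessimistic scenarios
# also dry the precipitation layers and urbanize.
demo_shifts <- function() {
  warm <- function(d) list(B1 = d, B5 = d, B6 = d, B8 = d, B9 = d, B10 = d, B11 = d)
  dry <- function(d) list(B12 = d, B13 = d, B16 = d, B17 = d)
  list(
    F126 = warm(0.35),
    F585 = c(warm(1.1), dry(-0.35), list(UR = 0.3)),
    M126 = c(warm(0.5), dry(0.15)),
    M585 = c(warm(1.3), dry(-0.45), list(UR = 0.4)))
}

#' Build the reference synthetic experiment
#'
#' Generates a current predictor stack (31 layers: 19 climate, 9
#' anthropogenic, 3 topographic, with a few planted collinear pairs to
#' exercise pruning), four future scenarios (`F126`, `F585`, `M126`,
#' `M585`: mild/strong coherent warming under two shift patterns, the
#' strong ones with drying and urbanization), and `n_species` virtual
#' species. Each species responds to 2-3 randomly chosen climate or
#' anthropogenic predictors with Gaussian niches (optima ~ N(0, 1), breadths
#' uniform in 0.4-0.7) through the logistic link.
#'
#' @param n_species Number of virtual species (default 15).
#' @param grid A [grid_spec()]; default 50 x 70 cells at 1 degree.
#' @param autocorr_length Field autocorrelation length in degrees (default 5).
#' @param seed Integer seed.
#' @return List with `stacks` (named list of 5 [env_stack()]s, first
#'   `"current"`) and `species` (list of [virtual_species()]).
#' @export
make_demo_world <- function(n_species = 15,
                            grid = grid_spec(-35, 35, -10, 40, resolution = 1),
                            autocorr_length = 5, seed = 1) {
  corr_pairs <- list(list(a = "B1", b = "B11", r = 0.85),
                     list(a = "B12", b = "B16", r = 0.9),
                     list(a = "B5", b = "B10", r = 0.8))
  current <- make_env_stack(grid, c(19, 9, 3), autocorr_length = autocorr_length,
                            corr_pairs = corr_pairs, seed = seed)
  stacks <- c(list(current = current),
              lapply(demo_shifts(), function(sh) NULL))
  for (lab in names(demo_shifts()))
    stacks[[lab]] <- make_future_scenario(current, demo_shifts()[[lab]], lab)

  # niche predictors: mostly climate, occasionally anthropogenic (the noise
  # topographic layer AS stays out of every niche, as a known irrelevant one)
  pool <- c(paste0("B", 1:19), "PO", "UR", "CR")
  set.seed(seed + 1)
  species <- lapply(seq_len(n_species), function(i) {
    k <- sample(2:3, 1)
    codes <- sample(pool, k)
    # optima stay within the commonly observed range of the standardized
    # fields (+-1.2 sd): a species whose optimum is absent from the
    # landscape has an unrecoverable (truncated) niche
    virtual_species(sprintf("vsp%02d", i),
                    data.frame(code = codes,
                               opt = stats::runif(k, -1.2, 1.2),
                               breadth = stats::runif(k, 0.5, 0.8)),
                    link = "logistic", slope = 15, midpoint = 0.5)
  })
  list(stacks = stacks, species = species)
}
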