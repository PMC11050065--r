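# Shared fixtures, built in code and cached for the test session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_grid <- function(resolution = 1) grid_spec(-20, 20, 0, 30, resolution = resolution)

# a 31-layer world shared by selection/ensemble tests
test_env <- function() cached("env31",
  make_env_stack(test_grid(), c(19, 9, 3), autocorr_length = 5, seed = 1))

test_species <- function() virtual_species(
  "testsp", data.frame(code = c("B1", "B12"), opt = c(0.5, -0.3),
                       breadth = c(0.5, 0.7)),
  link = "logistic", slope = 15, midpoint = 0.5)

# training table for the test species on the shared world
test_table <- function() cached("table", {
  env <- test_env()
  occ <- spatial_thin(sample_occurrences(test_species(), env, 300, seed = 42),
                      10, seed = 7)
  pres_vals <- extract_cells(env, cell_index(env$grid, occ$lon, occ$lat)$linear)
  pa <- generate_pseudo_absences(env, occ, fit_envelope(pres_vals, 0.025), seed = 8)
  build_training_table(env, occ, pa)
})

# single-layer stack with explicit values, for closed-form checks
manual_env <- function(values, code = "B1", group = "climate") {
  g <- grid_spec(0, ncol(values), 0, nrow(values), resolution = 1)
  env_stack(g, stats::setNames(list(values), code),
            stats::setNames(group, code))
}
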