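# cell-enumeration oracle for the range decomposition and indices
dynamics_oracle <- function(cur, fut, areas) {
  SR <- 0; exp_ <- 0; con <- 0
  for (i in seq_along(cur)) {
    c_i <- isTRUE(cur[i]); f_i <- isTRUE(fut[i])
    if (c_i && f_i) SR <- SR + areas[i]
    else if (f_i) exp_ <- exp_ + areas[i]
    else if (c_i) con <- con + areas[i]
  }
  RCS <- SR + con; RFS <- SR + exp_
  list(SR = SR, expansion = exp_, contraction = con, RCS = RCS, RFS = RFS,
       RRI = if (RCS > 0) RFS / RCS else NA_real_,
       RSI = if (RCS + RFS > 0) 2 * SR / (RCS + RFS) else NA_real_)
}

row_map <- function(presence, grid, label = "x") {
  binary_range_map(grid, matrix(presence, nrow = grid$n_rows), 0.5,
                   species = "sp", scenario_label = label)
}

test_that("binarization applies >= tau on land", {
  vals <- matrix(c(0.1, 0.5, 0.9, 0.4, 0.5, NA, 0, 1, 0.2), 3, 3)
  m <- suitability_map(grid_spec(0, 3, 0, 3, resolution = 1), vals)
  b <- binarize(m, 0.5)
  expect_equal(b$presence, vals >= 0.5)
  expect_equal(b$threshold_used, 0.5)
  expect_true(all(binarize(m, 0)$presence[!is.na(vals)]))
  expect_false(any(binarize(m, 1 + 1e-9)$presence, na.rm = TRUE))
})

test_that("range dynamics reproduce the set-counting identities", {
  g <- grid_spec(0, 70, 0, 1, resolution = 1) # single row: equal cell areas
  A <- cell_areas(g)[1]
  cur <- rep(FALSE, 70); fut <- rep(FALSE, 70)
  cur[1:40] <- TRUE           # 30 stable + 10 contraction
  fut[c(1:30, 41:60)] <- TRUE # 30 stable + 20 expansion
  d <- range_dynamics(row_map(cur, g, "current"), row_map(fut, g, "future"))
  expect_equal(d$SR, 30 * A)
  expect_equal(d$expansion, 20 * A)
  expect_equal(d$contraction, 10 * A)
  expect_equal(d$RCS, 40 * A)
  expect_equal(d$RFS, 50 * A)
  expect_equal(d$RRI, 1.25)
  expect_equal(d$RSI, 60 / 90)

  same <- range_dynamics(row_map(cur, g), row_map(cur, g))
  expect_equal(same$RRI, 1)
  expect_equal(same$RSI, 1)

  disjoint <- range_dynamics(row_map(c(rep(TRUE, 20), rep(FALSE, 50)), g),
                             row_map(c(rep(FALSE, 20), rep(TRUE, 20), rep(FALSE, 30)), g))
  expect_equal(disjoint$RRI, 1)
  expect_equal(disjoint$RSI, 0)

  empty <- row_map(rep(FALSE, 70), g)
  expect_warning(u <- range_dynamics(empty, row_map(fut, g)), "RCS = 0")
  expect_true(is.na(u$RRI))
  w <- capture_warnings(z <- range_dynamics(empty, empty))
  expect_match(w, "RCS = 0", all = FALSE)
  expect_match(w, "RSI undefined", all = FALSE)
  expect_true(is.na(z$RSI))
})

test_that("dynamics match the cell-enumeration oracle on random grids", {
  for (k in 1:25) {
    set.seed(k)
    nr <- sample(2:50, 1); nc <- sample(2:50, 1)
    lat0 <- runif(1, -60, 30)
    g <- grid_spec(0, nc * 0.5, lat0, lat0 + nr * 0.5, resolution = 0.5)
    cur <- matrix(runif(nr * nc) < 0.4, nr, nc)
    fut <- matrix(runif(nr * nc) < 0.4, nr, nc)
    d <- suppressWarnings(range_dynamics(
      binary_range_map(g, cur, 0.5, scenario_label = "current"),
      binary_range_map(g, fut, 0.5, scenario_label = "future")))
    areas <- matrix(cell_areas(g), nr, nc)
    o <- dynamics_oracle(cur, fut, areas)
    for (f in c("SR", "expansion", "contraction", "RCS", "RFS", "RRI", "RSI"))
      expect_equal(d[[f]], o[[f]], tolerance = 1e-12)

    # partition: SR + expansion + contraction + untouched = total area
    untouched <- sum(areas[!cur & !fut])
    expect_equal(d$SR + d$expansion + d$contraction + untouched, sum(areas),
                 tolerance = 1e-9)
    # symmetry / reciprocity
    rev_d <- suppressWarnings(range_dynamics(
      binary_range_map(g, fut, 0.5), binary_range_map(g, cur, 0.5)))
    expect_equal(rev_d$RSI, d$RSI)
    if (!is.na(d$RRI) && !is.na(rev_d$RRI) && d$RRI > 0)
      expect_equal(rev_d$RRI, 1 / d$RRI)
    if (!is.na(d$RSI)) { expect_gte(d$RSI, 0); expect_lte(d$RSI, 1) }
  }
})

test_that("adding a future-only cell weakly increases RRI", {
  g <- grid_spec(0, 30, 10, 11, resolution = 1)
  cur <- rep(c(TRUE, FALSE), 15)
  fut <- cur
  d0 <- range_dynamics(row_map(cur, g), row_map(fut, g))
  fut2 <- fut; fut2[2] <- TRUE
  d1 <- range_dynamics(row_map(cur, g), row_map(fut2, g))
  expect_gte(d1$RRI, d0$RRI)
})

test_that("overlays count presences additively", {
  g <- grid_spec(0, 10, 0, 10, resolution = 1)
  set.seed(9)
  maps <- lapply(1:15, function(i)
    binary_range_map(g, matrix(runif(100) < 0.3, 10, 10), 0.5))
  ov <- overlay_counts(maps)
  naive <- Reduce(`+`, lapply(maps, function(m) m$presence * 1L))
  expect_equal(ov$counts, naive)
  expect_lte(max(ov$counts), 15)

  one <- overlay_counts(maps[1])
  expect_equal(one$counts, maps[[1]]$presence * 1L)

  comp <- binary_range_map(g, !maps[[1]]$presence, 0.5)
  expect_true(all(overlay_counts(list(maps[[1]], comp))$counts == 1))

  g2 <- grid_spec(0, 5, 0, 5, resolution = 1)
  expect_error(overlay_counts(list(maps[[1]],
    binary_range_map(g2, matrix(TRUE, 5, 5), 0.5))), "grid")
})

test_that("total suitability sums per cell and differencing books areas", {
  g <- grid_spec(0, 4, 0, 1, resolution = 1)
  mk <- function(v) suitability_map(g, matrix(v, 1, 4))
  tot1 <- total_suitability(list(mk(c(0.2, 0.4, 0.6, 0.8))))
  expect_equal(tot1$values, matrix(c(0.2, 0.4, 0.6, 0.8), 1, 4))

  maps15 <- replicate(15, mk(rep(1, 4)), simplify = FALSE)
  expect_equal(unique(as.vector(total_suitability(maps15)$values)), 15)

  set.seed(4)
  rmaps <- replicate(6, mk(runif(4)), simplify = FALSE)
  expect_equal(total_suitability(rmaps)$values,
               Reduce(`+`, lapply(rmaps, `[[`, "values")))

  # toy 4-cell deltas {+, -, 0, +}
  a <- total_suitability(list(mk(c(0.5, 0.5, 0.5, 0.5))))
  b <- total_suitability(list(mk(c(0.7, 0.3, 0.5, 0.6))))
  ch <- suitability_change(b, a)
  A <- cell_areas(g)[1]
  expect_equal(ch$increased_area, 2 * A)
  expect_equal(ch$decreased_area, 1 * A)

  same <- suitability_change(a, a)
  expect_equal(same$increased_area, 0)
  expect_equal(same$decreased_area, 0)

  up <- total_suitability(list(mk(c(0.5, 0.5, 0.5, 0.5) + 0.1)))
  expect_equal(suitability_change(up, a)$increased_area, 4 * A)
})

test_that("scenario summaries average, rank and test paired differences", {
  d <- data.frame(
    species = rep(c("s1", "s2", "s3"), 2),
    scenario = rep(c("F1", "F2"), each = 3),
    RRI = c(1.0, 2.0, 3.0, 1.5, 2.5, 3.5),
    RSI = c(0.9, 0.5, 0.7, 0.8, 0.4, 0.6),
    RFS = c(5, 10, 15, 6, 12, 18))
  s <- summarize_scenarios(d, contrasts = list(c("F1", "F2")), top_k = 2)
  expect_equal(s$means$mean_RRI[s$means$scenario == "F1"], 2)
  expect_equal(s$means$report_RSI[s$means$scenario == "F2"], 0.6)
  expect_equal(s$rankings$F1$largest_rri$species, c("s3", "s2"))
  expect_equal(s$rankings$F2$smallest_rsi$species, c("s2", "s3"))
  expect_equal(s$rankings$F1$largest_range$species, c("s3", "s2"))
  tt <- s$tests[s$tests$index == "RRI", ]
  # constant difference of -0.5 across species: degenerate paired t
  expect_lt(tt$t, 0)
  expect_lt(tt$p_value, 0.01)
  # identical vectors must give t = 0
  d2 <- d; d2$RRI[d2$scenario == "F2"] <- d2$RRI[d2$scenario == "F1"]
  d2$RSI[d2$scenario == "F2"] <- d2$RSI[d2$scenario == "F1"]
  s2 <- summarize_scenarios(d2, contrasts = list(c("F1", "F2")))
  expect_equal(s2$tests$t, c(0, 0))
  expect_equal(s2$tests$p_value, c(1, 1))

  # unbalanced species are excluded pairwise with a warning
  d3 <- rbind(d, data.frame(species = "s4", scenario = "F1", RRI = 9, RSI = 0.1,
                            RFS = 1))
  expect_warning(s3 <- summarize_scenarios(d3, contrasts = list(c("F1", "F2"))),
                 "excluded")
  expect_equal(unique(s3$tests$n_pairs), 3)
})
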