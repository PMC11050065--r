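# brute-force metric oracles
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}
tss_oracle <- function(pres, abs_, tau) {
  tp <- sum(pres >= tau); fn <- sum(pres < tau)
  fp <- sum(abs_ >= tau); tn <- sum(abs_ < tau)
  tp / (tp + fn) + tn / (tn + fp) - 1
}
mss_oracle <- function(pres, abs_) {
  cand <- sort(unique(c(pres, abs_)))
  sums <- sapply(cand, function(t) mean(pres >= t) + mean(abs_ < t))
  cand[sums == max(sums)][1]
}

test_that("envelopes are presence quantile boxes", {
  set.seed(2)
  vals <- data.frame(a = rnorm(20), b = runif(20))
  e0 <- fit_envelope(vals, q = 0)
  expect_equal(e0$lower, c(a = min(vals$a), b = min(vals$b)))
  expect_equal(e0$upper, c(a = max(vals$a), b = max(vals$b)))

  # sort-based interpolation oracle (n - 1 spacing)
  e <- fit_envelope(vals, q = 0.025)
  h <- (20 - 1) * 0.025
  x <- sort(vals$a)
  expect_equal(unname(e$lower["a"]),
               x[floor(h) + 1] + (h - floor(h)) * (x[floor(h) + 2] - x[floor(h) + 1]))

  same <- data.frame(a = rep(1.5, 6))
  ez <- fit_envelope(same, q = 0.025)
  expect_equal(unname(ez$lower["a"]), unname(ez$upper["a"]))
  expect_error(fit_envelope(vals[1:4, , drop = FALSE]), "5")
})

test_that("pseudo-absence counts follow the 1000-or-match rule", {
  # a grid with plenty of candidate cells outside the envelope
  env <- cached("env_big", make_env_stack(grid_spec(-35, 35, -10, 40, resolution = 1),
                                          c(12, 0, 0), autocorr_length = 5, seed = 4))
  sp <- test_species()
  occ500 <- sample_occurrences(sp, env, 500, seed = 1)
  pres_vals <- extract_cells(env, cell_index(env$grid, occ500$lon, occ500$lat)$linear)
  envp <- fit_envelope(pres_vals, 0.025)
  pa <- generate_pseudo_absences(env, occ500, envp, seed = 2)
  expect_equal(nrow(pa), 1000)

  pa_big <- generate_pseudo_absences(env, occ500, envp, seed = 2, n_pa = 1100)
  expect_equal(nrow(pa_big), 1100)

  # contract: each PA violates the envelope somewhere and is not a presence cell
  pa_cells <- cell_index(env$grid, pa$lon, pa$lat)$linear
  pres_cells <- cell_index(env$grid, occ500$lon, occ500$lat)$linear
  expect_length(intersect(pa_cells, pres_cells), 0)
  frac_inside <- rangedyn:::sre_score(envp, extract_cells(env, pa_cells))
  expect_true(all(frac_inside < 1))
  # deterministic given seed
  expect_identical(pa, generate_pseudo_absences(env, occ500, envp, seed = 2))
  expect_error(generate_pseudo_absences(env, occ500, envp, seed = 2, n_pa = 1e6),
               "shortfall")
})

test_that("tss follows its confusion-table definition", {
  expect_equal(tss(50, 0, 50, 0), 1)
  expect_equal(tss(50, 0, 0, 50), 0) # all-positive classifier
  expect_equal(tss(40, 10, 30, 20), 0.4)
  expect_error(tss(0, 0, 10, 5), "empty")
})

test_that("auc equals the Mann-Whitney pair probability", {
  expect_equal(auc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(auc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_equal(auc(c(0.9, 0.3, 0.7), c(1, 1, 0)), 0.5)
  expect_error(auc(c(1, 2), c(1, 1)), "class")
})

test_that("metrics match brute-force oracles and auc is rank-invariant", {
  for (k in 1:50) {
    set.seed(k)
    n <- sample(5:30, 1)
    labels <- c(1, 0, rbinom(n, 1, 0.5))
    scores <- round(runif(n + 2), 2) # rounding forces ties
    expect_equal(auc(scores, labels), auc_oracle(scores, labels))
    # monotone transform invariance
    expect_equal(auc(qlogis(pmin(pmax(scores, 0.01), 0.99)), labels),
                 auc(pmin(pmax(scores, 0.01), 0.99), labels))
    pres <- scores[labels == 1]; abs_ <- scores[labels == 0]
    tau <- mss_threshold(pres, abs_)
    expect_equal(tau, mss_oracle(pres, abs_))
    expect_equal(rangedyn:::tss_at(pres, abs_, tau), tss_oracle(pres, abs_, tau))
  }
})

test_that("mss threshold picks the smallest maximizer", {
  expect_equal(mss_threshold(c(0.8, 0.6), c(0.4, 0.2)), 0.6)
  # degenerate: identical score sets; every candidate ties at sens + spec = 1
  tau <- mss_threshold(c(0.3, 0.5), c(0.3, 0.5))
  expect_equal(tau, 0.3)
  expect_equal(rangedyn:::tss_at(c(0.3, 0.5), c(0.3, 0.5), tau), 0)
  expect_error(mss_threshold(numeric(0), 0.5), "non-empty")
})

test_that("evaluation hits the expected extremes and screening rule", {
  set.seed(3)
  sep <- data.frame(label = rep(c(1, 0), each = 100),
                    x = c(rnorm(100, 4), rnorm(100, -4)))
  e <- evaluate_algorithm("glm", sep, seed = 1)
  expect_equal(e$tss, 1)
  expect_equal(e$auc, 1)
  expect_true(e$included)

  null <- data.frame(label = rbinom(2000, 1, 0.5), x = rnorm(2000), y = rnorm(2000))
  e0 <- evaluate_algorithm("glm", null, seed = 2)
  expect_gt(e0$auc, 0.45); expect_lt(e0$auc, 0.55)
  expect_false(e0$included)

  # OR rule on the recorded means
  fake <- function(tss, auc) structure(list(algorithm = "x", tss = tss, auc = auc,
                                            included = tss > 0.6 || auc > 0.8),
                                       class = "model_evaluation")
  expect_true(fake(0.5, 0.85)$included)
  expect_true(fake(0.65, 0.7)$included)
  expect_false(fake(0.5, 0.75)$included)
  expect_false(fake(0.6, 0.8)$included) # strict inequalities
})

test_that("ensembles weight included members by TSS", {
  tab <- test_table()[, c("label", "B1", "B12")]
  fake <- function(alg, tss, auc, included) structure(
    list(algorithm = alg, tss = tss, auc = auc, included = included),
    class = "model_evaluation")

  ens <- build_ensemble(list(fake("glm", 0.8, 0.9, TRUE),
                             fake("cart", 0.6, 0.85, TRUE),
                             fake("proto", 0.5, 0.75, FALSE)), tab)
  w <- vapply(ens$members, `[[`, numeric(1), "weight")
  expect_equal(w, c(4 / 7, 3 / 7))
  expect_equal(sum(w), 1)
  expect_equal(vapply(ens$members, `[[`, character(1), "algorithm"),
               c("glm", "cart")) # excluded member absent

  one <- build_ensemble(list(fake("glm", 0.7, 0.9, TRUE)), tab)
  expect_equal(one$members[[1]]$weight, 1)

  expect_error(build_ensemble(list(fake("glm", 0.2, 0.6, FALSE)), tab), "screening")
})

test_that("projection is the weighted member mean, bounded per cell", {
  env <- test_env()
  tab <- test_table()[, c("label", "B1", "B12")]
  fake <- function(alg, tss) structure(
    list(algorithm = alg, tss = tss, auc = 0.9, included = TRUE),
    class = "model_evaluation")

  one <- build_ensemble(list(fake("glm", 0.9)), tab)
  m1 <- predict_map(one, env)
  glm_model <- get_algorithm("glm")$fit(tab)
  lt <- land_vals <- extract_cells(env, which(env$land_mask), c("B1", "B12"))
  direct <- get_algorithm("glm")$score(glm_model, land_vals)
  expect_equal(m1$values[env$land_mask], direct)

  # equal TSS: arithmetic mean of the two member maps
  two <- build_ensemble(list(fake("glm", 0.7), fake("cart", 0.7)), tab)
  m2 <- predict_map(two, env)
  cart_model <- get_algorithm("cart")$fit(tab)
  cart_scores <- get_algorithm("cart")$score(cart_model, land_vals)
  expect_equal(m2$values[env$land_mask], (direct + cart_scores) / 2)

  # three members, TSS {0.9, 0.7, 0.7}: explicit weighted-sum oracle on cells
  three <- build_ensemble(list(fake("glm", 0.9), fake("cart", 0.7),
                               fake("proto", 0.7)), tab)
  m3 <- predict_map(three, env)
  proto_scores <- get_algorithm("proto")$score(get_algorithm("proto")$fit(tab),
                                               land_vals)
  w <- c(0.9, 0.7, 0.7) / 2.3
  manual <- w[1] * direct + w[2] * cart_scores + w[3] * proto_scores
  pick <- seq(1, length(manual), length.out = 10)
  expect_equal(m3$values[env$land_mask][pick], manual[pick])
  # bounded by member min/max
  lo <- pmin(direct, cart_scores, proto_scores)
  hi <- pmax(direct, cart_scores, proto_scores)
  got <- m3$values[env$land_mask]
  expect_true(all(got >= lo - 1e-9 & got <= hi + 1e-9))

  env_missing <- env; env_missing$layers$B12 <- NULL
  expect_error(predict_map(three, env_missing), "B12")
})

test_that("algorithm aliases map to implemented families with a notice", {
  expect_message(a <- get_algorithm("rf"), "xgb")
  expect_equal(a$name, "xgb")
  expect_message(get_algorithm("maxent"), "glm")
  expect_error(get_algorithm("nope"), "unknown")
  expect_setequal(names(algorithm_registry()),
                  c("sre", "glm", "gam", "cart", "xgb", "proto"))
})
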