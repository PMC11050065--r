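# Ensemble SDM: surface range envelope, pseudo-absence generation,
# TSS/AUC/MSS evaluation with repeated 70/30 splits, screening at
# TSS > 0.6 or AUC > 0.8, TSS-proportional weighting, and projection.

#' Fit a surface range envelope to presence predictor values
#'
#' Per-predictor bounds are the `q` and `1 - q` quantiles of the presence
#' values (type-7 quantiles); `q = 0` gives the min/max envelope.
#'
#' @param presence_values Data frame of predictor values at presences (>= 5).
#' @param q Quantile trimmed from each tail (default 0.025).
#' @return An `envelope`: list with `lower` and `upper` named vectors.
#' @export
fit_envelope <- function(presence_values, q = 0.025) {
  stopifnot(nrow(presence_values) >= 5, q >= 0, q < 0.5)
  lower <- vapply(presence_values, function(x) stats::quantile(x, q, names = FALSE),
                  numeric(1))
  upper <- vapply(presence_values, function(x) stats::quantile(x, 1 - q, names = FALSE),
                  numeric(1))
  structure(list(lower = lower, upper = upper, q = q), class = "envelope")
}

# fraction of predictors inside the envelope, per row
sre_score <- function(envelope, newdata) {
  codes <- names(envelope$lower)
  inside <- vapply(codes, function(p)
    newdata[[p]] >= envelope$lower[p] & newdata[[p]] <= envelope$upper[p],
    logical(nrow(newdata)))
  if (nrow(newdata) == 1) inside <- matrix(inside, nrow = 1)
  rowMeans(inside)
}

#' Generate pseudo-absences outside a presence envelope
#'
#' Samples cells uniformly without replacement from land cells that (a) fall
#' outside the envelope in at least one predictor and (b) contain no presence
#' record. Following the usual ensemble-platform rule, 1000 pseudo-absences
#' are drawn when there are fewer than 1000 presences; otherwise the count
#' matches the number of presences.
#'
#' @param env An [env_stack()].
#' @param occ Presence [occurrence_set()].
#' @param envelope An envelope from [fit_envelope()].
#' @param seed Integer seed.
#' @param n_pa Optional override of the pseudo-absence count.
#' @return An [occurrence_set()] of pseudo-absence cell centers.
#' @export
generate_pseudo_absences <- function(env, occ, envelope, seed = 1, n_pa = NULL) {
  n_pres <- nrow(occ)
  if (is.null(n_pa)) n_pa <- if (n_pres < 1000) 1000 else n_pres
  land <- which(env$land_mask)
  vals <- extract_cells(env, land, names(envelope$lower))
  outside <- sre_score(envelope, vals) < 1
  pres_cells <- unique(cell_index(env$grid, occ$lon, occ$lat)$linear)
  candidates <- land[outside & !(land %in% pres_cells)]
  if (length(candidates) < n_pa)
    stop("only ", length(candidates), " candidate cells for ", n_pa,
         " pseudo-absences (shortfall ", n_pa - length(candidates), ")")
  set.seed(seed)
  cells <- sample(candidates, n_pa)
  ctr <- cell_centers(env$grid)
  row <- ((cells - 1L) %% env$grid$n_rows) + 1L
  col <- ((cells - 1L) %/% env$grid$n_rows) + 1L
  occurrence_set(species = attr(occ, "species"), lon = ctr$lon[col], lat = ctr$lat[row])
}

#' True skill statistic from a confusion table
#'
#' `TSS = sensitivity + specificity - 1 = tp/(tp+fn) + tn/(tn+fp) - 1`.
#'
#' @param tp,fn,tn,fp Confusion counts; both classes must be represented.
#' @return Value in \[-1, 1\].
#' @export
tss <- function(tp, fn, tn, fp) {
  if (tp + fn == 0 || tn + fp == 0) stop("tss undefined: a class is empty")
  tp / (tp + fn) + tn / (tn + fp) - 1
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a random positive outscores a random negative, with
#' ties counted 1/2: `(concordant + ties/2) / (n_pos * n_neg)`. Computed via
#' midranks, which is exactly the Mann-Whitney statistic.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return Value in \[0, 1\].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("auc undefined: a class is absent")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Threshold maximizing sensitivity + specificity (MSS)
#'
#' Candidates are the unique observed scores; presence is predicted iff
#' `score >= tau`. Among maximizers the smallest candidate is returned, so
#' the threshold is deterministic.
#'
#' @param presence_scores,absence_scores Non-empty numeric score vectors.
#' @return The MSS threshold.
#' @export
mss_threshold <- function(presence_scores, absence_scores) {
  if (!length(presence_scores) || !length(absence_scores))
    stop("both score vectors must be non-empty")
  cand <- sort(unique(c(presence_scores, absence_scores)))
  sums <- vapply(cand, function(tau)
    mean(presence_scores >= tau) + mean(absence_scores < tau), numeric(1))
  cand[which.max(sums)] # which.max takes the first (= smallest) maximizer
}

# TSS of scores at threshold tau (predict presence iff score >= tau)
tss_at <- function(presence_scores, absence_scores, tau) {
  tss(tp = sum(presence_scores >= tau), fn = sum(presence_scores < tau),
      tn = sum(absence_scores < tau), fp = sum(absence_scores >= tau))
}

# seeded label-stratified train/test split; retries if a side is single-class
stratified_split <- function(labels, train_frac, seed, max_attempts = 10) {
  for (attempt in 0:(max_attempts - 1)) {
    set.seed(seed + attempt)
    train <- unlist(lapply(split(seq_along(labels), labels), function(idx)
      sample(idx, max(1, round(train_frac * length(idx))))))
    test <- setdiff(seq_along(labels), train)
    if (length(unique(labels[train])) == 2 && length(unique(labels[test])) == 2)
      return(list(train = sort(unname(train)), test = test))
  }
  stop("could not produce a two-class split in ", max_attempts, " attempts")
}

#' Cross-validated evaluation of one algorithm
#'
#' Runs `n_splits` seeded label-stratified random splits with `train_frac`
#' of each class for fitting and the rest held out. On each split the AUC is
#' computed on the held-out scores, the MSS threshold is located on the
#' held-out scores, and the TSS is evaluated at that threshold; metrics are
#' averaged over splits. The algorithm is flagged `included` if mean
#' TSS > `tss_min` or mean AUC > `auc_min` (strict, OR rule).
#'
#' @param alg Algorithm name (see [algorithm_registry()]) or plugin.
#' @param table Training table with `label` + predictors.
#' @param n_splits Number of repeated splits (default 5).
#' @param train_frac Training fraction per class (default 0.7).
#' @param seed Integer seed.
#' @param tss_min,auc_min Screening thresholds (defaults 0.6 and 0.8).
#' @return A `model_evaluation`: algorithm name, mean `tss`/`auc`, per-split
#'   metrics, and the `included` flag.
#' @export
evaluate_algorithm <- function(alg, table, n_splits = 5, train_frac = 0.7,
                               seed = 1, tss_min = 0.6, auc_min = 0.8) {
  plugin <- if (is.character(alg)) get_algorithm(alg) else alg
  codes <- predictor_cols(table)
  per_split <- data.frame(split = seq_len(n_splits), tss = NA_real_,
                          auc = NA_real_, threshold = NA_real_)
  for (s in seq_len(n_splits)) {
    sp <- stratified_split(table$label, train_frac, seed = seed * 1000 + s)
    model <- plugin$fit(table[sp$train, , drop = FALSE])
    scores <- plugin$score(model, table[sp$test, codes, drop = FALSE])
    lab <- table$label[sp$test]
    tau <- mss_threshold(scores[lab == 1], scores[lab == 0])
    per_split$auc[s] <- auc(scores, lab)
    per_split$tss[s] <- tss_at(scores[lab == 1], scores[lab == 0], tau)
    per_split$threshold[s] <- tau
  }
  mean_tss <- mean(per_split$tss); mean_auc <- mean(per_split$auc)
  structure(list(algorithm = plugin$name, tss = mean_tss, auc = mean_auc,
                 per_split = per_split,
                 included = (mean_tss > tss_min) || (mean_auc > auc_min)),
            class = "model_evaluation")
}

#' @export
print.model_evaluation <- function(x, ...) {
  cat(sprintf("model_evaluation %s: TSS %.3f, AUC %.3f, %s\n", x$algorithm,
              x$tss, x$auc, if (x$included) "included" else "excluded"))
  invisible(x)
}

#' Assemble an ensemble from screened algorithm evaluations
#'
#' Keeps the included algorithms, refits each on the full table, and assigns
#' weights proportional to mean TSS (normalized to sum to 1).
#'
#' @param evals List of `model_evaluation`s.
#' @param table Full training table for the final refits.
#' @return An `ensemble_model`: list of members (`algorithm`, `model`,
#'   `weight`, `tss`) plus the retained predictor codes.
#' @export
build_ensemble <- function(evals, table) {
  stopifnot(length(evals) >= 1)
  kept <- Filter(function(e) e$included, evals)
  if (!length(kept))
    stop("no algorithm passed screening (TSS > 0.6 or AUC > 0.8); ",
         "review thresholds or training data")
  tss_v <- vapply(kept, `[[`, numeric(1), "tss")
  weights <- tss_v / sum(tss_v)
  members <- lapply(seq_along(kept), function(i) {
    plugin <- get_algorithm(kept[[i]]$algorithm)
    list(algorithm = kept[[i]]$algorithm, plugin = plugin,
         model = plugin$fit(table), weight = weights[i], tss = tss_v[i])
  })
  structure(list(members = members, codes = predictor_cols(table)),
            class = "ensemble_model")
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model:", length(x$members), "members\n")
  for (m in x$members)
    cat(sprintf("  %-6s weight %.3f (TSS %.3f)\n", m$algorithm, m$weight, m$tss))
  invisible(x)
}

# score an arbitrary predictor data.frame with the ensemble
ensemble_score <- function(ens, newdata) {
  out <- numeric(nrow(newdata))
  for (m in ens$members)
    out <- out + m$weight * m$plugin$score(m$model, newdata)
  clamp01(out)
}

#' Project an ensemble onto an environmental stack
#'
#' Per-cell TSS-weighted mean of member suitabilities over land cells.
#'
#' @param ens An [build_ensemble()] result.
#' @param env An [env_stack()] containing the retained predictors.
#' @return A [suitability_map()] for `env`'s scenario.
#' @export
predict_map <- function(ens, env) {
  missing <- setdiff(ens$codes, names(env$layers))
  if (length(missing)) stop("stack is missing predictor layer(s): ",
                            paste(missing, collapse = ", "))
  lt <- land_table(env, ens$codes)
  vals <- matrix(NA_real_, env$grid$n_rows, env$grid$n_cols)
  vals[lt$linear] <- ensemble_score(ens, lt$values)
  suitability_map(env$grid, vals, species = attr(env, "species") %||% "",
                  scenario_label = env$scenario_label)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
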