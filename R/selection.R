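# Predictor selection: jackknife (permutation) importance from a preliminary
# model, Pearson collinearity screening, and greedy pruning at |r| > 0.7.

#' Build a presence/pseudo-absence training table
#'
#' @param env An [env_stack()].
#' @param presences,absences [occurrence_set()]s; labels 1 and 0.
#' @param codes Predictor codes to extract (default all layers).
#' @return A data frame with a `label` column (1/0) followed by one column
#'   per predictor, values taken at each record's grid cell.
#' @export
build_training_table <- function(env, presences, absences,
                                 codes = names(env$layers)) {
  stopifnot(nrow(presences) >= 1, nrow(absences) >= 1)
  tab <- function(occ, label) {
    idx <- cell_index(env$grid, occ$lon, occ$lat)
    cbind(label = label, extract_cells(env, idx$linear, codes))
  }
  out <- rbind(tab(presences, 1L), tab(absences, 0L))
  if (anyNA(out)) stop("training table has missing predictor values (off-land records?)")
  rownames(out) <- NULL
  out
}

#' Jackknife (permutation) predictor importance
#'
#' Fits the model once on the full table, then for each predictor shuffles
#' that column and re-scores: the importance value is
#' `IV(p) = mean over permutations of (1 - cor(yhat_full, yhat_p_shuffled))`,
#' clipped at 0. Predictors the model ignores score ~0; predictors that drive
#' the predictions score high. A min-max standardized copy (`[0, 1]` across
#' predictors) is included for reporting.
#'
#' @param fit A fitting function `fit(table) -> model` with a matching
#'   `score(model, newdata) -> numeric`; see [algorithm_registry()]. May also
#'   be an algorithm name; the default `"cart"` (classification tree) gives
#'   sparse, stable importances — an unpenalized logistic preliminary model
#'   can suffer quasi-separation against envelope-based pseudo-absences,
#'   which spreads spurious importance over every predictor.
#' @param table A training table from [build_training_table()].
#' @param n_permutations Permutations per predictor (default 5).
#' @param seed Integer seed.
#' @return An `importance_report` list with `iv`, `iv_standardized`,
#'   `n_permutations`, `seed`.
#' @export
jackknife_importance <- function(fit = "cart", table, n_permutations = 5, seed = 1) {
  alg <- if (is.character(fit)) get_algorithm(fit) else fit
  codes <- setdiff(names(table), c("label", "weight"))
  model <- alg$fit(table)
  yhat <- alg$score(model, table[codes])
  iv <- stats::setNames(numeric(length(codes)), codes)
  if (stats::sd(yhat) == 0) {
    warning("constant predictions from the preliminary model; all IVs set to 0")
  } else {
    set.seed(seed)
    for (p in codes) {
      drops <- vapply(seq_len(n_permutations), function(k) {
        shuffled <- table[codes]
        shuffled[[p]] <- sample(shuffled[[p]])
        ys <- alg$score(model, shuffled)
        if (stats::sd(ys) == 0) 1 else 1 - stats::cor(yhat, ys)
      }, numeric(1))
      iv[p] <- max(0, mean(drops))
    }
  }
  rng <- range(iv)
  iv_std <- if (diff(rng) > 0) (iv - rng[1]) / diff(rng)
            else if (rng[2] > 0) iv * 0 + 1 # all tied at the max
            else iv * 0
  structure(list(iv = iv, iv_standardized = iv_std,
                 n_permutations = n_permutations, seed = seed),
            class = "importance_report")
}

#' @export
print.importance_report <- function(x, ...) {
  ord <- order(-x$iv)
  cat(sprintf("importance_report (%d predictors, %d permutations):\n",
              length(x$iv), x$n_permutations))
  print(round(x$iv[ord], 4))
  invisible(x)
}

#' Pairwise Pearson correlation matrix of a training table's predictors
#'
#' @param table A training table (the `label`/`weight` columns are ignored).
#' @return Symmetric matrix with unit diagonal. A zero-variance predictor
#'   gets 0 off-diagonal correlations, with a warning.
#' @export
pearson_matrix <- function(table) {
  codes <- setdiff(names(table), c("label", "weight"))
  x <- as.matrix(table[codes])
  if (nrow(x) < 3) stop("need at least 3 rows for correlations")
  sds <- apply(x, 2, stats::sd)
  degenerate <- sds == 0
  if (any(degenerate))
    warning("zero-variance predictor(s): ", paste(codes[degenerate], collapse = ", "),
            "; their correlations set to 0")
  r <- suppressWarnings(stats::cor(x))
  r[degenerate, ] <- 0; r[, degenerate] <- 0
  diag(r) <- 1
  r
}

#' Prune collinear predictors by importance dominance
#'
#' Greedy elimination: while any retained pair has `|r| > threshold`, take
#' the pair with the currently largest `|r|` and drop its member with the
#' lower raw importance value (ties: drop the later code in the matrix's
#' column order). The retained set therefore contains no pair above the
#' threshold and is maximal under this rule.
#'
#' @param corr Correlation matrix from [pearson_matrix()].
#' @param report An `importance_report` covering the same codes.
#' @param threshold Collinearity threshold (default 0.7, strict `>`).
#' @return Character vector of retained predictor codes (original order).
#' @export
prune_collinear <- function(corr, report, threshold = 0.7) {
  codes <- colnames(corr)
  stopifnot(all(codes %in% names(report$iv)))
  iv <- report$iv[codes]
  retained <- codes
  repeat {
    r <- abs(corr[retained, retained, drop = FALSE])
    diag(r) <- 0
    if (!length(r) || max(r) <= threshold) break
    ij <- which(r == max(r), arr.ind = TRUE)[1, ] # first = earliest pair
    a <- retained[ij[1]]; b <- retained[ij[2]]
    drop <- if (iv[a] < iv[b]) a
            else if (iv[b] < iv[a]) b
            else retained[max(ij)] # tie: later code in canonical order
    retained <- setdiff(retained, drop)
  }
  retained
}

#' Write an importance report as CSV
#'
#' @param report An `importance_report`.
#' @param group Named group vector (as in an [env_stack()]); optional.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(report, path, group = NULL) {
  codes <- names(report$iv)
  df <- data.frame(code = codes,
                   group = if (is.null(group)) NA_character_ else unname(group[codes]),
                   raw_iv = unname(report$iv),
                   standardized_iv = unname(report$iv_standardized))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
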