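# Pluggable algorithm registry. Each algorithm exposes
#   fit(table)            -> fitted model (table: label + predictor columns)
#   score(model, newdata) -> suitability in [0, 1] per row
# Six families are implemented; the remaining names commonly used by
# ensemble-SDM platforms are accepted as aliases of the closest family.

clamp01 <- function(x) pmin(pmax(x, 0), 1)

predictor_cols <- function(table) setdiff(names(table), c("label", "weight"))

alg_sre <- list(
  name = "sre",
  fit = function(table, q = 0.025) {
    fit_envelope(table[table$label == 1, predictor_cols(table), drop = FALSE], q = q)
  },
  score = function(model, newdata) sre_score(model, newdata))

alg_glm <- list(
  name = "glm",
  fit = function(table) {
    codes <- predictor_cols(table)
    # linear + quadratic terms, so bell-shaped responses are representable
    rhs <- paste(sprintf("%s + I(%s^2)", codes, codes), collapse = " + ")
    f <- stats::as.formula(paste("label ~", rhs))
    suppressWarnings(stats::glm(f, family = stats::binomial(),
                                data = table[c("label", codes)]))
  },
  score = function(model, newdata)
    clamp01(unname(suppressWarnings(
      stats::predict(model, newdata = newdata, type = "response")))))

alg_gam <- list(
  name = "gam",
  fit = function(table) {
    codes <- predictor_cols(table)
    # shrink the basis when a predictor has few unique values
    terms <- vapply(codes, function(p) {
      k <- min(5, length(unique(table[[p]])))
      if (k >= 3) sprintf("s(%s, k = %d)", p, k) else p
    }, character(1))
    f <- stats::as.formula(paste("label ~", paste(terms, collapse = " + ")))
    suppressWarnings(mgcv::gam(f, family = stats::binomial(), data = table,
                               method = "REML"))
  },
  score = function(model, newdata)
    clamp01(unname(suppressWarnings(
      mgcv::predict.gam(model, newdata = newdata, type = "response")))))

alg_cart <- list(
  name = "cart",
  fit = function(table) {
    df <- table[c("label", predictor_cols(table))]
    df$label <- factor(df$label, levels = c(0, 1))
    rpart::rpart(label ~ ., data = df, method = "class",
                 control = rpart::rpart.control(cp = 0.005, minbucket = 5))
  },
  score = function(model, newdata)
    clamp01(unname(stats::predict(model, newdata = newdata, type = "prob")[, "1"])))

alg_xgb <- list(
  name = "xgb",
  fit = function(table) {
    codes <- predictor_cols(table)
    x <- as.matrix(table[codes])
    m <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3, eta = 0.3,
                    nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = table$label, nthread = 1),
      nrounds = 60, verbose = 0)
    list(model = m, codes = codes)
  },
  score = function(model, newdata)
    clamp01(stats::predict(model$model,
                           xgboost::xgb.DMatrix(as.matrix(newdata[model$codes]),
                                                nthread = 1))))

# nearest-prototype: standardized distance to the presence vs absence centroid
alg_proto <- list(
  name = "proto",
  fit = function(table) {
    codes <- predictor_cols(table)
    x <- as.matrix(table[codes])
    mu <- colMeans(x); sdv <- apply(x, 2, stats::sd); sdv[sdv == 0] <- 1
    z <- sweep(sweep(x, 2, mu), 2, sdv, "/")
    list(codes = codes, mu = mu, sd = sdv,
         c1 = colMeans(z[table$label == 1, , drop = FALSE]),
         c0 = colMeans(z[table$label == 0, , drop = FALSE]))
  },
  score = function(model, newdata) {
    z <- sweep(sweep(as.matrix(newdata[model$codes]), 2, model$mu), 2, model$sd, "/")
    d1 <- sqrt(rowSums(sweep(z, 2, model$c1)^2))
    d0 <- sqrt(rowSums(sweep(z, 2, model$c0)^2))
    stats::plogis(d0 - d1)
  })

ALG_REGISTRY <- list(sre = alg_sre, glm = alg_glm, gam = alg_gam,
                     cart = alg_cart, xgb = alg_xgb, proto = alg_proto)

ALG_ALIASES <- c(rf = "xgb", gbm = "xgb", xgboost = "xgb", mars = "gam",
                 fda = "cart", ct = "cart", maxent = "glm", maxnet = "glm",
                 ann = "proto")

#' The algorithm registry
#'
#' Six implemented families: `sre` (surface-range-envelope scorer), `glm`
#' (logistic regression), `gam` (penalized spline additive model), `cart`
#' (classification tree), `xgb` (boosted trees), `proto` (nearest prototype
#' in standardized predictor space). Common platform names (`rf`, `gbm`,
#' `mars`, `fda`, `ct`, `maxent`, `maxnet`, `ann`) are accepted as aliases of
#' the closest family, with a logged notice.
#'
#' @return Named list of algorithm plugins, each with `fit` and `score`.
#' @export
algorithm_registry <- function() ALG_REGISTRY

#' Resolve an algorithm name (alias-aware)
#'
#' @param name Algorithm or alias name.
#' @return The algorithm plugin; aliases emit a message naming the family used.
#' @export
get_algorithm <- function(name) {
  name <- tolower(name)
  if (name %in% names(ALG_REGISTRY)) return(ALG_REGISTRY[[name]])
  if (name %in% names(ALG_ALIASES)) {
    target <- ALG_ALIASES[[name]]
    message("algorithm '", name, "' mapped to implemented family '", target, "'")
    return(ALG_REGISTRY[[target]])
  }
  stop("unknown algorithm '", name, "'; see algorithm_registry()")
}
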