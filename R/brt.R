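## Weighted Bernoulli boosted regression trees with cross-validated tree
## selection, relative influence and partial dependence.

#' Configuration for boosted regression tree fitting
#'
#' Defaults follow common practice for large vegetation-plot datasets:
#' learning rate 0.001, tree complexity (maximum tree depth) 5, per-tree
#' subsampling fraction 0.5 (the train/test ratio of the stepwise-boosting
#' routine this emulates) and 10-fold cross-validation for selecting the
#' number of trees, evaluated every `stepSize` trees.
#'
#' @param learningRate shrinkage applied to each tree (> 0).
#' @param treeComplexity maximum tree depth (>= 1).
#' @param bagFraction fraction of rows subsampled per tree.
#' @param nFolds cross-validation folds (>= 2).
#' @param stepSize evaluation grid spacing in trees.
#' @param maxTrees upper bound on ensemble size.
#' @param seed RNG seed (fold assignment and tree subsampling).
#' @return named list of class "BrtConfig".
#' @export
brtConfig <- function(learningRate = 0.001, treeComplexity = 5,
                      bagFraction = 0.5, nFolds = 10, stepSize = 50,
                      maxTrees = 5000, seed = 1) {
  stopifnot(learningRate > 0, treeComplexity >= 1, nFolds >= 2,
            bagFraction > 0, bagFraction <= 1, stepSize >= 1,
            maxTrees >= stepSize)
  structure(list(learningRate = learningRate,
                 treeComplexity = as.integer(treeComplexity),
                 bagFraction = bagFraction, nFolds = as.integer(nFolds),
                 stepSize = as.integer(stepSize),
                 maxTrees = as.integer(maxTrees),
                 seed = as.integer(seed)),
            class = "BrtConfig")
}

#' Min-max scale plot weights to the 1..101 range
#'
#' scaled = (w - min(w)) / (max(w) - min(w)) * 100 + 1, computed within the
#' focal functional type: the minimum raw weight (typically the 1 assigned
#' to absence plots) maps to 1, the maximum relative cover maps to 101.
#' If all raw weights are equal the scaled weights are all 1 (with a
#' warning).
#'
#' @param raw non-negative finite weights.
#' @return weights in [1, 101].
#' @export
scaleWeights <- function(raw) {
  if (any(!is.finite(raw)) || any(raw < 0))
    stopf("scaleWeights: weights must be finite and >= 0")
  rng <- range(raw)
  if (rng[1] == rng[2]) {
    warnf("scaleWeights: all raw weights equal; returning unit weights")
    return(rep(1, length(raw)))
  }
  (raw - rng[1]) / (rng[2] - rng[1]) * 100 + 1
}

#' Raw plot weights for one functional type
#'
#' 1 where the type is absent, its relative cover where present.
#'
#' @param cover a [VegCover-class].
#' @param type functional type.
#' @return numeric vector aligned with the cover rows.
#' @export
typeWeightsRaw <- function(cover, type) {
  pres <- typePresence(cover)[, type]
  ifelse(pres > 0, typeRelativeCover(cover)[, type], 1)
}

## mean weighted Bernoulli deviance
bernoulliDeviance <- function(y, p, w) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -2 * sum(w * (y * log(p) + (1 - y) * log(1 - p))) / sum(w)
}

xgbParams <- function(cfg, seed) {
  list(objective = "binary:logistic",
       eta = cfg$learningRate,
       max_depth = cfg$treeComplexity,
       subsample = cfg$bagFraction,
       lambda = 0, alpha = 0, gamma = 0, min_child_weight = 0,
       max_delta_step = 5,   # caps leaf logits; keeps weight-scale invariance
       tree_method = "exact",
       base_score = 0.5,
       nthread = 1,
       seed = seed)
}

#' Fit a weighted Bernoulli boosted regression tree model
#'
#' Stagewise gradient boosting on the Bernoulli deviance with observation
#' weights. The number of trees is chosen as in stepwise-boosting routines:
#' each cross-validation fold is grown once to `maxTrees`, staged held-out
#' predictions are evaluated at multiples of `stepSize`, and the tree count
#' minimising the mean weighted held-out deviance is kept; the final model
#' is refit on all data at that size.
#'
#' @param X predictor matrix or data.frame (numeric columns).
#' @param y binary response (presence/absence of the functional type);
#'   must contain both classes.
#' @param w observation weights (default all 1); see [scaleWeights()].
#' @param config a [brtConfig()] list.
#' @return a [BrtFit-class].
#' @export
fitBrt <- function(X, y, w = NULL, config = brtConfig()) {
  X <- as.matrix(X)
  mode(X) <- "numeric"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stopf("fitBrt: length(y) != nrow(X)")
  if (length(unique(y)) < 2)
    stopf("fitBrt: response has a single class; cannot fit a Bernoulli model")
  if (is.null(w)) w <- rep(1, n)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0))
    stopf("fitBrt: weights must be positive and finite")
  cfg <- config

  set.seed(cfg$seed)
  folds <- sample(rep(seq_len(cfg$nFolds), length.out = n))
  steps <- seq(cfg$stepSize, cfg$maxTrees, by = cfg$stepSize)
  devMat <- matrix(NA_real_, nrow = length(steps), ncol = cfg$nFolds)
  for (f in seq_len(cfg$nFolds)) {
    tr <- folds != f
    dtr <- xgboost::xgb.DMatrix(X[tr, , drop = FALSE], label = y[tr],
                                weight = w[tr])
    fit <- xgboost::xgb.train(xgbParams(cfg, cfg$seed + f), dtr,
                              nrounds = cfg$maxTrees, verbose = 0)
    Xte <- X[!tr, , drop = FALSE]
    for (s in seq_along(steps)) {
      p <- stats::predict(fit, Xte, iterationrange = c(1, steps[s]))
      devMat[s, f] <- bernoulliDeviance(y[!tr], p, w[!tr])
    }
  }
  cvDev <- rowMeans(devMat)
  sel <- steps[which.min(cvDev)]
  if (sel == cfg$maxTrees)
    warnf("fitBrt: CV deviance still decreasing at maxTrees = %d; consider more trees",
          cfg$maxTrees)

  dall <- xgboost::xgb.DMatrix(X, label = y, weight = w)
  final <- xgboost::xgb.train(xgbParams(cfg, cfg$seed), dall,
                              nrounds = sel, verbose = 0)

  imp <- xgboost::xgb.importance(model = final)
  inf <- stats::setNames(rep(0, ncol(X)), colnames(X))
  inf[imp$Feature] <- imp$Gain
  inf <- inf / sum(inf) * 100

  methods::new("BrtFit",
               model = final,
               nTreesSelected = as.integer(sel),
               cvDeviance = data.frame(n_trees = steps, deviance = cvDev),
               influence = inf,
               config = unclass(cfg),
               trainX = X, trainY = y, trainW = w)
}

#' Predicted occurrence probability from a fitted BRT
#'
#' @param object a [BrtFit-class].
#' @param newdata predictor matrix (defaults to the training matrix).
#' @param type "response" (probability) or "link" (logit).
#' @param ... ignored.
#' @export
setMethod("predict", "BrtFit", function(object, newdata = NULL,
                                        type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object@trainX
  newdata <- as.matrix(newdata)[, colnames(object@trainX), drop = FALSE]
  stats::predict(object@model, newdata, outputmargin = (type == "link"))
})

#' Partial dependence of the model on one predictor
#'
#' Clamp-and-average: for each grid value spanning the predictor's observed
#' range, the predictor is set to that value for every training row and the
#' mean model output on the logit scale is recorded.
#'
#' @param fit a [BrtFit-class].
#' @param predictor predictor name.
#' @param gridSize number of grid points (default 100).
#' @return data.frame with columns `value` and `yhat` (mean logit).
#' @export
partialDependence <- function(fit, predictor, gridSize = 100) {
  X <- fit@trainX
  if (!predictor %in% colnames(X))
    stopf("partialDependence: unknown predictor '%s'", predictor)
  grid <- seq(min(X[, predictor]), max(X[, predictor]), length.out = gridSize)
  yhat <- vapply(grid, function(v) {
    Xc <- X
    Xc[, predictor] <- v
    mean(stats::predict(fit@model, Xc, outputmargin = TRUE))
  }, 0)
  data.frame(value = grid, yhat = yhat)
}
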