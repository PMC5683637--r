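#' @include predictor-prep.R
NULL

#' Default SDM settings
#'
#' Reads the pinned default-settings file shipped with the package
#' (`inst/extdata/sdm-defaults.yaml`): per-algorithm hyperparameters,
#' background size and fold/replicate counts.  Runs are reproducible
#' because these defaults are committed, not inherited silently from the
#' adapter libraries.
#'
#' @param path optional path to an alternative YAML config
#' @return nested list of settings
#' @export
sdmDefaults <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "sdm-defaults.yaml",
                        package = "virtualSDM")
  yaml::read_yaml(path)
}

fillHyper <- function(algorithm, hyper) {
  d <- sdmDefaults()$algorithms[[algorithm]]
  d[names(hyper)] <- hyper
  d
}

checkTrainingData <- function(features) {
  stopIfNot("label" %in% names(features),
            "features must contain a 'label' column")
  lab <- features$label
  stopIfNot(all(lab %in% c(0, 1)), "labels must be 0/1")
  if (length(unique(lab)) < 2)
    stop("degenerate training data: only one class present", call. = FALSE)
  stopIfNot(sum(lab == 1) >= 2, "need at least 2 presence rows")
}

# prevalence-0.5 case weights: total presence weight == total background
# weight, the usual presence-background convention for regression models
prevalenceWeights <- function(label) {
  np <- sum(label == 1)
  nb <- sum(label == 0)
  ifelse(label == 1, 1, np / nb)
}

quadFormula <- function(vars) {
  stats::as.formula(paste(
    "label ~",
    paste(c(vars, sprintf("I(%s^2)", vars)), collapse = " + ")
  ))
}

fitGLM <- function(features, hyper, seed) {
  vars <- setdiff(names(features), "label")
  features$.w <- prevalenceWeights(features$label)
  fit <- suppressWarnings(stats::glm(
    quadFormula(vars),
    data = features, family = stats::binomial(), weights = .w
  ))
  list(predict = function(nd) {
    as.numeric(stats::predict(fit, newdata = nd, type = "response"))
  }, object = fit)
}

fitGAM <- function(features, hyper, seed) {
  vars <- setdiff(names(features), "label")
  k <- hyper$k %||% 4
  f <- stats::as.formula(paste(
    "label ~", paste(sprintf("s(%s, k = %d)", vars, k), collapse = " + ")
  ))
  features$.w <- prevalenceWeights(features$label)
  fit <- suppressWarnings(mgcv::gam(
    f, data = features, family = stats::binomial(), weights = .w,
    method = "REML"
  ))
  list(predict = function(nd) {
    as.numeric(stats::predict(fit, newdata = nd, type = "response"))
  }, object = fit)
}

fitGBM <- function(features, hyper, seed) {
  vars <- setdiff(names(features), "label")
  dtrain <- xgboost::xgb.DMatrix(
    as.matrix(features[vars]),
    label = features$label
  )
  fit <- withSeed(seed, xgboost::xgb.train(
    params = list(
      objective = "binary:logistic",
      eta = hyper$eta %||% 0.001,
      max_depth = hyper$max_depth %||% 7,
      subsample = hyper$subsample %||% 0.5,
      nthread = 1
    ),
    data = dtrain,
    nrounds = hyper$nrounds %||% 2500,
    verbose = 0
  ))
  list(predict = function(nd) {
    as.numeric(stats::predict(fit, xgboost::xgb.DMatrix(
      as.matrix(nd[vars])
    )))
  }, object = fit)
}

fitRF <- function(features, hyper, seed) {
  vars <- setdiff(names(features), "label")
  fit <- withSeed(seed, randomForest::randomForest(
    x = features[vars], y = factor(features$label, levels = c(0, 1)),
    ntree = hyper$ntree %||% 500
  ))
  list(predict = function(nd) {
    as.numeric(stats::predict(fit, newdata = nd[vars],
                              type = "prob")[, "1"])
  }, object = fit)
}

# Maxent-style feature expansion: linear + quadratic + two-sided hinge
# basis with knots spread over the training range of each predictor.
maxentBasis <- function(X, nKnots) {
  rng <- apply(X, 2, range)
  transform <- function(nd) {
    M <- as.matrix(nd[, colnames(rng), drop = FALSE])
    out <- list(M, M^2)
    for (j in seq_len(ncol(M))) {
      lo <- rng[1, j]
      hi <- rng[2, j]
      if (hi <= lo) next
      knots <- seq(lo, hi, length.out = nKnots + 2)[2:(nKnots + 1)]
      x <- M[, j]
      for (t in knots) {
        out[[length(out) + 1L]] <-
          cbind(pmax(0, (x - t) / (hi - t)), pmax(0, (t - x) / (t - lo)))
      }
    }
    do.call(cbind, out)
  }
  transform
}

fitMAXENT <- function(features, hyper, seed) {
  vars <- setdiff(names(features), "label")
  X <- as.matrix(features[vars])
  basis <- maxentBasis(X, hyper$n_hinge_knots %||% 10)
  M <- basis(features[vars])
  y <- features$label
  # presence weight 1, background weight >> 1: the background approximates
  # the environment distribution (infinitely-weighted logistic trick)
  w <- ifelse(y == 1, 1, hyper$weight_background %||% 100)
  regmult <- hyper$regmult %||% 1
  lambdas <- 10^(seq(4, 0, length.out = 200)) * regmult *
    (sum(y) / sum(w)) * 0.05
  fit <- glmnet::glmnet(
    x = M, y = y, family = "binomial", weights = w,
    lambda = lambdas, standardize = TRUE
  )
  sFinal <- min(fit$lambda)
  list(predict = function(nd) {
    as.numeric(stats::predict(fit, newx = basis(nd[vars]),
                              s = sFinal, type = "response"))
  }, object = fit)
}

#' Fit one species distribution model
#'
#' Trains one of the five algorithm families on a presence-background
#' feature table and returns it behind the uniform [predictScores()]
#' contract:
#' * `GLM` — logistic regression with linear + quadratic terms
#'   (prevalence-0.5 weights);
#' * `GAM` — logistic additive model with a smooth (basis dimension `k`)
#'   per predictor;
#' * `GBM` — gradient-boosted trees (binary logistic objective);
#' * `RF` — random forest, class-probability output;
#' * `MAXENT` — Maxent-style penalised logistic regression on linear,
#'   quadratic and hinge features of presence vs background (maxnet
#'   formulation), logistic output.
#'
#' Hyperparameters default to the pinned settings in [sdmDefaults()]; any
#' value in `hyper` overrides its default.
#'
#' @param algorithm one of [SDM_ALGORITHMS]
#' @param features data.frame with a 0/1 `label` column (1 = presence,
#'   0 = background) and one numeric column per predictor
#' @param hyper named list of hyperparameter overrides
#' @param seed integer seed (used by the stochastic learners)
#' @param meta optional metadata list stored on the model (fold, replicate)
#' @return a [FittedSDM-class]
#' @examples
#' f <- data.frame(label = rep(1:0, each = 30),
#'                 x = c(rnorm(30, 1), rnorm(30, -1)))
#' m <- fitSDM("GLM", f)
#' predictScores(m, data.frame(x = c(-2, 0, 2)))
#' @export
fitSDM <- function(algorithm, features, hyper = list(), seed = 1,
                   meta = list()) {
  algorithm <- match.arg(algorithm, SDM_ALGORITHMS)
  checkTrainingData(features)
  hyper <- fillHyper(algorithm, hyper)
  fitter <- switch(algorithm,
    GLM = fitGLM, GAM = fitGAM, GBM = fitGBM, RF = fitRF,
    MAXENT = fitMAXENT
  )
  fit <- fitter(features, hyper, seed)
  new("FittedSDM",
    algorithm = algorithm, fit = fit,
    hyper = if (is.null(hyper)) list() else hyper,
    featureNames = setdiff(names(features), "label"),
    meta = c(meta, list(seed = seed))
  )
}

#' @rdname predictScores
#' @export
setMethod("predictScores", "FittedSDM", function(object, newdata) {
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object@featureNames, names(newdata))
  if (length(missing))
    stop("newdata is missing predictor(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  p <- object@fit$predict(newdata)
  pmin(pmax(p, 0), 1)
})

#' Predict a suitability surface over a stack
#'
#' Scores every non-nodata cell of the stack with the fitted model.
#'
#' @param model a [FittedSDM-class]
#' @param stack an [EnvStack-class] containing the model's training layers
#' @return a [GridRaster-class] of scores in `[0, 1]`; nodata propagates
#' @export
predictSurface <- function(model, stack) {
  missing <- setdiff(model@featureNames, layerNames(stack))
  if (length(missing))
    stop("stack is missing layer(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  X <- as.data.frame(stackMatrix(stack))
  names(X) <- layerNames(stack)
  ok <- stats::complete.cases(X)
  out <- rep(NA_real_, nrow(X))
  out[ok] <- predictScores(model, X[ok, , drop = FALSE])
  GridRaster(matrix(out, stack@spec@nrows, stack@spec@ncols), stack@spec)
}

#' Sample background points
#'
#' Draws `nBg` distinct non-nodata cells uniformly at random and places one
#' point uniformly within each, characterising the available environment
#' for presence-background fitting.
#'
#' @param stack an [EnvStack-class]
#' @param nBg number of background points (at most the number of non-nodata
#'   cells)
#' @param seed integer seed
#' @return data.frame with columns `x`, `y`
#' @export
makeBackground <- function(stack, nBg, seed = 1) {
  X <- stackMatrix(stack)
  cells <- which(stats::complete.cases(X))
  stopIfNot(nBg >= 1, "nBg must be >= 1")
  if (nBg > length(cells))
    stop("nBg (", nBg, ") exceeds the ", length(cells),
         " available cells", call. = FALSE)
  spec <- stack@spec
  nr <- spec@nrows
  withSeed(seed, {
    chosen <- cells[sample.int(length(cells), nBg)]
    row <- ((chosen - 1L) %% nr) + 1L
    col <- ((chosen - 1L) %/% nr) + 1L
    cs <- spec@cellSize
    data.frame(
      x = spec@originX + (col - 1 + stats::runif(nBg)) * cs,
      y = spec@originY + (nr - row + stats::runif(nBg)) * cs
    )
  })
}

#' Cross-validation plan
#'
#' Five-fold cross-validation repeated over five background replicates
#' (each replicate draws a fresh background set), i.e. 25 model runs per
#' configuration by default.
#'
#' @param kFolds number of folds
#' @param nReplicates number of background replicates
#' @param backgroundSize background points per replicate
#' @param seed integer seed from which all replicate/fold seeds derive
#' @return a list with class `"cvPlan"`
#' @export
cvPlan <- function(kFolds = 5, nReplicates = 5, backgroundSize = 1000,
                   seed = 1) {
  stopIfNot(kFolds >= 2, "kFolds must be >= 2")
  stopIfNot(nReplicates >= 1, "nReplicates must be >= 1")
  structure(
    list(kFolds = kFolds, nReplicates = nReplicates,
         backgroundSize = backgroundSize, seed = seed),
    class = "cvPlan"
  )
}

# stratified fold assignment: each class is split into k near-equal folds
foldAssign <- function(n, k, seed) {
  withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' Replicated cross-validation of one algorithm
#'
#' For each background replicate, draws a fresh background set, splits
#' presences and background separately into `kFolds` stratified folds
#' (so every fold contains both classes), fits the model on each training
#' split and scores the held-out fold.  The default plan yields exactly
#' `kFolds * nReplicates = 25` runs.
#'
#' @param algorithm one of [SDM_ALGORITHMS]
#' @param presences presence occurrence data.frame (columns `x`, `y`)
#' @param stack the predictor [EnvStack-class] (already VIF-reduced)
#' @param plan a [cvPlan()]
#' @param hyper hyperparameter overrides passed to [fitSDM()]
#' @return list of runs; each run is a list with `model`
#'   ([FittedSDM-class]), `scores` and `labels` of the held-out fold, and
#'   `replicate` / `fold` identifiers
#' @export
crossValidate <- function(algorithm, presences, stack, plan = cvPlan(),
                          hyper = list()) {
  presFeat <- extractFeatures(stack, presences)
  if (nrow(presFeat) < plan$kFolds)
    stop("fewer presences (", nrow(presFeat), ") than folds (",
         plan$kFolds, ")", call. = FALSE)
  runs <- vector("list", plan$kFolds * plan$nReplicates)
  i <- 0L
  for (r in seq_len(plan$nReplicates)) {
    bg <- makeBackground(stack, plan$backgroundSize,
                         seed = deriveSeed(plan$seed, "bg", r))
    bgFeat <- extractFeatures(stack, bg)
    presFold <- foldAssign(nrow(presFeat), plan$kFolds,
                           deriveSeed(plan$seed, "pfold", r))
    bgFold <- foldAssign(nrow(bgFeat), plan$kFolds,
                         deriveSeed(plan$seed, "bfold", r))
    all <- rbind(
      cbind(label = 1, presFeat),
      cbind(label = 0, bgFeat)
    )
    fold <- c(presFold, bgFold)
    for (f in seq_len(plan$kFolds)) {
      i <- i + 1L
      train <- all[fold != f, , drop = FALSE]
      test <- all[fold == f, , drop = FALSE]
      model <- fitSDM(algorithm, train, hyper = hyper,
                      seed = deriveSeed(plan$seed, "fit", r, f),
                      meta = list(replicate = r, fold = f))
      runs[[i]] <- list(
        model = model,
        scores = predictScores(model, test),
        labels = test$label,
        replicate = r, fold = f
      )
    }
  }
  runs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
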