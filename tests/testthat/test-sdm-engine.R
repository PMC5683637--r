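test_that("background sampling is seeded, valid and bounded", {
  bg <- makeBackground(FIX_STACK, 300, seed = 7)
  expect_equal(nrow(bg), 300L)
  expect_identical(bg, makeBackground(FIX_STACK, 300, seed = 7))
  expect_false(identical(bg, makeBackground(FIX_STACK, 300, seed = 8)))
  rc <- cellFromXY(FIX_SPEC, bg$x, bg$y)
  expect_false(anyNA(rc))
  expect_error(makeBackground(FIX_STACK, 50 * 50 + 1, 1), "exceeds")
})

test_that("single-class tables are refused by every algorithm", {
  f <- separableFeatures()
  f1 <- f[f$label == 1, ]
  for (alg in SDM_ALGORITHMS)
    expect_error(fitSDM(alg, f1), "one class")
})

test_that("random forest ranks a separable table perfectly", {
  f <- separableFeatures(30)
  m <- fitSDM("RF", f, seed = 3)
  expect_equal(aucScore(predictScores(m, f), f$label), 1)
})

test_that("GLM predictions are monotone in a single informative predictor", {
  set.seed(4)
  f <- data.frame(
    label = rep(c(1, 0), each = 40),
    x1 = c(rnorm(40, 2, 0.5), rnorm(40, -2, 0.5))
  )
  m <- fitSDM("GLM", f)
  grid <- data.frame(x1 = seq(min(f$x1), max(f$x1), length.out = 50))
  p <- predictScores(m, grid)
  expect_true(all(diff(p) >= -1e-10))
})

test_that("all five algorithms respect the common fit/predict contract", {
  pres <- samplePresences(FIX_GENERALIST, 40, seed = 2)
  presFeat <- extractFeatures(FIX_STACK_RED, pres)
  bgFeat <- extractFeatures(FIX_STACK_RED,
                            makeBackground(FIX_STACK_RED, 200, 3))
  f <- rbind(cbind(label = 1, presFeat), cbind(label = 0, bgFeat))
  fastHyper <- list(GBM = list(nrounds = 60, eta = 0.1))
  for (alg in SDM_ALGORITHMS) {
    hy <- if (is.null(fastHyper[[alg]])) list() else fastHyper[[alg]]
    m <- fitSDM(alg, f, hyper = hy, seed = 5)
    expect_s4_class(m, "FittedSDM")
    p <- predictScores(m, f)
    expect_true(all(is.finite(p) & p >= 0 & p <= 1), info = alg)
    surf <- predictSurface(m, FIX_STACK_RED)
    v <- gridValues(surf)
    expect_true(all(v >= 0 & v <= 1), info = alg)
    # determinism: same model, same stack, identical surface
    expect_identical(v, gridValues(predictSurface(m, FIX_STACK_RED)),
                     info = alg)
    expect_error(predictScores(m, data.frame(bogus = 1)), "missing")
  }
})

test_that("a constant stack yields a constant predicted surface", {
  f <- separableFeatures(25)
  m <- fitSDM("GLM", f)
  flat <- EnvStack(list(x1 = matrix(0.3, 10, 10), x2 = matrix(-1, 10, 10)),
                   GridSpec(10, 10))
  v <- gridValues(predictSurface(m, flat))
  expect_equal(max(v) - min(v), 0)
  expect_error(
    predictSurface(m, EnvStack(list(x1 = matrix(1, 10, 10)),
                               GridSpec(10, 10))),
    "missing layer"
  )
})

test_that("cross-validation produces 25 disjoint, covering runs", {
  pres <- samplePresences(FIX_GENERALIST, 25, seed = 6)
  plan <- cvPlan(5, 5, backgroundSize = 200, seed = 10)
  runs <- crossValidate("GLM", pres, FIX_STACK_RED, plan)
  expect_length(runs, 25L)
  expect_equal(sort(unique(vapply(runs, `[[`, 0, "replicate"))), 1:5)
  # within one replicate the held-out labels partition presences+background
  byRep <- split(runs, vapply(runs, `[[`, 0, "replicate"))
  for (rr in byRep) {
    nTest <- vapply(rr, function(r) length(r$labels), 0)
    expect_equal(sum(nTest), 25 + 200)
    presTest <- vapply(rr, function(r) sum(r$labels == 1), 0)
    expect_equal(sum(presTest), 25) # each presence held out exactly once
    expect_true(all(vapply(rr, function(r) all(c(0, 1) %in% r$labels),
                           TRUE))) # stratified: both classes in every fold
  }
  expect_error(
    crossValidate("GLM", samplePresences(FIX_GENERALIST, 4, 1),
                  FIX_STACK_RED, plan),
    "fewer presences"
  )
})

test_that("pinned defaults load and fill hyperparameters", {
  d <- sdmDefaults()
  expect_equal(d$algorithms$RF$ntree, 500)
  expect_equal(d$algorithms$GBM$nrounds, 2500)
  expect_equal(d$k_folds, 5)
  m <- fitSDM("RF", separableFeatures(10), hyper = list(ntree = 50))
  expect_equal(m@hyper$ntree, 50)
})

test_that("every algorithm models the generalist well at high sample size", {
  pres <- samplePresences(FIX_GENERALIST, 200, seed = 14)
  presFeat <- extractFeatures(FIX_STACK_RED, pres)
  bgFeat <- extractFeatures(FIX_STACK_RED,
                            makeBackground(FIX_STACK_RED, 1000, 15))
  f <- rbind(cbind(label = 1, presFeat), cbind(label = 0, bgFeat))
  for (alg in SDM_ALGORITHMS) {
    m <- fitSDM(alg, f, seed = 16)
    ev <- independentEvaluation(m, FIX_GENERALIST, nEval = 300, seed = 17,
                                stack = FIX_STACK_RED)
    expect_gt(ev$auc, 0.7, label = paste(alg, "independent AUC"))
  }
})
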