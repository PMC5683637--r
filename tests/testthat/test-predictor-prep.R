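# build a stack whose layers have an exactly known correlation structure
orthonormalLayers <- function(n = 400, k = 3, seed = 1) {
  set.seed(seed)
  q <- qr.Q(qr(scale(matrix(rnorm(n * k), n, k), scale = FALSE)))
  scale(q) # centred, unit variance, exactly orthogonal
}

test_that("orthogonal layers all have VIF exactly 1", {
  q <- orthonormalLayers(400, 3)
  st <- stackFromMatrices(
    a = matrix(q[, 1], 20, 20), b = matrix(q[, 2], 20, 20),
    c = matrix(q[, 3], 20, 20)
  )
  expect_equal(unname(vifScores(st)), rep(1, 3), tolerance = 1e-10)
})

test_that("a correlation of 0.95 gives the closed-form VIF 10.256", {
  q <- orthonormalLayers(400, 2)
  r <- 0.95
  b <- r * q[, 1] + sqrt(1 - r^2) * q[, 2] # exact empirical correlation r
  st <- stackFromMatrices(a = matrix(q[, 1], 20, 20), b = matrix(b, 20, 20))
  v <- vifScores(st)
  expect_equal(unname(v), rep(1 / (1 - r^2), 2), tolerance = 1e-8)
})

test_that("an exactly duplicated layer reports infinite VIF", {
  m <- gridValues(FIX_STACK[["env01"]])
  st <- stackFromMatrices(a = m, b = m, c = gridValues(FIX_STACK[["env03"]]))
  v <- vifScores(st)
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["b"]]))
  expect_true(is.finite(v[["c"]]))
})

test_that("VIF agrees with a per-layer regression oracle", {
  X <- layersMatrix(FIX_STACK)
  v <- vifScores(FIX_STACK)
  expect_equal(unname(v), vifOracle(X), tolerance = 1e-8)
})

test_that("stepwise elimination stops below the threshold", {
  red <- vifStep(FIX_STACK, threshold = 10)
  expect_true(all(vifScores(red) <= 10))
  log <- attr(red, "removed")
  expect_true(all(log$vif > 10))
  # weakly collinear stacks survive untouched
  q <- orthonormalLayers(400, 4, seed = 2)
  S <- matrix(0.45, 4, 4); diag(S) <- 1 # pairwise r = 0.45
  mild <- q %*% chol(S)
  st <- EnvStack(lapply(seq_len(4), function(j) matrix(mild[, j], 20, 20)),
                 GridSpec(20, 20))
  expect_true(all(vifScores(st) < 10))
  expect_equal(nLayers(vifStep(st, 10)), 4L)
  # threshold Inf never removes anything
  expect_equal(nLayers(vifStep(FIX_STACK, Inf)), nLayers(FIX_STACK))
})

test_that("removal follows the greedy max-VIF order of an lm oracle", {
  S <- defaultEnvCorrelation(5, baseCor = 0.3, pairCor = 0.99, nPairs = 2)
  st <- generateEnvStack(GridSpec(30, 30), 5, S, seed = 9)
  red <- vifStep(st, threshold = 10)
  # oracle: recompute VIFs with stats::lm after each removal
  X <- layersMatrix(st)
  keep <- seq_len(5)
  expected <- character(0)
  repeat {
    v <- vifOracle(X[, keep, drop = FALSE])
    if (max(v) <= 10) break
    w <- which.max(v)
    expected <- c(expected, layerNames(st)[keep[w]])
    keep <- keep[-w]
  }
  expect_equal(attr(red, "removed")$removedLayer, expected)
  expect_equal(layerNames(red), layerNames(st)[keep])
})

test_that("duplicated layers lose exactly one member first", {
  m <- gridValues(FIX_STACK[["env01"]])
  st <- stackFromMatrices(a = m, b = m, c = gridValues(FIX_STACK[["env04"]]))
  red <- vifStep(st, threshold = 10)
  log <- attr(red, "removed")
  expect_equal(log$removedLayer[1], "a") # tie on Inf broken to earliest
  expect_true(sum(c("a", "b") %in% layerNames(red)) == 1L)
})

test_that("the default 27-layer correlation lets VIF retain about 15", {
  st <- generateEnvStack(GridSpec(80, 80), 27, defaultEnvCorrelation(27),
                         smoothness = 4, seed = 42)
  red <- vifStep(st, threshold = 10)
  expect_gte(nLayers(red), 13L)
  expect_lte(nLayers(red), 17L)
})

test_that("feature extraction reads the containing cell", {
  ctr <- cellCenters(FIX_SPEC, c(3, 3, 10), c(5, 5, 40))
  pts <- data.frame(x = ctr[, "x"] + c(0, 0.2, 0), y = ctr[, "y"])
  f <- extractFeatures(FIX_STACK, pts)
  expect_equal(nrow(f), 3L)
  expect_equal(names(f), layerNames(FIX_STACK))
  expect_equal(unlist(f[1, ]), unlist(f[2, ])) # same cell, same row
  expect_equal(f[[1]][1], FIX_STACK@layers[[1]][3, 5])
  expect_equal(f[[1]][3], FIX_STACK@layers[[1]][10, 40])
})

test_that("points in nodata cells are dropped with a warning", {
  m <- gridValues(FIX_STACK[["env01"]])
  m[1, 1] <- NA
  st <- stackFromMatrices(a = m, spec = FIX_SPEC)
  pts <- data.frame(x = c(0.5, 5.5), y = c(49.5, 5.5)) # (1,1) and (45,6)
  expect_warning(f <- extractFeatures(st, pts), "dropped")
  expect_equal(nrow(f), 1L)
  expect_equal(attr(f, "kept"), 2L)
})
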