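test_that("AUC handles separation, ties and inversion", {
  expect_equal(aucScore(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)), 1)
  expect_equal(aucScore(c(0.6, 0.6), c(1, 0)), 0.5)
  expect_equal(aucScore(c(0.3, 0.4, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_error(aucScore(c(0.1, 0.2), c(1, 1)), "both classes")
  # complement property on tie-free scores
  set.seed(1)
  s <- runif(20)
  l <- rep(c(1, 0), 10)
  expect_equal(aucScore(s, l) + aucScore(-s, l), 1)
})

test_that("AUC equals the exhaustive pair oracle and pROC", {
  skip_if_not_installed("pROC")
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, 0.1), n, replace = TRUE) # ties likely
    l <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(aucScore(s, l), aucOracle(s, l), info = seed)
    expect_equal(
      aucScore(s, l),
      as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                     direction = "<"))),
      tolerance = 1e-12, info = seed
    )
  }
})

test_that("TSS maximises sensitivity + specificity - 1 over observed cuts", {
  r <- tssScore(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))
  expect_equal(r$tss, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  # fixed confusion: sens 0.8, spec 0.7 -> tss 0.5 at that cut
  s <- c(rep(0.9, 8), rep(0.1, 2), rep(0.9, 3), rep(0.1, 7))
  l <- rep(c(1, 0), c(10, 10))
  r2 <- tssScore(s, l)
  expect_equal(r2$tss, 0.5)
  expect_equal(r2$sensitivity, 0.8)
  expect_equal(r2$specificity, 0.7)
  # exhaustive-threshold oracle on random small instances
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:12, 1)
    s <- sample(seq(0, 1, 0.05), n, replace = TRUE)
    l <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    expect_equal(tssScore(s, l)$tss, tssOracle(s, l), info = seed)
  }
  # tie on the maximum resolves to the lower threshold:
  # cuts 0.4 and 0.9 both reach TSS 0.5 here
  rt <- tssScore(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))
  expect_equal(rt$tss, 0.5)
  expect_equal(rt$threshold, 0.4)
})

test_that("Schoener's D matches its formula and invariances", {
  a <- rasterFrom(c(0.25, 0.25, 0.25, 0.25))
  b <- rasterFrom(c(1, 0, 0, 0))
  # normalised p1 = rep(1/4), p2 = (1,0,0,0): D = 1 - 0.5 * 1.5 = 0.25
  expect_equal(schoenersD(a, b), 0.25)
  # two-cell archetype 1 - 0.5*(|0.5-1| + |0.5-0|) = 0.5, embedded in 4 cells
  expect_equal(schoenersD(rasterFrom(c(0.5, 0.5, 0, 0)),
                          rasterFrom(c(1, 0, 0, 0))), 0.5)
  r <- suitability(FIX_GENERALIST)
  expect_equal(schoenersD(r, r), 1)
  # disjoint supports overlap not at all
  expect_equal(schoenersD(rasterFrom(c(1, 1, 0, 0)),
                          rasterFrom(c(0, 0, 1, 1))), 0)
  # symmetry and positive-scale invariance
  x <- rasterFrom(runif(4)); y <- rasterFrom(runif(4))
  expect_equal(schoenersD(x, y), schoenersD(y, x))
  x5 <- rasterFrom(5 * gridValues(x))
  expect_equal(schoenersD(x5, y), schoenersD(x, y), tolerance = 1e-12)
  expect_error(schoenersD(rasterFrom(rep(0, 4)), y), "zero-mass")
  # random-instance oracle
  for (seed in 1:10) {
    set.seed(seed)
    vx <- runif(9); vy <- runif(9)
    expect_equal(schoenersD(rasterFrom(vx, 3, 3), rasterFrom(vy, 3, 3)),
                 schoenersDOracle(vx, vy), info = seed)
  }
})

test_that("OCCC reduces to Lin's concordance with population moments", {
  # x = (0,1), y = (1,2) duplicated over 4 cells: 2*0.25/(0.25+0.25+1) = 1/3
  x <- rasterFrom(c(0, 1, 0, 1))
  y <- rasterFrom(c(1, 2, 1, 2))
  expect_equal(occc(x, y), 1 / 3)
  r <- suitability(FIX_SPECIALIST)
  expect_equal(occc(r, r), 1)
  expect_equal(occc(x, y), occc(y, x))
  expect_error(occc(rasterFrom(rep(2, 4)), rasterFrom(rep(2, 4))),
               "constant")
  # |OCCC| <= |Pearson| on the same pairs
  for (seed in 1:10) {
    set.seed(seed)
    vx <- rnorm(9); vy <- 2 * vx + rnorm(9)
    o <- occc(rasterFrom(vx, 3, 3), rasterFrom(vy, 3, 3))
    expect_equal(o, occcOracle(vx, vy), info = seed)
    expect_lte(abs(o), abs(cor(vx, vy)) + 1e-12)
  }
  # independent noise surfaces agree at chance level
  set.seed(99)
  a <- GridRaster(matrix(rnorm(10000), 100, 100), GridSpec(100, 100))
  b <- GridRaster(matrix(rnorm(10000), 100, 100), GridSpec(100, 100))
  expect_lt(abs(occc(a, b)), 0.05)
})

test_that("agreement metrics respect the shared nodata mask", {
  va <- c(1, 2, NA, 4); vb <- c(2, 2, 5, NA)
  a <- rasterFrom(va); b <- rasterFrom(vb)
  expect_equal(occc(a, b), occcOracle(va[c(1, 2)], vb[c(1, 2)]))
  expect_equal(schoenersD(a, b), schoenersDOracle(va[c(1, 2)], vb[c(1, 2)]))
})

test_that("independent evaluation recovers the generating surface", {
  truth <- suitability(FIX_GENERALIST)
  ev <- independentEvaluation(truth, FIX_GENERALIST, nEval = 300, seed = 8)
  expect_equal(ev$mode, "independent")
  expect_gt(ev$auc, 0.5)
  # a seeded random scorer does worse on the same species
  set.seed(12)
  noise <- GridRaster(matrix(runif(2500), 50, 50), FIX_SPEC)
  evNoise <- independentEvaluation(noise, FIX_GENERALIST, 300, seed = 8)
  expect_gt(ev$auc, evNoise$auc)
  # reproducible from the seed
  expect_identical(ev,
                   independentEvaluation(truth, FIX_GENERALIST, 300, 8))
})
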