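test_that("one-sample Wilcoxon matches exact enumeration", {
  # five values all above mu0: two-sided exact p = 2 / 2^5
  r <- wilcoxonOneSample(c(0.71, 0.72, 0.73, 0.74, 0.76), mu0 = 0.7)
  expect_true(r$exact)
  expect_equal(r$p.value, 0.0625)
  # sign-assignment enumeration oracle on tie-free instances, n <= 10
  for (seed in 1:15) {
    set.seed(seed)
    n <- sample(4:10, 1)
    d <- round(rnorm(n), 3)
    d <- d[!duplicated(abs(d)) & d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxonOneSample(d, 0)$p.value, wilcoxOneOracle(d),
                 tolerance = 1e-12, info = seed)
  }
  expect_error(wilcoxonOneSample(rep(0.4, 5), 0.4), "zero")
})

test_that("symmetric samples sit at the null centre", {
  # +/- c pairs tie in |d|, so the continuity-corrected approximation is
  # used; the statistic is at its null expectation and p is ~ 1
  r <- wilcoxonOneSample(c(-3, 3, -1, 1, -2, 2), 0)
  expect_equal(r$statistic, 10.5) # half of n(n+1)/2 = 21
  expect_gt(r$p.value, 0.95)
})

test_that("two-sample Wilcoxon matches exact enumeration", {
  r <- wilcoxonTwoSample(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p.value, 0.1) # 2 / choose(6, 3)
  # symmetry in the arguments
  expect_equal(wilcoxonTwoSample(c(4, 5, 6), c(1, 2, 3))$p.value, 0.1)
  # assignment-enumeration oracle, n1 + n2 <= 12, tie-free
  for (seed in 1:15) {
    set.seed(seed)
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    v <- sample(seq_len(50), n1 + n2) # distinct
    a <- v[seq_len(n1)]
    b <- v[-seq_len(n1)]
    expect_equal(wilcoxonTwoSample(a, b)$p.value, wilcoxTwoOracle(a, b),
                 tolerance = 1e-12, info = seed)
  }
  # identical samples: maximal p
  expect_gt(wilcoxonTwoSample(c(1, 2, 3), c(1, 2, 3))$p.value, 0.95)
})

# synthetic results table where species specialisation carries all signal
# and the remaining factors are pure noise
syntheticAucTable <- function(seed = 2, reps = 4) {
  set.seed(seed)
  g <- expand.grid(
    resolution = c("high", "low"),
    algorithm = c("GLM", "RF"),
    precisionLevel = 0:1,
    sampleSize = c(10, 200),
    species = c("generalist", "specialist"),
    rep = seq_len(reps)
  )
  g$auc <- ifelse(g$species == "generalist", 0.85, 0.6) +
    rnorm(nrow(g), 0, 0.02)
  g
}

test_that("the exp(AUC) factor model detects the signal factor via AIC", {
  tab <- syntheticAucTable()
  full <- fitAucModel(tab, includeInteractions = FALSE)
  expect_equal(full$df, 5L) # five 2-level factors, 1 df each
  expect_error(fitAucModel(transform(tab, species = "generalist")),
               "fewer than 2 levels")
  # dropping the signal factor must cost > 2 AIC; a noise factor < 2
  d <- dropTermTable(tab)
  expect_equal(nrow(d), 7L)
  expect_equal(min(d$deltaAIC), 0)
  minus <- d[startsWith(d$model, "- "), ]
  aicNoSpec <- d$deltaAIC[d$model == "- species"] -
    d$deltaAIC[d$model == "full model without interactions"]
  expect_gt(aicNoSpec, 2)
  aicNoRes <- d$deltaAIC[d$model == "- resolution"] -
    d$deltaAIC[d$model == "full model without interactions"]
  expect_lt(abs(aicNoRes), 2)
  # the costliest dropped factor is the true signal factor
  expect_equal(minus$model[which.max(minus$deltaAIC)], "- species")
  # the reported df of a minus-row is the dropped factor's df
  expect_equal(d$df[d$model == "- sampleSize"], 1L)
})

test_that("adjusted R2 of the signal model beats the intercept baseline", {
  tab <- syntheticAucTable()
  full <- fitAucModel(tab)
  expect_lte(full$adjR2, 1)
  null <- summary(lm(exp(auc) ~ 1, data = tab))$adj.r.squared
  expect_gt(full$adjR2, null)
})

test_that("interaction and additive models are both fitted and ranked", {
  tab <- syntheticAucTable(seed = 4, reps = 6)
  withInt <- fitAucModel(tab, includeInteractions = TRUE)
  without <- fitAucModel(tab, includeInteractions = FALSE)
  expect_gt(withInt$df, without$df)
  d <- dropTermTable(tab)
  expect_equal(d$model[1], "full model with interactions")
  # pure-noise interactions: the additive model should win on AIC
  expect_lt(without$aic, withInt$aic)
})

test_that("the Wilcoxon report covers both comparisons", {
  set.seed(6)
  res <- expand.grid(
    species = "generalist", algorithm = c("GLM", "RF"),
    resolution = c("high", "low"), sampleSize = 20, precisionLevel = 0,
    replicate = 1:5, fold = 1:5
  )
  res$auc <- runif(nrow(res), 0.6, 0.9)
  res$aucIndep <- res$auc + rnorm(nrow(res), 0.02, 0.01)
  rep <- wilcoxonReport(res, "auc")
  expect_equal(nrow(rep$standardVsIndependent), 4L) # 2 algs x 2 resolutions
  expect_true(all(rep$standardVsIndependent$p.value >= 0 &
                    rep$standardVsIndependent$p.value <= 1))
  expect_equal(sort(rep$highVsLowResolution$algorithm), c("GLM", "RF"))
})
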