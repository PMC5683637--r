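# Shared fixtures, built once per test run.  Small grids keep the suite
# fast; seeds are fixed so every expectation is reproducible.

FIX_SPEC <- GridSpec(50, 50)
FIX_STACK <- generateEnvStack(FIX_SPEC, 5,
  defaultEnvCorrelation(5, nPairs = 1), smoothness = 4, seed = 7)
FIX_STACK_RED <- vifStep(FIX_STACK)
FIX_GENERALIST <- makeSpecies(FIX_STACK, "generalist")
FIX_SPECIALIST <- makeSpecies(FIX_STACK, "specialist")

# Hand-built species on a 2x2 grid whose presence cells have known
# suitabilities; cell (2,2) is below the 0.2 threshold (absence).
toySpecies <- function(suits = c(1.0, 0.8, 0.6, 0.1)) {
  spec <- GridSpec(2, 2)
  suit <- GridRaster(matrix(suits, 2, 2), spec)
  VirtualSpecies(NicheParams("generalist"), suit)
}

# Species whose cells all share one suitability (all presence when p >= 0.2)
uniformSpecies <- function(p, nr = 2, nc = 2) {
  spec <- GridSpec(nr, nc)
  VirtualSpecies(NicheParams("generalist"),
                 GridRaster(matrix(p, nr, nc), spec))
}

# Stack with exactly known layer matrices on the fixture grid
stackFromMatrices <- function(..., spec = NULL) {
  layers <- list(...)
  if (is.null(spec))
    spec <- GridSpec(nrow(layers[[1]]), ncol(layers[[1]]))
  EnvStack(layers, spec)
}

# Separable toy feature table: presences clustered at +1, background at -1
separableFeatures <- function(n = 30, seed = 1) {
  set.seed(seed)
  data.frame(
    label = rep(c(1, 0), each = n),
    x1 = c(rnorm(n, 1, 0.1), rnorm(n, -1, 0.1)),
    x2 = c(rnorm(n, 1, 0.1), rnorm(n, -1, 0.1))
  )
}

# Brute-force metric oracles -------------------------------------------------

aucOracle <- function(scores, labels) {
  sp <- scores[labels == 1]
  sa <- scores[labels == 0]
  mean(outer(sp, sa, function(p, a) (p > a) + 0.5 * (p == a)))
}

tssOracle <- function(scores, labels) {
  cuts <- sort(unique(c(0, scores, 1)))
  best <- -Inf
  for (t in cuts) {
    pos <- scores >= t
    v <- sum(pos & labels == 1) / sum(labels == 1) +
      sum(!pos & labels == 0) / sum(labels == 0) - 1
    if (v > best) best <- v
  }
  best
}

schoenersDOracle <- function(x, y) 1 - 0.5 * sum(abs(x / sum(x) - y / sum(y)))

occcOracle <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / n
  2 * sxy / (sum((x - mx)^2) / n + sum((y - my)^2) / n + (mx - my)^2)
}

vifOracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    d <- data.frame(y = X[, j], X[, -j, drop = FALSE])
    r2 <- summary(stats::lm(y ~ ., data = d))$r.squared
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

# Exact two-sided one-sample signed-rank p by enumeration of sign vectors
wilcoxOneOracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  vs <- as.matrix(signs) %*% r
  pLow <- mean(vs <= v)
  pHigh <- mean(vs >= v)
  min(1, 2 * min(pLow, pHigh))
}

# Exact two-sided rank-sum p by enumeration of group assignments
wilcoxTwoOracle <- function(a, b) {
  pooled <- c(a, b)
  r <- rank(pooled)
  n1 <- length(a)
  w <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(pooled), n1)
  ws <- apply(combs, 2, function(i) sum(r[i]))
  min(1, 2 * min(mean(ws <= w), mean(ws >= w)))
}

# GridRaster helpers
rasterFrom <- function(v, nr = 2, nc = 2) {
  GridRaster(matrix(v, nr, nc), GridSpec(nr, nc))
}

# cells-by-layers matrix of a stack (test-side twin of the internal helper)
layersMatrix <- function(stack) {
  vapply(stack@layers, as.vector, numeric(length(stack@layers[[1]])))
}
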