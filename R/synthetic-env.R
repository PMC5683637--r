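#' @include AllClasses.R grid-io.R
NULL

# Gaussian smoothing of a matrix, separable, edge-renormalised.
# lengthScale is the kernel S.D. in cell units; 0 = no smoothing.
smoothField <- function(m, lengthScale) {
  if (lengthScale <= 0) return(m)
  kern <- function(n) {
    d <- outer(seq_len(n), seq_len(n), "-")
    k <- exp(-d^2 / (2 * lengthScale^2))
    k / rowSums(k)
  }
  kern(nrow(m)) %*% m %*% t(kern(ncol(m)))
}

standardise <- function(v) {
  s <- stats::sd(v)
  if (s == 0) return(v - mean(v))
  (v - mean(v)) / s
}

# symmetric matrix square root, erroring on non-PSD input
psdSqrt <- function(S, tol = 1e-8) {
  if (!isSymmetric(unname(S), tol = 1e-8))
    stop("target correlation matrix must be symmetric", call. = FALSE)
  e <- eigen(S, symmetric = TRUE)
  if (min(e$values) < -tol * max(abs(e$values)))
    stop("target correlation matrix is not positive semi-definite",
         call. = FALSE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Generate a collinear, spatially autocorrelated environmental stack
#'
#' Builds `nLayers` synthetic environmental layers emulating a multi-layer
#' climatic predictor set: independent Gaussian white-noise fields are
#' smoothed with a Gaussian kernel of standard deviation `smoothness`
#' cells (spatial autocorrelation), optionally blended with a random-
#' orientation linear spatial gradient (large-scale structure), each field
#' standardised, and the fields mixed through the symmetric square root of
#' `targetCorrelation` so the layers' empirical inter-layer correlations
#' approximate the target.  The whole construction is deterministic given
#' `seed`.
#'
#' @param spec a [GridSpec-class]
#' @param nLayers number of layers
#' @param targetCorrelation symmetric positive semi-definite matrix of size
#'   `nLayers`; default identity (mutually independent layers)
#' @param smoothness Gaussian smoothing length-scale in cell units
#' @param seed integer seed
#' @param gradientWeight weight of the linear spatial gradient added to each
#'   base field before standardisation (0 disables gradients)
#' @return an [EnvStack-class] with layers `env01`, `env02`, ...
#' @examples
#' stack <- generateEnvStack(GridSpec(50, 50), 4, seed = 1)
#' nLayers(stack)
#' @export
generateEnvStack <- function(spec, nLayers,
                             targetCorrelation = diag(nLayers),
                             smoothness = 5, seed = 1,
                             gradientWeight = 0.5) {
  stopIfNot(nLayers >= 1, "nLayers must be >= 1")
  targetCorrelation <- as.matrix(targetCorrelation)
  stopIfNot(
    all(dim(targetCorrelation) == nLayers),
    "targetCorrelation must be ", nLayers, " x ", nLayers
  )
  mix <- psdSqrt(targetCorrelation)
  nr <- spec@nrows
  nc <- spec@ncols
  # normalised cell-centre coordinates for gradient fields
  gx <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  gy <- matrix(rep((seq_len(nr) - 0.5) / nr, times = nc), nr, nc)
  base <- withSeed(seed, {
    vapply(seq_len(nLayers), function(i) {
      f <- smoothField(matrix(stats::rnorm(nr * nc), nr, nc), smoothness)
      f <- standardise(as.vector(f))
      if (gradientWeight > 0) {
        theta <- stats::runif(1, 0, 2 * pi)
        g <- standardise(as.vector(cos(theta) * gx + sin(theta) * gy))
        f <- standardise(f + gradientWeight * g)
      }
      f
    }, numeric(nr * nc))
  })
  mixed <- base %*% mix
  layers <- lapply(seq_len(nLayers), function(i) matrix(mixed[, i], nr, nc))
  names(layers) <- sprintf("env%02d", seq_len(nLayers))
  EnvStack(layers, spec)
}

#' Default correlation structure for the synthetic predictor set
#'
#' A 27-layer correlation target emulating a realistic climatic predictor
#' set: a mild baseline correlation among all layers plus twelve highly
#' collinear pairs (such as temperature layers derived from one another),
#' so that stepwise VIF filtering at the conventional threshold of 10
#' removes roughly one layer per pair and retains about 15 of 27.
#'
#' @param nLayers number of layers (default 27)
#' @param baseCor baseline correlation among all layers
#' @param pairCor within-pair correlation for the collinear pairs
#' @param nPairs number of collinear pairs (consecutive layers 1-2, 3-4, ...)
#' @return an `nLayers` x `nLayers` correlation matrix
#' @export
defaultEnvCorrelation <- function(nLayers = 27, baseCor = 0.2,
                                  pairCor = 0.975,
                                  nPairs = min(12L, nLayers %/% 2L)) {
  S <- matrix(baseCor, nLayers, nLayers)
  diag(S) <- 1
  for (p in seq_len(nPairs)) {
    i <- 2L * p - 1L
    S[i, i + 1L] <- S[i + 1L, i] <- pairCor
  }
  S
}

#' Bilinear resampling onto a new grid
#'
#' Each target cell value is the bilinear interpolation of the four source
#' cell centres surrounding the target cell centre; target centres lying
#' between the extent edge and the outermost source centres use the edge
#' value (clamped interpolation).  A target cell whose centre falls outside
#' the source extent is an error; nodata in any contributing source cell
#' propagates to the target cell.
#'
#' @param raster a [GridRaster-class]
#' @param target the output [GridSpec-class]
#' @return a [GridRaster-class] on `target`
#' @examples
#' src <- GridRaster(matrix(1:16, 4, 4), GridSpec(4, 4, cellSize = 1))
#' lowres <- bilinearResample(src, GridSpec(2, 2, cellSize = 2))
#' @export
bilinearResample <- function(raster, target) {
  src <- raster@spec
  pts <- cellCenters(target,
    rows = rep(seq_len(target@nrows), times = target@ncols),
    cols = rep(seq_len(target@ncols), each = target@nrows)
  )
  if (!all(insideExtent(src, pts[, "x"], pts[, "y"])))
    stop("target grid extends outside the source extent", call. = FALSE)
  cs <- src@cellSize
  # continuous (0-based) position in the source cell-centre lattice
  px <- (pts[, "x"] - src@originX) / cs - 0.5
  py <- (src@originY + src@nrows * cs - pts[, "y"]) / cs - 0.5
  clamp <- function(v, hi) pmin(pmax(v, 0), hi)
  px <- clamp(px, src@ncols - 1)
  py <- clamp(py, src@nrows - 1)
  c0 <- pmin(floor(px), src@ncols - 2); c1 <- c0 + 1
  r0 <- pmin(floor(py), src@nrows - 2); r1 <- r0 + 1
  wx <- px - c0
  wy <- py - r0
  v <- raster@values
  at <- function(r, c) v[cbind(r + 1, c + 1)]
  out <- (1 - wy) * ((1 - wx) * at(r0, c0) + wx * at(r0, c1)) +
    wy * ((1 - wx) * at(r1, c0) + wx * at(r1, c1))
  GridRaster(matrix(out, target@nrows, target@ncols), target)
}

#' Resample every layer of a stack
#'
#' @param stack an [EnvStack-class]
#' @param target the output [GridSpec-class]
#' @return an [EnvStack-class] on `target`
#' @export
resampleStack <- function(stack, target) {
  layers <- lapply(stack@layers, function(m) {
    gridValues(bilinearResample(GridRaster(m, stack@spec), target))
  })
  EnvStack(layers, target)
}

#' Principal-component score surfaces of an environmental stack
#'
#' Layers are z-standardised over non-nodata cells and decomposed with PCA;
#' the first `nComponents` per-cell score surfaces are returned, each
#' re-standardised to mean 0 and unit variance so downstream niche breadths
#' are expressed in axis-standard-deviation units.  Components are oriented
#' so the loading of largest magnitude is positive, making score signs
#' reproducible under layer reordering.
#'
#' @param stack an [EnvStack-class] with >= 2 layers
#' @param nComponents number of leading components to return
#' @return list with `scores` (named list of [GridRaster-class]s `PC1`,
#'   `PC2`, ...) and `varExplained` (fractions of total variance, one per
#'   returned component)
#' @examples
#' stack <- generateEnvStack(GridSpec(40, 40), 4, seed = 1)
#' pcs <- pcaScores(stack, 2)
#' pcs$varExplained
#' @export
pcaScores <- function(stack, nComponents = 2) {
  stopIfNot(nLayers(stack) >= 2, "need at least 2 layers for PCA")
  X <- stackMatrix(stack)
  ok <- stats::complete.cases(X)
  sds <- apply(X[ok, , drop = FALSE], 2, stats::sd)
  if (any(sds == 0))
    stop("layer '", layerNames(stack)[which(sds == 0)[1]],
         "' is constant over non-nodata cells", call. = FALSE)
  Z <- scale(X[ok, , drop = FALSE])
  p <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  stopIfNot(nComponents <= ncol(p$x),
            "nComponents exceeds the number of components")
  if (any(p$sdev[seq_len(nComponents)] < 1e-10))
    stop("requested component has zero variance (degenerate stack)",
         call. = FALSE)
  varExplained <- p$sdev^2 / sum(p$sdev^2)
  nr <- stack@spec@nrows
  nc <- stack@spec@ncols
  scores <- lapply(seq_len(nComponents), function(j) {
    s <- p$x[, j]
    if (p$rotation[which.max(abs(p$rotation[, j])), j] < 0) s <- -s
    s <- standardise(s)
    full <- rep(NA_real_, nr * nc)
    full[ok] <- s
    GridRaster(matrix(full, nr, nc), stack@spec)
  })
  names(scores) <- paste0("PC", seq_len(nComponents))
  list(scores = scores, varExplained = varExplained[seq_len(nComponents)])
}
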