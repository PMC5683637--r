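#' @include AllClasses.R
NULL

vifFromMatrix <- function(X) {
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    y <- X[, j]
    Z <- X[, -j, drop = FALSE]
    fit <- stats::lm.fit(cbind(1, Z), y)
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
}

vifMatrix <- function(stack, maxCells, seed) {
  X <- stackMatrix(stack)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  stopIfNot(nrow(X) > ncol(X), "too few non-nodata cells for VIF")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("layer '", layerNames(stack)[which(sds == 0)[1]],
         "' is constant; VIF undefined", call. = FALSE)
  if (nrow(X) > maxCells)
    X <- withSeed(seed, X[sample.int(nrow(X), maxCells), , drop = FALSE])
  X
}

#' Variance inflation factors of a stack's layers
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` comes from regressing layer `j`
#' on all other layers over non-nodata cells.  Perfectly collinear layers
#' get `Inf`.  For large grids the regression uses a deterministic uniform
#' subsample of at most `maxCells` cells.
#'
#' @param stack an [EnvStack-class] with >= 2 non-constant layers
#' @param maxCells cell subsample cap
#' @param seed seed for the subsample
#' @return named numeric vector of VIF values, one per layer
#' @examples
#' stack <- generateEnvStack(GridSpec(40, 40), 4, seed = 1)
#' vifScores(stack)
#' @export
vifScores <- function(stack, maxCells = 50000, seed = 1) {
  stopIfNot(nLayers(stack) >= 2, "need at least 2 layers")
  X <- vifMatrix(stack, maxCells, seed)
  stats::setNames(vifFromMatrix(X), layerNames(stack))
}

#' Stepwise VIF elimination
#'
#' Iteratively removes the layer with the largest VIF (ties broken toward
#' the earliest layer), recomputing the VIFs after each removal, until all
#' remaining layers have VIF <= `threshold` — the conventional collinearity
#' screen at threshold 10.
#'
#' @inheritParams vifScores
#' @param threshold retention cut (default 10)
#' @return the reduced [EnvStack-class]; attribute `"removed"` holds the
#'   removal log (`iteration`, `removedLayer`, `vif`)
#' @examples
#' S <- defaultEnvCorrelation(8, nPairs = 3)
#' stack <- generateEnvStack(GridSpec(60, 60), 8, S, seed = 1)
#' reduced <- vifStep(stack)
#' attr(reduced, "removed")
#' @export
vifStep <- function(stack, threshold = 10, maxCells = 50000, seed = 1) {
  X <- vifMatrix(stack, maxCells, seed)
  keep <- seq_len(ncol(X))
  log <- data.frame(
    iteration = integer(0), removedLayer = character(0), vif = numeric(0)
  )
  it <- 0L
  while (length(keep) >= 2) {
    v <- vifFromMatrix(X[, keep, drop = FALSE])
    if (max(v) <= threshold) break
    it <- it + 1L
    worst <- which.max(v) # which.max takes the first maximum: earliest layer
    log <- rbind(log, data.frame(
      iteration = it,
      removedLayer = layerNames(stack)[keep[worst]],
      vif = v[worst]
    ))
    keep <- keep[-worst]
  }
  out <- EnvStack(stack@layers[keep], stack@spec)
  attr(out, "removed") <- log
  out
}

#' Extract per-point predictor values
#'
#' Each point receives the layer values of the cell containing it.  Points
#' falling in nodata cells (or outside the extent) are dropped with a
#' warning; the attribute `"kept"` gives the surviving row indices of the
#' input.
#'
#' @param stack an [EnvStack-class]
#' @param points data.frame with columns `x`, `y`
#' @return data.frame with one column per layer, one row per retained point
#' @export
extractFeatures <- function(stack, points) {
  rc <- cellFromXY(stack@spec, points$x, points$y)
  nr <- stack@spec@nrows
  cell <- (rc[, "col"] - 1L) * nr + rc[, "row"]
  X <- stackMatrix(stack)
  vals <- X[ifelse(is.na(cell), 1L, cell), , drop = FALSE]
  vals[is.na(cell), ] <- NA_real_
  ok <- stats::complete.cases(vals)
  if (any(!ok))
    warning(sum(!ok), " point(s) in nodata cells or outside the extent ",
            "were dropped")
  out <- as.data.frame(vals[ok, , drop = FALSE])
  names(out) <- layerNames(stack)
  attr(out, "kept") <- which(ok)
  out
}
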