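#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# GridSpec
# ---------------------------------------------------------------------------

#' Planar grid specification
#'
#' Describes a regular planar grid: dimensions, square cell size and the
#' coordinates of the lower-left corner of the extent.  Cells are indexed
#' `(row, col)` with row 1 the *top* row (matrix convention, matching ESRI
#' ASCII raster layout); the centre of cell `(r, c)` is at
#' `x = originX + (c - 1/2) * cellSize`,
#' `y = originY + (nrows - r + 1/2) * cellSize`.
#'
#' @slot nrows,ncols integer grid dimensions (both >= 2)
#' @slot cellSize positive cell edge length (arc-minutes or any abstract
#'   planar unit; all distances in the package are in this unit)
#' @slot originX,originY coordinates of the lower-left corner of the extent
#' @slot nodata numeric sentinel written for missing cells in `.asc` files
#'   (in memory, missing cells are `NA`)
#' @seealso [GridSpec()], [GridRaster-class]
#' @export
setClass("GridSpec",
  representation(
    nrows = "integer", ncols = "integer",
    cellSize = "numeric", originX = "numeric", originY = "numeric",
    nodata = "numeric"
  )
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nrows) != 1L || is.na(object@nrows) || object@nrows < 2L)
    msg <- c(msg, "nrows must be a single integer >= 2")
  if (length(object@ncols) != 1L || is.na(object@ncols) || object@ncols < 2L)
    msg <- c(msg, "ncols must be a single integer >= 2")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) ||
      object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (length(object@originX) != 1L || length(object@originY) != 1L ||
      !is.finite(object@originX) || !is.finite(object@originY))
    msg <- c(msg, "origin coordinates must be single finite numbers")
  if (length(msg)) msg else TRUE
})

#' Construct a grid specification
#'
#' @param nrows,ncols grid dimensions (>= 2)
#' @param cellSize cell edge length (> 0)
#' @param originX,originY lower-left corner of the extent
#' @param nodata sentinel written for missing cells in `.asc` output
#' @return a [GridSpec-class]
#' @examples
#' GridSpec(100, 100, cellSize = 2.5)
#' @export
GridSpec <- function(nrows, ncols, cellSize = 1, originX = 0, originY = 0,
                     nodata = -9999) {
  new("GridSpec",
    nrows = as.integer(nrows), ncols = as.integer(ncols),
    cellSize = as.numeric(cellSize),
    originX = as.numeric(originX), originY = as.numeric(originY),
    nodata = as.numeric(nodata)
  )
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells, cell size %g, origin (%g, %g)\n",
    object@nrows, object@ncols, object@cellSize,
    object@originX, object@originY
  ))
})

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "GridSpec", function(x) x)

#' @describeIn GridSpec-class grid dimensions as `c(nrows, ncols)`
#' @param x a `GridSpec`
#' @export
setMethod("dim", "GridSpec", function(x) c(x@nrows, x@ncols))

sameGrid <- function(a, b) {
  isTRUE(all.equal(
    c(a@nrows, a@ncols, a@cellSize, a@originX, a@originY),
    c(b@nrows, b@ncols, b@cellSize, b@originX, b@originY)
  ))
}

# ---------------------------------------------------------------------------
# GridRaster
# ---------------------------------------------------------------------------

#' Single-layer raster on a planar grid
#'
#' A numeric matrix tied to a [GridSpec-class]; `NA` marks nodata cells.
#' All raster-valued quantities in the package (environmental layers,
#' principal-component scores, suitability surfaces, binary ranges,
#' predicted surfaces) are `GridRaster` objects.
#'
#' @slot spec the [GridSpec-class]
#' @slot values numeric matrix of dimension `dim(spec)`; finite or `NA`
#' @seealso [GridRaster()], [readAsc()], [writeAsc()]
#' @export
setClass("GridRaster",
  representation(spec = "GridSpec", values = "matrix")
)

setValidity("GridRaster", function(object) {
  v <- object@values
  if (!is.numeric(v))
    return("values must be a numeric matrix")
  if (!identical(dim(v), c(object@spec@nrows, object@spec@ncols)))
    return(sprintf(
      "values dimension (%d x %d) does not match spec (%d x %d)",
      nrow(v), ncol(v), object@spec@nrows, object@spec@ncols
    ))
  if (any(is.infinite(v) | is.nan(v)))
    return("values must be finite or NA")
  TRUE
})

#' Construct a raster
#'
#' @param values numeric matrix (`NA` = nodata)
#' @param spec a [GridSpec-class] matching `dim(values)`
#' @return a [GridRaster-class]
#' @examples
#' GridRaster(matrix(runif(12), 3, 4), GridSpec(3, 4))
#' @export
GridRaster <- function(values, spec) {
  storage.mode(values) <- "double"
  new("GridRaster", spec = spec, values = values)
}

setMethod("show", "GridRaster", function(object) {
  v <- object@values
  ok <- !is.na(v)
  cat(sprintf(
    "GridRaster: %d x %d cells (%d nodata); range [%s, %s]\n",
    nrow(v), ncol(v), sum(!ok),
    if (any(ok)) format(min(v[ok]), digits = 4) else "NA",
    if (any(ok)) format(max(v[ok]), digits = 4) else "NA"
  ))
})

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "GridRaster", function(x) x@spec)

#' @rdname grid-accessors
#' @export
setMethod("gridValues", "GridRaster", function(x) x@values)

#' @describeIn GridRaster-class grid dimensions
#' @param x a `GridRaster`
#' @export
setMethod("dim", "GridRaster", function(x) dim(x@values))

# ---------------------------------------------------------------------------
# EnvStack
# ---------------------------------------------------------------------------

#' Stack of co-registered environmental layers
#'
#' An ordered, named collection of raster layers sharing one
#' [GridSpec-class]; the synthetic counterpart of a multi-layer climatic /
#' topographic predictor set.
#'
#' @slot spec the shared [GridSpec-class]
#' @slot layers named list of numeric matrices, all of dimension `dim(spec)`
#' @seealso [EnvStack()], [generateEnvStack()], [vifStep()]
#' @export
setClass("EnvStack",
  representation(spec = "GridSpec", layers = "list")
)

setValidity("EnvStack", function(object) {
  ls <- object@layers
  if (length(ls) < 1L) return("stack must contain at least one layer")
  nm <- names(ls)
  if (is.null(nm) || any(!nzchar(nm)))
    return("all layers must be named")
  if (anyDuplicated(nm)) return("layer names must be unique")
  d <- c(object@spec@nrows, object@spec@ncols)
  for (i in seq_along(ls)) {
    if (!is.matrix(ls[[i]]) || !is.numeric(ls[[i]]) ||
        !identical(dim(ls[[i]]), d))
      return(sprintf("layer '%s' is not a %d x %d numeric matrix",
                     nm[i], d[1], d[2]))
  }
  TRUE
})

#' Construct an environmental stack
#'
#' @param layers named list of numeric matrices (or `GridRaster`s) sharing
#'   one grid
#' @param spec the shared [GridSpec-class]
#' @return an [EnvStack-class]
#' @export
EnvStack <- function(layers, spec) {
  layers <- lapply(layers, function(l) {
    if (is(l, "GridRaster")) l <- l@values
    storage.mode(l) <- "double"
    l
  })
  if (is.null(names(layers)))
    names(layers) <- paste0("env", seq_along(layers))
  new("EnvStack", spec = spec, layers = layers)
}

setMethod("show", "EnvStack", function(object) {
  cat(sprintf(
    "EnvStack: %d layers on a %d x %d grid\n  layers: %s\n",
    length(object@layers), object@spec@nrows, object@spec@ncols,
    paste(names(object@layers), collapse = ", ")
  ))
})

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "EnvStack", function(x) x@spec)

#' @rdname grid-accessors
#' @export
setMethod("nLayers", "EnvStack", function(x) length(x@layers))

#' @rdname grid-accessors
#' @export
setMethod("layerNames", "EnvStack", function(x) names(x@layers))

#' @describeIn EnvStack-class extract one layer as a [GridRaster-class]
#' @param x an `EnvStack`
#' @param i layer index or name
#' @export
setMethod("[[", "EnvStack", function(x, i) {
  GridRaster(x@layers[[i]], x@spec)
})

#' Flatten a stack to a cells-by-layers matrix
#'
#' @param stack an [EnvStack-class]
#' @return numeric matrix with one column per layer and one row per cell
#'   (column-major cell order); rows with any `NA` correspond to nodata.
#' @keywords internal
stackMatrix <- function(stack) {
  do.call(cbind, lapply(stack@layers, as.vector))
}

# ---------------------------------------------------------------------------
# NicheParams / VirtualSpecies
# ---------------------------------------------------------------------------

#' Specialisation levels
#'
#' The four niche-breadth levels, ordered from widest to narrowest niche.
#' The associated Gaussian response standard deviations on the standardised
#' principal-component axes are 0.8, 0.6, 0.4 and 0.2.
#' @export
SPECIALISATION_LEVELS <- c(
  "generalist", "restricted_generalist", "relaxed_specialist", "specialist"
)

specialisationSigma <- c(
  generalist = 0.8, restricted_generalist = 0.6,
  relaxed_specialist = 0.4, specialist = 0.2
)

#' Gaussian niche parameters
#'
#' The niche is a product of two Gaussian responses on the first two
#' (standardised) principal-component axes of the environment, with a
#' common optimum at the axis origin `(0, 0)` and a common breadth `sigma`
#' per specialisation level: 0.8 (generalist), 0.6 (restricted generalist),
#' 0.4 (relaxed specialist), 0.2 (specialist).  `threshold` is the
#' suitability cut converting the continuous surface into the binary true
#' range (default 0.2, boundary inclusive).
#'
#' @slot label one of [SPECIALISATION_LEVELS]
#' @slot mu1,mu2 niche optimum on the two axes (0, 0)
#' @slot sigma1,sigma2 niche breadth in axis-standard-deviation units
#' @slot threshold suitability cut in (0, 1)
#' @export
setClass("NicheParams",
  representation(
    label = "character",
    mu1 = "numeric", mu2 = "numeric",
    sigma1 = "numeric", sigma2 = "numeric",
    threshold = "numeric"
  )
)

setValidity("NicheParams", function(object) {
  msg <- character()
  if (!object@label %in% SPECIALISATION_LEVELS)
    msg <- c(msg, sprintf("unknown specialisation label '%s'", object@label))
  if (object@sigma1 <= 0 || object@sigma2 <= 0)
    msg <- c(msg, "sigma1 and sigma2 must be positive")
  if (object@threshold <= 0 || object@threshold >= 1)
    msg <- c(msg, "threshold must lie strictly between 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Construct niche parameters for a specialisation level
#'
#' @param label one of [SPECIALISATION_LEVELS]
#' @param threshold suitability cut for the binary range (default 0.2)
#' @return a [NicheParams-class] with `sigma1 = sigma2` set by the label
#'   (0.8 / 0.6 / 0.4 / 0.2) and optimum at the origin
#' @examples
#' NicheParams("specialist")
#' @export
NicheParams <- function(label, threshold = 0.2) {
  label <- match.arg(label, SPECIALISATION_LEVELS)
  s <- unname(specialisationSigma[label])
  new("NicheParams",
    label = label, mu1 = 0, mu2 = 0,
    sigma1 = s, sigma2 = s, threshold = as.numeric(threshold)
  )
}

setMethod("show", "NicheParams", function(object) {
  cat(sprintf(
    "NicheParams: %s (sigma = %g, %g; optimum (%g, %g); threshold %g)\n",
    object@label, object@sigma1, object@sigma2,
    object@mu1, object@mu2, object@threshold
  ))
})

#' Virtual species with known niche and range
#'
#' Couples the niche definition with its realisation on a grid: the
#' continuous suitability surface in `[0, 1]` (rescaled so the maximum over
#' non-nodata cells is 1) and the binary true range obtained by
#' thresholding it (presence iff suitability >= threshold).
#'
#' @slot params the [NicheParams-class]
#' @slot suitability continuous [GridRaster-class] in `[0, 1]`
#' @slot trueRange binary [GridRaster-class] (1 presence / 0 absence)
#' @slot resolution free-text tag, conventionally `"high"` or `"low"`
#' @seealso [makeSpecies()], [samplePresences()]
#' @export
setClass("VirtualSpecies",
  representation(
    params = "NicheParams",
    suitability = "GridRaster",
    trueRange = "GridRaster",
    resolution = "character"
  )
)

setValidity("VirtualSpecies", function(object) {
  s <- object@suitability@values
  b <- object@trueRange@values
  if (!sameGrid(object@suitability@spec, object@trueRange@spec))
    return("suitability and trueRange must share one grid")
  ok <- !is.na(s)
  if (any(s[ok] < 0 | s[ok] > 1))
    return("suitability values must lie in [0, 1]")
  okb <- !is.na(b)
  if (any(!b[okb] %in% c(0, 1)))
    return("trueRange must be binary (0/1)")
  if (!identical(which(is.na(s)), which(is.na(b))))
    return("suitability and trueRange must share the nodata mask")
  TRUE
})

#' Construct a virtual species from its components
#'
#' Low-level constructor; most users will call [makeSpecies()], which
#' derives all components from an environmental stack.  The binary range is
#' recomputed from the suitability surface unless supplied.
#'
#' @param params a [NicheParams-class]
#' @param suitability continuous suitability [GridRaster-class] in `[0, 1]`
#' @param trueRange optional binary [GridRaster-class]; defaults to
#'   `thresholdRange(suitability, params@threshold)`
#' @param resolution tag, conventionally `"high"` or `"low"`
#' @return a [VirtualSpecies-class]
#' @export
VirtualSpecies <- function(params, suitability, trueRange = NULL,
                           resolution = "high") {
  if (is.null(trueRange))
    trueRange <- thresholdRange(suitability, params@threshold)
  new("VirtualSpecies",
    params = params, suitability = suitability,
    trueRange = trueRange, resolution = resolution
  )
}

setMethod("show", "VirtualSpecies", function(object) {
  b <- object@trueRange@values
  cat(sprintf(
    "VirtualSpecies: %s (%s resolution)\n  presence cells: %d of %d\n",
    object@params@label, object@resolution,
    sum(b == 1, na.rm = TRUE), sum(!is.na(b))
  ))
})

#' @rdname species-accessors
#' @export
setMethod("suitability", "VirtualSpecies", function(x) x@suitability)

#' @rdname species-accessors
#' @export
setMethod("trueRange", "VirtualSpecies", function(x) x@trueRange)

#' @rdname species-accessors
#' @export
setMethod("nicheParams", "VirtualSpecies", function(x) x@params)

#' @rdname grid-accessors
#' @export
setMethod("gridSpec", "VirtualSpecies", function(x) x@suitability@spec)

# ---------------------------------------------------------------------------
# FittedSDM
# ---------------------------------------------------------------------------

#' Fitted species distribution model
#'
#' Wraps one fitted presence-background model behind a uniform
#' fit / [predictScores()] contract, so the cross-validation harness and the
#' evaluation code never branch on the algorithm.
#'
#' @slot algorithm one of `"GLM"`, `"GAM"`, `"GBM"`, `"RF"`, `"MAXENT"`
#' @slot fit the underlying fitted object (algorithm-specific)
#' @slot hyper hyperparameters used, after default-filling
#' @slot featureNames predictor column names seen at training
#' @slot meta run metadata (fold, replicate, seed, ...)
#' @seealso [fitSDM()], [predictSurface()], [crossValidate()]
#' @export
setClass("FittedSDM",
  representation(
    algorithm = "character", fit = "ANY", hyper = "list",
    featureNames = "character", meta = "list"
  )
)

setValidity("FittedSDM", function(object) {
  if (!object@algorithm %in% SDM_ALGORITHMS)
    return(sprintf("unknown algorithm '%s'", object@algorithm))
  if (length(object@featureNames) < 1L)
    return("featureNames must be non-empty")
  TRUE
})

setMethod("show", "FittedSDM", function(object) {
  cat(sprintf(
    "FittedSDM: %s on %d predictors (%s)\n",
    object@algorithm, length(object@featureNames),
    paste(object@featureNames, collapse = ", ")
  ))
})

#' The five supported SDM algorithm families
#' @export
SDM_ALGORITHMS <- c("GLM", "GAM", "GBM", "RF", "MAXENT")
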