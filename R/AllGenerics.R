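#' @include AllGenerics.R
NULL

#' Accessor generics for grid-valued objects
#'
#' `gridSpec()` returns the [GridSpec-class] shared by an object's raster
#' content; `gridValues()` returns the numeric value matrix (with `NA` for
#' nodata cells); `nLayers()` and `layerNames()` describe an
#' [EnvStack-class].
#'
#' @param x a `GridRaster`, `EnvStack` or `VirtualSpecies`
#' @return `gridSpec()`: a `GridSpec`; `gridValues()`: a numeric matrix;
#'   `nLayers()`: integer count; `layerNames()`: character vector.
#' @name grid-accessors
#' @aliases gridSpec gridValues nLayers layerNames
#' @examples
#' r <- GridRaster(matrix(1:6, 2, 3), GridSpec(2, 3))
#' gridSpec(r)
#' gridValues(r)
NULL

#' @rdname grid-accessors
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname grid-accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname grid-accessors
#' @export
setGeneric("nLayers", function(x) standardGeneric("nLayers"))

#' @rdname grid-accessors
#' @export
setGeneric("layerNames", function(x) standardGeneric("layerNames"))

#' Accessors for virtual species components
#'
#' @param x a [VirtualSpecies-class]
#' @return `suitability()` and `trueRange()` return [GridRaster-class]
#'   objects (the continuous suitability surface and the thresholded binary
#'   range); `nicheParams()` returns the [NicheParams-class].
#' @name species-accessors
#' @aliases suitability trueRange nicheParams
NULL

#' @rdname species-accessors
#' @export
setGeneric("suitability", function(x) standardGeneric("suitability"))

#' @rdname species-accessors
#' @export
setGeneric("trueRange", function(x) standardGeneric("trueRange"))

#' @rdname species-accessors
#' @export
setGeneric("nicheParams", function(x) standardGeneric("nicheParams"))

#' Score new observations with a fitted SDM
#'
#' Evaluates a fitted model's suitability scorer on a table of predictor
#' values, returning one score in `[0, 1]` per row.
#'
#' @param object a [FittedSDM-class]
#' @param newdata data.frame (or matrix) whose columns include the model's
#'   training predictors
#' @return numeric vector of scores in `[0, 1]`, one per row of `newdata`.
#' @export
setGeneric("predictScores", function(object, newdata) standardGeneric("predictScores"))
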