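#' @include AllClasses.R synthetic-env.R
NULL

#' Gaussian niche response
#'
#' The species' response to one environmental axis:
#' `exp(-(x - mu)^2 / (2 * sigma^2))`, equal to 1 at the optimum and
#' symmetric about it.  `sigma` is the niche breadth; on standardised
#' principal-component axes the four specialisation levels use
#' 0.8, 0.6, 0.4 and 0.2.
#'
#' @param x axis score (vectorised)
#' @param mu niche optimum
#' @param sigma niche breadth (> 0)
#' @return suitability factor in `(0, 1]`
#' @examples
#' gaussianResponse(0, 0, 0.8)        # 1 at the optimum
#' gaussianResponse(0.8, 0, 0.8)      # exp(-1/2) one S.D. away
#' @export
gaussianResponse <- function(x, mu = 0, sigma) {
  stopIfNot(length(sigma) == 1 && is.finite(sigma) && sigma > 0,
            "sigma must be a single positive number")
  exp(-(x - mu)^2 / (2 * sigma^2))
}

#' Multiplicative suitability surface from two axis scores
#'
#' Per-cell product of the Gaussian responses on the first two principal
#' component axes, rescaled by its maximum over non-nodata cells so the
#' best cell has suitability exactly 1.  The multiplicative combination
#' means one strongly unfavourable axis keeps overall suitability low even
#' when the other axis is optimal.
#'
#' @param pc1,pc2 score [GridRaster-class]s on one grid
#' @param params a [NicheParams-class]
#' @return suitability [GridRaster-class] with values in `[0, 1]`, max 1
#' @export
buildSuitability <- function(pc1, pc2, params) {
  if (!sameGrid(pc1@spec, pc2@spec))
    stop("pc1 and pc2 must share one grid", call. = FALSE)
  s <- gaussianResponse(pc1@values, params@mu1, params@sigma1) *
    gaussianResponse(pc2@values, params@mu2, params@sigma2)
  mx <- max(s, na.rm = TRUE)
  stopIfNot(is.finite(mx) && mx > 0, "suitability surface has no mass")
  GridRaster(s / mx, pc1@spec)
}

#' Threshold a suitability surface into a binary range
#'
#' Presence iff suitability `>= threshold` (boundary inclusive); nodata
#' propagates.
#'
#' @param suitability [GridRaster-class] with values in `[0, 1]`
#' @param threshold cut in (0, 1), default 0.2
#' @return binary [GridRaster-class] (1 presence / 0 absence)
#' @examples
#' r <- GridRaster(matrix(c(0.1, 0.2, 0.5, 0.9), 2, 2), GridSpec(2, 2))
#' gridValues(thresholdRange(r, 0.2))
#' @export
thresholdRange <- function(suitability, threshold = 0.2) {
  v <- suitability@values
  ok <- !is.na(v)
  stopIfNot(all(v[ok] >= 0 & v[ok] <= 1),
            "suitability values must lie in [0, 1]")
  b <- v
  b[ok] <- as.numeric(v[ok] >= threshold)
  GridRaster(b, suitability@spec)
}

#' Build a virtual species on an environmental stack
#'
#' Composes the full construction: PCA of the (standardised) stack, Gaussian
#' responses on the first two standardised axes with optimum `(0, 0)` and a
#' breadth set by the specialisation level, multiplicative combination
#' rescaled to max 1, and thresholding at `threshold` into the binary true
#' range.  Deterministic given the stack and label.
#'
#' @param stack an [EnvStack-class] (>= 2 non-degenerate layers)
#' @param label one of [SPECIALISATION_LEVELS]
#' @param threshold suitability cut (default 0.2)
#' @param resolution tag stored on the species (`"high"` / `"low"`)
#' @return a [VirtualSpecies-class]
#' @examples
#' stack <- generateEnvStack(GridSpec(60, 60), 4, seed = 1)
#' sp <- makeSpecies(stack, "generalist")
#' sp
#' @export
makeSpecies <- function(stack, label, threshold = 0.2,
                        resolution = "high") {
  params <- NicheParams(label, threshold = threshold)
  pcs <- pcaScores(stack, 2)
  suit <- buildSuitability(pcs$scores$PC1, pcs$scores$PC2, params)
  VirtualSpecies(params, suit, resolution = resolution)
}

#' Write a virtual species to disk
#'
#' Writes the suitability and true-range rasters as `.asc` files plus a
#' YAML sidecar with the niche parameters.
#'
#' @param species a [VirtualSpecies-class]
#' @param dir output directory (created if absent)
#' @return the directory, invisibly
#' @export
writeSpecies <- function(species, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeAsc(species@suitability, file.path(dir, "suitability.asc"))
  writeAsc(species@trueRange, file.path(dir, "true_range.asc"))
  p <- species@params
  yaml::write_yaml(
    list(
      label = p@label, mu = c(p@mu1, p@mu2),
      sigma = c(p@sigma1, p@sigma2),
      threshold = p@threshold, resolution = species@resolution
    ),
    file.path(dir, "species.yaml")
  )
  invisible(dir)
}
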