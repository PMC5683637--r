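#' @include sdm-engine.R occurrence-sampler.R
NULL

#' Area under the ROC curve
#'
#' Rank (Mann-Whitney) formulation: the probability that a randomly chosen
#' presence outranks a randomly chosen absence, with ties counted one half.
#' Ranges from 0 to 1; 0.5 is no better than random.
#'
#' @param scores numeric prediction scores
#' @param labels 0/1 labels (1 = presence)
#' @return AUC in `[0, 1]`
#' @examples
#' aucScore(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0)) # 1: perfect separation
#' @export
aucScore <- function(scores, labels) {
  stopIfNot(length(scores) == length(labels),
            "scores and labels must have equal length")
  labels <- as.numeric(labels)
  np <- sum(labels == 1)
  na <- sum(labels == 0)
  if (np == 0 || na == 0)
    stop("AUC undefined: both classes must be present", call. = FALSE)
  r <- rank(scores) # midranks handle ties as 1/2
  (sum(r[labels == 1]) - np * (np + 1) / 2) / (np * na)
}

#' True Skill Statistic with threshold optimisation
#'
#' `TSS = sensitivity + specificity - 1` at the threshold maximising it;
#' candidate thresholds are the observed scores plus 0 and 1, with a
#' prediction counted positive when `score >= threshold`.  Ties on the
#' maximum are broken toward the lower threshold.  TSS ranges from -1 to 1;
#' values at or below 0 are no better than random.
#'
#' @inheritParams aucScore
#' @return list with `tss`, `threshold`, `sensitivity`, `specificity`
#' @examples
#' tssScore(c(0.9, 0.8, 0.4, 0.3), c(1, 1, 0, 0))$tss # 1
#' @export
tssScore <- function(scores, labels) {
  stopIfNot(length(scores) == length(labels),
            "scores and labels must have equal length")
  labels <- as.numeric(labels)
  np <- sum(labels == 1)
  na <- sum(labels == 0)
  if (np == 0 || na == 0)
    stop("TSS undefined: both classes must be present", call. = FALSE)
  cuts <- sort(unique(c(0, scores, 1)))
  best <- list(tss = -Inf)
  for (t in cuts) { # ascending, so the first maximum is the lowest cut
    pos <- scores >= t
    sens <- sum(pos & labels == 1) / np
    spec <- sum(!pos & labels == 0) / na
    tss <- sens + spec - 1
    if (tss > best$tss)
      best <- list(tss = tss, threshold = t, sensitivity = sens,
                   specificity = spec)
  }
  best
}

pairedCells <- function(r1, r2) {
  if (!sameGrid(r1@spec, r2@spec))
    stop("rasters must share one grid", call. = FALSE)
  v1 <- as.vector(r1@values)
  v2 <- as.vector(r2@values)
  ok <- !is.na(v1) & !is.na(v2)
  list(x = v1[ok], y = v2[ok])
}

#' Schoener's D niche overlap
#'
#' Each surface is normalised to sum 1 over the shared non-nodata cells and
#' compared as a distribution: `D = 1 - 0.5 * sum(|p1 - p2|)`.  0 means no
#' overlap, 1 complete overlap; D is invariant to multiplying either
#' surface by a positive constant.
#'
#' @param r1,r2 [GridRaster-class]s on one grid with non-negative values
#'   and positive total mass
#' @return D in `[0, 1]`
#' @examples
#' a <- GridRaster(matrix(runif(16), 4, 4), GridSpec(4, 4))
#' schoenersD(a, a) # 1
#' @export
schoenersD <- function(r1, r2) {
  p <- pairedCells(r1, r2)
  stopIfNot(all(p$x >= 0) && all(p$y >= 0),
            "Schoener's D needs non-negative surfaces")
  s1 <- sum(p$x)
  s2 <- sum(p$y)
  if (s1 <= 0 || s2 <= 0)
    stop("Schoener's D undefined for zero-mass surfaces", call. = FALSE)
  1 - 0.5 * sum(abs(p$x / s1 - p$y / s2))
}

#' Overall concordance correlation coefficient (two surfaces)
#'
#' For two rasters the OCCC reduces to Lin's concordance correlation:
#' `2 * s12 / (s1^2 + s2^2 + (m1 - m2)^2)` with population (n-denominator)
#' moments over the paired non-nodata cells.  It penalises both
#' decorrelation and location/scale shift: 1 means perfect agreement, 0
#' none; negative values indicate discordance and are returned unclamped.
#'
#' @param r1,r2 [GridRaster-class]s on one grid with >= 2 paired cells, not
#'   both constant
#' @return OCCC in `[-1, 1]`
#' @examples
#' a <- GridRaster(matrix(rnorm(16), 4, 4), GridSpec(4, 4))
#' occc(a, a) # 1
#' @export
occc <- function(r1, r2) {
  p <- pairedCells(r1, r2)
  n <- length(p$x)
  stopIfNot(n >= 2, "need at least 2 paired non-nodata cells")
  m1 <- mean(p$x)
  m2 <- mean(p$y)
  s1 <- mean((p$x - m1)^2)
  s2 <- mean((p$y - m2)^2)
  s12 <- mean((p$x - m1) * (p$y - m2))
  denom <- s1 + s2 + (m1 - m2)^2
  if (denom == 0)
    stop("OCCC undefined: both rasters constant and equal", call. = FALSE)
  2 * s12 / denom
}

#' Evaluate a score vector against labels
#'
#' Convenience wrapper returning one evaluation record (AUC, TSS and its
#' optimising threshold, sensitivity, specificity).
#'
#' @inheritParams aucScore
#' @param mode `"standard"` (cross-validation holdout) or `"independent"`
#' @return one-row data.frame with columns `auc`, `tss`, `tssThreshold`,
#'   `sensitivity`, `specificity`, `mode`
#' @export
evaluateScores <- function(scores, labels, mode = "standard") {
  t <- tssScore(scores, labels)
  data.frame(
    auc = aucScore(scores, labels),
    tss = t$tss, tssThreshold = t$threshold,
    sensitivity = t$sensitivity, specificity = t$specificity,
    mode = mode
  )
}

#' Independent evaluation against the true ranges
#'
#' Samples `nEval` fresh presences and `nEval` true absences from the
#' species' known ranges (via [samplePresences()] / [sampleAbsences()]),
#' scores them, and returns AUC/TSS with `mode = "independent"` — the
#' evaluation an empirical study cannot do, possible here because the true
#' range is known.
#'
#' @param model a [FittedSDM-class], or a [GridRaster-class] used directly
#'   as the score surface (e.g. the species' own true suitability, the
#'   ideal-limit scorer)
#' @param species a [VirtualSpecies-class]
#' @param nEval evaluation points per class
#' @param seed integer seed
#' @param stack predictor [EnvStack-class]; required when `model` is a
#'   [FittedSDM-class]
#' @return one-row data.frame as in [evaluateScores()]
#' @export
independentEvaluation <- function(model, species, nEval = 500, seed = 1,
                                  stack = NULL) {
  pres <- samplePresences(species, n = nEval,
                          seed = deriveSeed(seed, "evalpres"))
  abs <- sampleAbsences(species, n = nEval,
                        seed = deriveSeed(seed, "evalabs"))
  pts <- rbind(pres, abs)
  labels <- c(rep(1, nrow(pres)), rep(0, nrow(abs)))
  scores <- scorePoints(model, pts, stack)
  evaluateScores(scores, labels, mode = "independent")
}

scorePoints <- function(model, pts, stack = NULL) {
  if (is(model, "GridRaster")) {
    rc <- cellFromXY(model@spec, pts$x, pts$y)
    model@values[rc]
  } else if (is(model, "FittedSDM")) {
    stopIfNot(!is.null(stack),
              "a predictor stack is required to score a FittedSDM")
    feat <- extractFeatures(stack, pts)
    stopIfNot(nrow(feat) == nrow(pts),
              "evaluation points fell in nodata cells")
    predictScores(model, feat)
  } else {
    stop("model must be a FittedSDM or a GridRaster", call. = FALSE)
  }
}
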