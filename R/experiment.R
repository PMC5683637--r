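#' @include metrics.R
NULL

#' Factorial experiment configuration
#'
#' The full design crosses species specialisation (4 levels), SDM algorithm
#' (5), grid resolution (high/low), occurrence sample size
#' (5, 10, 20, 50, 100, 200) and positional-accuracy level (0-3); each cell
#' runs `kFolds * nReplicates` (default 25) model fits, giving
#' 4 * 5 * 2 * 6 * 4 * 25 = 24,000 rows at the defaults.  All randomness
#' derives deterministically from `masterSeed` per cell, so any subset of
#' cells reproduces independently of execution order.
#'
#' @param speciesLabels subset of [SPECIALISATION_LEVELS]
#' @param algorithms subset of [SDM_ALGORITHMS]
#' @param resolutions names of the stacks to model on (conventionally
#'   `"high"`, `"low"`)
#' @param sampleSizes occurrence counts
#' @param precisionLevels positional-accuracy levels (0 precise ... 3)
#' @param kFolds,nReplicates,backgroundSize cross-validation plan
#' @param masterSeed integer master seed
#' @param aucCut,tssCut good-model cuts (median AUC >= 0.7 or median
#'   TSS >= 0.4)
#' @param nEval independent-evaluation points per class
#' @param vifThreshold stepwise VIF cut applied to each stack before
#'   modelling (`Inf` disables)
#' @param independentEval compute independent AUC/TSS per run?
#' @param hyper named list of per-algorithm hyperparameter overrides,
#'   e.g. `list(GBM = list(nrounds = 100))`
#' @return a list with class `"experimentConfig"`
#' @export
experimentConfig <- function(speciesLabels = SPECIALISATION_LEVELS,
                             algorithms = SDM_ALGORITHMS,
                             resolutions = c("high", "low"),
                             sampleSizes = c(5, 10, 20, 50, 100, 200),
                             precisionLevels = 0:3,
                             kFolds = 5, nReplicates = 5,
                             backgroundSize = 1000,
                             masterSeed = 1,
                             aucCut = 0.7, tssCut = 0.4,
                             nEval = 500,
                             vifThreshold = 10,
                             independentEval = TRUE,
                             hyper = list()) {
  stopIfNot(length(speciesLabels) > 0 && length(algorithms) > 0 &&
            length(resolutions) > 0 && length(sampleSizes) > 0 &&
            length(precisionLevels) > 0,
            "all factor lists must be non-empty")
  structure(
    list(
      speciesLabels = match.arg(speciesLabels, SPECIALISATION_LEVELS,
                                several.ok = TRUE),
      algorithms = match.arg(algorithms, SDM_ALGORITHMS, several.ok = TRUE),
      resolutions = resolutions,
      sampleSizes = sampleSizes,
      precisionLevels = sort(as.integer(precisionLevels)),
      kFolds = kFolds, nReplicates = nReplicates,
      backgroundSize = backgroundSize,
      masterSeed = as.integer(masterSeed),
      aucCut = aucCut, tssCut = tssCut,
      nEval = nEval, vifThreshold = vifThreshold,
      independentEval = isTRUE(independentEval),
      hyper = hyper
    ),
    class = "experimentConfig"
  )
}

#' Run the factorial virtual-ecologist experiment
#'
#' For every design cell: build (or reuse) the virtual species on the
#' resolution's stack, sample `n` presences with the binomial acceptance
#' rule, degrade their positions to the cell's precision level, run the
#' replicated cross-validation, and collect per run the standard
#' (holdout) AUC/TSS, the independent AUC/TSS against fresh truth samples,
#' and the agreement (Schoener's D, OCCC) of the predicted surface with the
#' true continuous suitability.  When level 0 is part of the design, each
#' imprecise run's surface is additionally compared with the corresponding
#' precise run's surface (`dVsPrecise`, `occcVsPrecise`).
#'
#' Precision levels are processed in ascending order; cells are otherwise
#' independent and their seeds derive from `masterSeed` and the cell's
#' factor levels only, so results do not depend on execution order.
#' Failures in a cell are logged (attribute `"failures"`) and the run
#' continues.
#'
#' @param config an [experimentConfig()]
#' @param stacks named list of [EnvStack-class]s, one per resolution in
#'   `config$resolutions` (full stacks; VIF reduction happens here)
#' @return data.frame with one row per model run (the results table);
#'   attributes `"failures"` (data.frame) and `"config"`
#' @export
runExperiment <- function(config, stacks) {
  stopIfNot(all(config$resolutions %in% names(stacks)),
            "stacks must be supplied for every resolution")
  reduced <- lapply(config$resolutions, function(res) {
    if (is.finite(config$vifThreshold))
      vifStep(stacks[[res]], threshold = config$vifThreshold)
    else stacks[[res]]
  })
  names(reduced) <- config$resolutions
  species <- list()
  for (res in config$resolutions)
    for (lab in config$speciesLabels)
      species[[paste(res, lab)]] <-
        makeSpecies(stacks[[res]], lab, resolution = res)

  rows <- list()
  failures <- list()
  precise <- new.env(parent = emptyenv())
  for (res in config$resolutions) {
    stack <- reduced[[res]]
    spec <- gridSpec(stack)
    for (lab in config$speciesLabels) {
      sp <- species[[paste(res, lab)]]
      truth <- suitability(sp)
      for (alg in config$algorithms) {
        for (n in config$sampleSizes) {
          for (lev in config$precisionLevels) {
            cellSeed <- deriveSeed(config$masterSeed, lab, alg, res, n, lev)
            cellId <- paste(lab, alg, res, n, sep = "|")
            res1 <- tryCatch(
              runCell(config, stack, spec, sp, truth, lab, alg, res, n,
                      lev, cellSeed, cellId, precise),
              error = function(e) e
            )
            if (inherits(res1, "error")) {
              failures[[length(failures) + 1L]] <- data.frame(
                species = lab, algorithm = alg, resolution = res,
                sampleSize = n, precisionLevel = lev,
                message = conditionMessage(res1)
              )
            } else {
              rows[[length(rows) + 1L]] <- res1
            }
          }
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- if (length(failures)) do.call(rbind, failures)
    else data.frame()
  attr(out, "config") <- config
  out
}

runCell <- function(config, stack, spec, sp, truth, lab, alg, res, n, lev,
                    cellSeed, cellId, precise) {
  pres <- samplePresences(sp, n = n, seed = deriveSeed(cellSeed, "pres"))
  occ <- degradePositions(pres, lev, spec,
                          seed = deriveSeed(cellSeed, "degrade"))
  plan <- cvPlan(config$kFolds, config$nReplicates, config$backgroundSize,
                 seed = deriveSeed(cellSeed, "cv"))
  runs <- crossValidate(alg, occ, stack, plan,
                        hyper = config$hyper[[alg]] %||% list())
  surfKey <- function(r, f) paste(cellId, r, f)
  out <- lapply(runs, function(run) {
    std <- evaluateScores(run$scores, run$labels, mode = "standard")
    surf <- predictSurface(run$model, stack)
    if (lev == 0L)
      assign(surfKey(run$replicate, run$fold), surf, envir = precise)
    row <- data.frame(
      species = lab, algorithm = alg, resolution = res,
      sampleSize = n, precisionLevel = lev,
      replicate = run$replicate, fold = run$fold,
      auc = std$auc, tss = std$tss, tssThreshold = std$tssThreshold,
      sensitivity = std$sensitivity, specificity = std$specificity,
      aucIndep = NA_real_, tssIndep = NA_real_,
      dTruth = schoenersD(surf, truth),
      occcTruth = occc(surf, truth),
      dVsPrecise = NA_real_, occcVsPrecise = NA_real_
    )
    if (config$independentEval) {
      ind <- independentEvaluation(
        run$model, sp, nEval = config$nEval,
        seed = deriveSeed(cellSeed, "indep", run$replicate, run$fold),
        stack = stack
      )
      row$aucIndep <- ind$auc
      row$tssIndep <- ind$tss
    }
    key <- surfKey(run$replicate, run$fold)
    if (lev > 0L && exists(key, envir = precise)) {
      ref <- get(key, envir = precise)
      row$dVsPrecise <- schoenersD(surf, ref)
      row$occcVsPrecise <- occc(surf, ref)
    }
    row
  })
  do.call(rbind, out)
}

#' Summarise a results table
#'
#' Per group: the median and inter-quartile range of every metric column
#' present, plus the good-model flag: median AUC >= `aucCut` *or* median
#' TSS >= `tssCut` (boundary inclusive).  `on = "independent"` bases the
#' flag on the independent metrics instead of the standard ones.
#'
#' @param results results data.frame from [runExperiment()]
#' @param groupBy character vector of grouping columns
#' @param aucCut,tssCut good-model cuts
#' @param on `"standard"` or `"independent"`: which metrics drive the flag
#' @return data.frame with one row per group: grouping columns,
#'   `median_*` / `iqr_*` per metric, `nRuns`, and `good`
#' @export
summarizeResults <- function(results, groupBy = c("species", "algorithm",
                                                  "sampleSize"),
                             aucCut = 0.7, tssCut = 0.4,
                             on = c("standard", "independent")) {
  on <- match.arg(on)
  missing <- setdiff(groupBy, names(results))
  if (length(missing))
    stop("grouping factor(s) not in results: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!nrow(results)) stop("results table is empty", call. = FALSE)
  metricCols <- intersect(
    c("auc", "tss", "sensitivity", "specificity", "aucIndep", "tssIndep",
      "dTruth", "occcTruth", "dVsPrecise", "occcVsPrecise"),
    names(results)
  )
  groups <- split(results, results[groupBy], drop = TRUE, sep = "\r")
  out <- lapply(groups, function(g) {
    row <- g[1, groupBy, drop = FALSE]
    for (m in metricCols) {
      row[[paste0("median_", m)]] <- stats::median(g[[m]], na.rm = TRUE)
      row[[paste0("iqr_", m)]] <- stats::IQR(g[[m]], na.rm = TRUE)
    }
    row$nRuns <- nrow(g)
    aucMed <- row[[if (on == "standard") "median_auc" else "median_aucIndep"]]
    tssMed <- row[[if (on == "standard") "median_tss" else "median_tssIndep"]]
    row$good <- (!is.na(aucMed) && aucMed >= aucCut) ||
      (!is.na(tssMed) && tssMed >= tssCut)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Minimum sample size for a good model
#'
#' Scans the summary for each species x algorithm (or any other grouping)
#' and reports the smallest sample size whose group is flagged good;
#' `NA` means no sample size qualified.
#'
#' @param summary output of [summarizeResults()] grouped by (at least)
#'   `per` and `sampleSize`
#' @param per identifying columns (default species and algorithm)
#' @return data.frame with `per` columns and `minSampleSize`
#' @export
minSampleSize <- function(summary, per = c("species", "algorithm")) {
  stopIfNot(all(c(per, "sampleSize", "good") %in% names(summary)),
            "summary must contain ", paste(per, collapse = ", "),
            ", sampleSize and good columns")
  groups <- split(summary, summary[per], drop = TRUE, sep = "\r")
  out <- lapply(groups, function(g) {
    row <- g[1, per, drop = FALSE]
    goodN <- sort(g$sampleSize[g$good])
    row$minSampleSize <- if (length(goodN)) goodN[1] else NA_real_
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
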