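#' @include experiment.R
NULL

#' One-sample Wilcoxon signed-rank test
#'
#' Tests whether `values` are symmetric about `mu0` (two-sided).  Exact
#' zero differences are dropped before ranking (Wilcoxon's original
#' policy); the null distribution is exact for n <= 25 tie-free
#' differences and a normal approximation with continuity correction
#' otherwise.  Used to compare the 25 standard cross-validation metrics of
#' a configuration against its independent metric.
#'
#' @param values numeric sample
#' @param mu0 hypothesised centre
#' @return list with `statistic` (signed-rank V), `p.value`, `n` (non-zero
#'   differences used), `exact` (logical)
#' @examples
#' wilcoxonOneSample(c(0.72, 0.74, 0.71, 0.75, 0.73), mu0 = 0.7)
#' @export
wilcoxonOneSample <- function(values, mu0 = 0) {
  d <- values - mu0
  d <- d[d != 0]
  if (!length(d))
    stop("all differences from mu0 are zero; test undefined", call. = FALSE)
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  ht <- suppressWarnings(stats::wilcox.test(
    d, mu = 0, exact = exact, correct = TRUE
  ))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       n = length(d), exact = exact)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney test for a location difference between two
#' samples; exact for small tie-free samples, otherwise the normal
#' approximation with tie correction and continuity correction.  Used to
#' compare the standard metrics at high versus low grid resolution.
#'
#' @param a,b numeric samples
#' @return list with `statistic` (rank-sum W), `p.value`, `exact`
#' @examples
#' wilcoxonTwoSample(c(1, 2, 3), c(4, 5, 6))
#' @export
wilcoxonTwoSample <- function(a, b) {
  stopIfNot(length(a) >= 1 && length(b) >= 1,
            "both samples must be non-empty")
  exact <- (length(a) + length(b)) < 50 && !any(duplicated(c(a, b)))
  ht <- suppressWarnings(stats::wilcox.test(
    a, b, exact = exact, correct = TRUE
  ))
  list(statistic = unname(ht$statistic), p.value = ht$p.value,
       exact = exact)
}

AUC_MODEL_FACTORS <- c("resolution", "algorithm", "precisionLevel",
                       "sampleSize", "species")

aucModelFrame <- function(results, factors = AUC_MODEL_FACTORS) {
  missing <- setdiff(c(factors, "auc"), names(results))
  if (length(missing))
    stop("results lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  df <- data.frame(y = exp(results$auc))
  for (f in factors) {
    v <- factor(results[[f]])
    if (nlevels(v) < 2)
      stop("factor '", f, "' has fewer than 2 levels", call. = FALSE)
    df[[f]] <- v
  }
  df
}

fitLinear <- function(df, terms) {
  f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
  fit <- stats::lm(f, data = df)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; aliased terms: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  fit
}

#' Linear factor model for exponentially transformed AUC
#'
#' Ordinary least squares on the response `exp(AUC)` with categorical
#' codings of the five design factors (sample size is categorical — the
#' design has six discrete levels); `includeInteractions = TRUE` adds all
#' two-way interactions.  Returns the AIC, adjusted R-squared and model
#' degrees of freedom (estimated parameters excluding the intercept),
#' the basis of the drop-one-factor comparison in [dropTermTable()].
#'
#' @param results results data.frame with an `auc` column and the five
#'   factors (each with >= 2 levels)
#' @param includeInteractions add all two-way interactions?
#' @return list with `model` (the `lm` fit), `aic`, `adjR2`, `df`, `terms`
#' @export
fitAucModel <- function(results, includeInteractions = FALSE) {
  df <- aucModelFrame(results)
  factors <- AUC_MODEL_FACTORS
  terms <- if (includeInteractions)
    paste0("(", paste(factors, collapse = " + "), ")^2")
  else factors
  fit <- fitLinear(df, terms)
  list(
    model = fit,
    aic = stats::AIC(fit),
    adjR2 = summary(fit)$adj.r.squared,
    df = length(stats::coef(fit)) - 1L,
    terms = terms
  )
}

#' Drop-one-factor AIC comparison table
#'
#' Fits the full model with all two-way interactions, the full additive
#' model, and the additive model minus each single factor, and tabulates
#' the degrees of freedom, AIC difference to the best model, and adjusted
#' R-squared.  For the "minus" rows the reported degrees of freedom are
#' those of the dropped factor (its number of levels minus one), so the
#' table reads as a determinants-of-performance summary.
#'
#' @param results results data.frame (see [fitAucModel()])
#' @return data.frame with columns `model`, `df`, `deltaAIC`, `adjR2`,
#'   ordered: interaction model, additive model, then one row per dropped
#'   factor
#' @export
dropTermTable <- function(results) {
  df <- aucModelFrame(results)
  factors <- AUC_MODEL_FACTORS
  fits <- list()
  fits[["full model with interactions"]] <- fitLinear(
    df, paste0("(", paste(factors, collapse = " + "), ")^2")
  )
  fits[["full model without interactions"]] <- fitLinear(df, factors)
  for (f in factors)
    fits[[paste("-", f)]] <- fitLinear(df, setdiff(factors, f))
  aics <- vapply(fits, stats::AIC, numeric(1))
  dfs <- vapply(names(fits), function(nm) {
    if (startsWith(nm, "- ")) {
      nlevels(df[[sub("^- ", "", nm)]]) - 1L
    } else {
      length(stats::coef(fits[[nm]])) - 1L
    }
  }, integer(1))
  out <- data.frame(
    model = names(fits),
    df = dfs,
    deltaAIC = aics - min(aics),
    adjR2 = vapply(fits, function(m) summary(m)$adj.r.squared, numeric(1))
  )
  rownames(out) <- NULL
  out
}

#' Wilcoxon comparison report
#'
#' The two statistical comparisons run on a results table: per
#' configuration cell, the one-sample test of the 25 standard metric values
#' against the cell's median independent metric; and per algorithm, the
#' two-sample test of the standard metric at high versus low resolution.
#'
#' @param results results data.frame from [runExperiment()]
#' @param metric `"auc"` or `"tss"`
#' @return list with data.frames `standardVsIndependent` and
#'   `highVsLowResolution`
#' @export
wilcoxonReport <- function(results, metric = c("auc", "tss")) {
  metric <- match.arg(metric)
  indep <- paste0(metric, "Indep")
  cells <- split(
    results,
    results[c("species", "algorithm", "resolution", "sampleSize",
              "precisionLevel")],
    drop = TRUE, sep = "\r"
  )
  svi <- do.call(rbind, lapply(cells, function(g) {
    row <- g[1, c("species", "algorithm", "resolution", "sampleSize",
                  "precisionLevel")]
    row$p.value <- tryCatch(
      wilcoxonOneSample(g[[metric]],
                        mu0 = stats::median(g[[indep]]))$p.value,
      error = function(e) NA_real_
    )
    row
  }))
  rownames(svi) <- NULL
  hvl <- NULL
  if (all(c("high", "low") %in% results$resolution)) {
    byAlg <- split(results, results$algorithm, drop = TRUE)
    hvl <- do.call(rbind, lapply(names(byAlg), function(a) {
      g <- byAlg[[a]]
      data.frame(
        algorithm = a,
        p.value = wilcoxonTwoSample(
          g[[metric]][g$resolution == "high"],
          g[[metric]][g$resolution == "low"]
        )$p.value
      )
    }))
  }
  list(standardVsIndependent = svi, highVsLowResolution = hvl)
}
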