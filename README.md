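# virtualSDM

A virtual-ecologist workbench for presence-background species
distribution modelling (SDM).

SDM practitioners fit models to whatever occurrence records exist —
often few, and often with imprecise coordinates — and judge them with
internal evaluation statistics, because the species' true distribution
is unknown.  `virtualSDM` is for methodologists who want to know what
those statistics are actually worth.  It simulates the entire loop on a
species whose niche and range are known exactly, so the usual
*performance* metrics (AUC, TSS) can be confronted with *reliability*
metrics computed against the truth (Schoener's D niche overlap, the
overall concordance correlation coefficient, OCCC), across a factorial
design in sample size, positional accuracy, grid resolution, algorithm,
and ecological specialisation.

## The model in brief

- **Environment**: stacks of spatially autocorrelated, deliberately
  collinear synthetic layers (smoothed Gaussian fields mixed through the
  square root of a target correlation matrix), at two grid resolutions
  linked by bilinear resampling; stepwise VIF elimination (cut 10)
  reduces the predictor set, as in standard SDM practice.
- **Species**: a Gaussian niche on the first two standardised
  principal-component axes of the environment,
  `g(x) = exp(-(x-mu)^2 / (2 sigma^2))`, multiplied across axes and
  rescaled to a maximum of 1.  Niche breadth `sigma` in
  {0.8, 0.6, 0.4, 0.2} encodes specialisation (generalist →
  specialist); suitability ≥ 0.2 defines the binary true range.
- **Occurrences**: presence cells are accepted with probability equal to
  their suitability (a 0.8 pixel is occupied in 80% of offers), true
  absences with probability 1 − suitability; positional-accuracy level
  `k` in {0,1,2,3} displaces points into the annulus `(k·w, (k+1)·w]`
  of cell widths in a uniform random direction.
- **Models**: GLM, GAM, boosted trees, random forest and a Maxent-style
  penalised logistic regression behind one fit/predict contract, under
  5-fold cross-validation × 5 background replicates (25 runs per cell).
- **Metrics**: rank AUC; TSS at the threshold maximising
  sensitivity + specificity − 1; Schoener's
  `D = 1 − ½·Σ|p1 − p2|` on normalised surfaces; OCCC = Lin's
  concordance `2·s12 / (s1² + s2² + (m1 − m2)²)`.  "Good model":
  median AUC ≥ 0.7 or median TSS ≥ 0.4.
- **Downstream statistics**: one- and two-sample Wilcoxon comparisons,
  and an AIC-ranked linear factor model of `exp(AUC)` with a
  drop-one-factor table.

## Worked example

```r
library(virtualSDM)

stack   <- generateEnvStack(GridSpec(80, 80), 10,
                            defaultEnvCorrelation(10, nPairs = 4), seed = 42)
reduced <- vifStep(stack)          # collinearity screen at VIF > 10
attr(reduced, "removed")
#>   iteration removedLayer      vif
#> 1         1        env02 86.52461
#> 2         2        env07 47.51940
#> 3         3        env03 41.21953
#> 4         4        env06 17.46254

sp  <- makeSpecies(stack, "relaxed_specialist")   # sigma = 0.4 niche
sp
#> VirtualSpecies: relaxed_specialist (high resolution)
#>   presence cells: 1518 of 6400

occ  <- samplePresences(sp, n = 50, seed = 1)     # binomial acceptance
occ3 <- degradePositions(occ, level = 3, gridSpec(stack), seed = 2)
runs <- crossValidate("RF", occ3, reduced, cvPlan(seed = 3))  # 25 runs

ev <- do.call(rbind, lapply(runs, function(r)
  evaluateScores(r$scores, r$labels)))
median(ev$auc); median(ev$tss)
#> [1] 0.59
#> [1] 0.235

surf <- predictSurface(runs[[1]]$model, reduced)
schoenersD(surf, suitability(sp)); occc(surf, suitability(sp))
#> [1] 0.535
#> [1] 0.249

independentEvaluation(runs[[1]]$model, sp, nEval = 500, seed = 4,
                      stack = reduced)[, c("auc", "tss")]
#>     auc   tss
#> 1 0.827 0.494
```

Reading: 50 heavily displaced occurrences of a moderately specialised
species give a model whose *internal* cross-validation metrics look poor
(median standard AUC 0.59 — the background overlaps the range), whose
*independent* evaluation against true absences is respectable (AUC
0.83), yet whose predicted surface agrees with the truth only partially
(D 0.54, OCCC 0.25).  Performance and reliability are different
questions — which is the point of the package.

The full factorial design is one call
(`runExperiment(experimentConfig(...), stacks)`), returning a
one-row-per-run results table for `summarizeResults()`,
`minSampleSize()`, `wilcoxonReport()`, `fitAucModel()` and
`dropTermTable()`.

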