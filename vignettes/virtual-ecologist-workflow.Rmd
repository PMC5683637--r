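---
title: "Benchmarking presence-background SDMs with virtual species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking presence-background SDMs with virtual species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(virtualSDM)
```

## The problem

Species distribution models (SDMs) relate species occurrence records to
environmental predictors in order to map habitat suitability.  With real
species the true distribution is unknown, so the effect of noisy input
data — few occurrence records, imprecise coordinates — on model *output*
can only be judged indirectly.  The virtual-ecologist approach replaces
the real species with a simulated one whose niche and range are known
exactly, runs the ordinary SDM workflow on data sampled from that known
truth, and measures both *performance* (how well the model separates
presences from absences: AUC, TSS) and *reliability* (how close the
predicted surface is to the truth: Schoener's D, the overall concordance
correlation coefficient).  The two families of metrics can, and do,
disagree — that divergence is the scientific payoff of the design.

`virtualSDM` implements this loop end to end: synthetic environments,
virtual species at four specialisation levels, occurrence sampling with
positional-error injection, five SDM algorithm families under replicated
cross-validation, the metric suite, and the downstream Wilcoxon and
AIC factor analyses.

## The model

### Synthetic environments

`generateEnvStack()` builds a stack of environmental layers on a planar
grid.  Each layer starts as Gaussian white noise, smoothed with a
separable Gaussian kernel (`smoothness`, in cell units — the spatial
autocorrelation length), optionally blended with a random-orientation
linear gradient (`gradientWeight`, default 0.5) that gives the landscape
large-scale structure.  Collinearity between layers — the situation that
makes VIF filtering meaningful — is induced by mixing the independent
fields through the symmetric square root of a target correlation matrix.
`defaultEnvCorrelation()` encodes the default structure: 27 layers with a
0.2 baseline correlation and twelve 0.975-correlated pairs, so that
stepwise VIF elimination at the conventional threshold of 10 retains
roughly 15 of 27 layers, emulating a realistic climatic predictor set.
That retained count is a property of the fixture, not a guarantee; it
drifts with grid size and smoothing because the effective sample size of
the empirical correlations is finite.

Two grid resolutions are related by an integer linear factor (default 4,
mirroring 2.5 vs 10 arc-minute grids); `bilinearResample()` moves layers
between them by bilinear interpolation of the four surrounding cell
centres, clamping at the extent edge and propagating nodata.

### Virtual species

The niche lives on the first two principal-component axes of the
(z-standardised) stack.  The PC score surfaces are re-standardised to
mean 0, unit variance, and sign-fixed (largest-magnitude loading
positive) so niches are reproducible across runs and niche breadths are
expressed in axis-standard-deviation units.  Whether the original
analysis rescaled its axes before applying breadths is not stated
anywhere we could check; unit variance is the interpretation under which
"a breadth of 0.8 covers 80% of the environmental range" is closest to
literal, and it is the convention used throughout this package.

Each axis contributes a Gaussian response
$g(x) = \exp(-(x - \mu)^2 / 2\sigma^2)$ with a common optimum at the
origin; the suitability surface is the *product* of the two responses
(one hostile axis keeps suitability low no matter how good the other
is), rescaled by its maximum so the best cell scores exactly 1.  The
rescaling matters: without it, a narrow niche's raw product could fall
entirely below the range threshold and the specialist would have no
range at all.  Specialisation levels map to breadths
$\sigma \in \{0.8, 0.6, 0.4, 0.2\}$ (generalist, restricted generalist,
relaxed specialist, specialist), isotropic across the two axes since no
axis-specific values are available.  The binary true range is
`suitability >= 0.2`, boundary inclusive.

```{r species, eval = FALSE}
stack <- generateEnvStack(GridSpec(100, 100), 27,
                          defaultEnvCorrelation(27), seed = 1)
sp <- makeSpecies(stack, "specialist")
sp
```

### Occurrence sampling and positional error

Presences are sampled by rejection: a presence-region cell is offered
uniformly at random and accepted with probability equal to its
suitability, so a pixel with suitability 0.8 is occupied in 80% of
offers and sampling frequencies are proportional to suitability.
Absences mirror the rule with probability $1 -$ suitability.  (The prose
this rule descends from states the comparison in one direction and
glosses it in the other; the gloss — higher suitability, more likely
present — is the only reading consistent with the design's intent, and
is what is implemented.)  Points are placed uniformly within their cell.
`samplePresences()` supports both a fixed accepted count `n` and a fixed
survey effort `nOffers`.

Positional error (`degradePositions()`) displaces each point in a
uniformly random direction by a distance drawn uniformly from the
annulus $(kw, (k+1)w]$, $w$ the cell width, for imprecision level
$k \in \{1,2,3\}$; level 0 is the identity.  "Outside a buffer of $k$
pixels" is unbounded as stated; the annulus keeps the error magnitude
tied to the level.  Displaced points falling outside the study extent
are re-drawn rather than clipped, avoiding pile-up at the edges.  The
exact distance law and whether degraded points should snap to cell
centres are not specified anywhere; continuous coordinates in the
annulus are this package's choice.

### Modelling

Five algorithm families sit behind one `fitSDM()`/`predictScores()`
contract, so the harness never branches on the algorithm: logistic GLM
with linear and quadratic terms, logistic GAM (one smooth per predictor,
basis dimension 4), gradient-boosted trees, random forest
(class-probability output), and a Maxent-style penalised logistic
regression on linear, quadratic and hinge features of presence versus
background — the maxnet formulation, not the Java application, with a
heavily weighted background playing the role of the environment sample.
All defaults are pinned in `inst/extdata/sdm-defaults.yaml`
(`sdmDefaults()`) rather than inherited silently from the adapter
libraries: RF 500 trees; boosted trees 2500 rounds at learning rate
0.001, depth 7, subsample 0.5; Maxent regularisation multiplier 1 and 10
hinge knots per predictor.  Regression models (GLM, GAM) use
prevalence-0.5 case weights so the presence and background classes
contribute equally.

Cross-validation (`crossValidate()`) stratifies presences and background
into five folds separately — every fold contains both classes — and
repeats the split over five background replicates, each with a freshly
drawn background set of 1000 points (a size the source never states;
1000 is common presence-background practice and is configurable).  One
configuration cell therefore yields exactly 25 model runs.

### Metrics

* **AUC** — rank (Mann–Whitney) formulation, ties counted ½.
* **TSS** — sensitivity + specificity − 1, maximised over the observed
  scores plus 0 and 1 (no search-grid convention exists to follow);
  ties on the maximum resolve to the lower threshold.
* **Schoener's D** — surfaces normalised to sum 1 and compared as
  distributions, $D = 1 - \tfrac12\sum_i |p_{1,i} - p_{2,i}|$.
* **OCCC** — for two surfaces this is Lin's concordance correlation,
  $2 s_{12} / (s_1^2 + s_2^2 + (m_1 - m_2)^2)$, computed with
  population (n-denominator) moments — the convention of Lin's original
  estimator; sample-moment versions differ at small n.  Concordance can
  be negative; the signed value is returned and any clamping is left to
  reporting.

"Standard" evaluation scores the held-out fold (presences vs
background), the only evaluation an empirical study can run.
"Independent" evaluation (`independentEvaluation()`) samples fresh
presences and *true absences* from the known ranges — 500 per class by
default — and is the truth-based yardstick.  Agreement metrics are
computed against the continuous true suitability surface rather than the
binary range: the continuous comparison is strictly more informative and
matches how the predicted surfaces are produced.

### The factorial experiment

`runExperiment()` crosses species × algorithm × resolution × sample size
× precision level, with 25 runs per cell (24,000 rows at the full
default design).  Every cell's seed derives from the master seed and the
cell's factor levels alone (`deriveSeed()`), so any subset of cells
reproduces independently of execution order, and per-cell failures are
logged without aborting the run.  Precision levels run in ascending
order so each imprecise run can also be compared against its precise
(level-0) twin (`occcVsPrecise`, `dVsPrecise`).  `summarizeResults()`
applies the good-model rule — median AUC ≥ 0.7 *or* median TSS ≥ 0.4,
boundary inclusive — and `minSampleSize()` scans for the smallest
qualifying sample size.

### Statistical comparisons

`wilcoxonOneSample()` and `wilcoxonTwoSample()` wrap the exact/
approximate signed-rank and rank-sum tests (zero differences dropped,
Wilcoxon's original policy — the Pratt alternative changes p-values;
exact null for small tie-free samples).  `fitAucModel()` regresses
`exp(AUC)` on the five design factors, all categorical — sample size
included, since its six discrete levels are design levels, not a
continuous dose — optionally with all two-way interactions;
`dropTermTable()` assembles the interaction model, the additive model,
and each leave-one-factor-out model into an AIC comparison table
(`stats::AIC`, so ΔAIC is invariant to the likelihood constant).

## What the tests do and do not show

The test suite and the scaled-down reproduction run on grids of 50×50 to
100×100 cells with 4–8 synthetic layers, 200–1000 background points, and
a reduced design ({generalist, specialist} × {GLM, RF} × n ∈ {10, 200} ×
levels {0, 3}, 25 runs per cell) — sizes chosen so the whole suite runs
in a couple of minutes on one core while every qualitative contrast of
interest is still measurable.  On those fixtures the package reproduces
the qualitative pattern that motivates the design: agreement with the
truth improves with sample size at every specialisation level; the
specialist loses more agreement to positional error than the generalist
(a contrast measured at the largest sample size, where imprecise points
are numerous — at n = 10 fold-level sampling noise dominates it); and a
generalist can be modelled usefully (median independent AUC ≥ 0.7) from
as few as 10 occurrences.

The synthetic environment is stationary, isotropic, gap-free and
planar.  It does not emulate coastlines or nodata holes (supported by
the data structures, but not generated), elevation-like heavy-tailed
marginals, anisotropic autocorrelation, or the particular correlation
geometry of real climate surfaces.  Passing tests therefore demonstrate
the internal consistency of the workflow and the reproducibility of the
specialisation/sample-size/precision effects on a known truth — not that
any particular real-world dataset would yield the same minimum sample
sizes.  Two further caveats: the standard holdout AUC of a widespread
species is bounded well below 1 (much of the background is genuine
habitat), so cross-study comparisons of standard metrics are exactly as
treacherous here as in the field; and the Maxent adapter is a penalised
logistic approximation, not the reference Java implementation.

## Numerical choices and degenerate inputs

* Thresholding and the good-model rule are boundary-inclusive (`>=`).
* PCA on a stack with a constant layer, agreement between zero-mass or
  twin-constant surfaces, metrics with a single class, and fits with a
  single label class all raise informative errors rather than NaN.
* Perfect collinearity reports `VIF = Inf` (not an error); the stepwise
  eliminator breaks ties toward the earliest layer, and on large grids
  computes VIF on a deterministic 50,000-cell subsample.
* Acceptance sampling stalls (everything rejected) are capped and
  reported; annulus re-draws are likewise capped.
* All Monte-Carlo tolerances in the tests are set from the sampling
  error of the check itself (binomial error at n = 10,000, rank-statistic
  error at n = 5,000), not from what the implementation happens to emit.
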