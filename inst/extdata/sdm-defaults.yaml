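# Pinned default settings for the five SDM algorithm families.
# Committing these (rather than inheriting library defaults silently)
# keeps every run reproducible across library versions.
background_size: 1000
k_folds: 5
n_background_replicates: 5
algorithms:
  GLM:
    terms: linear_quadratic     # logistic regression, linear + quadratic
  GAM:
    k: 4                        # smooth basis dimension per predictor
  GBM:
    nrounds: 2500               # boosted-tree defaults in the biomod2 style
    eta: 0.001
    max_depth: 7
    subsample: 0.5
  RF:
    ntree: 500
  MAXENT:
    regmult: 1                  # regularisation multiplier
    n_hinge_knots: 10           # hinge knots per predictor (both directions)
    weight_background: 100      # background weight in the weighted logistic
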