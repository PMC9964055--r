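# Demonstration configuration: a full synthetic QSRR study small enough to
# rerun in minutes. The generator defaults emulate a ~97-compound,
# 239-descriptor, five-pH chromatographic dataset; the planted structural
# outlier is forced into the external test set so the applicability-domain
# report exercises the Out path. Grids are deliberately compact (rows are
# aligned columns, already crossed).
seed: 42
transform: log
n_test: 10
force_outlier_test: true
sim: {}
pipeline:
  folds: 5
  cfs:
    max_features: 20
  rfe:
    learner: LASSO
    subset_sizes: [5, 10, 20, 40]
    folds: 5
  grids:
    LASSO:
      lambda: [0.001, 0.00316, 0.01, 0.0316, 0.1, 0.316, 1.0]
    # SVR_RBF deliberately keeps its default grid: the kernel-width scale
    # heuristic must be computed on the model's own (post-selection)
    # feature subset, so a fixed gamma cannot be written here.
    RF:
      num_trees: 300
      mtry: [15, 79]
    GBR:
      nrounds: [150, 300, 150, 300]
      max_depth: [2, 2, 3, 3]
      eta: 0.1
  stack:
    mode: out_of_fold
    folds: 5
  ad:
    k: 5
    percentile: 95
    # conjunctive aggregation: a compound is outside the domain only when
    # it is out at every pH. A structural outlier sits outside the cloud at
    # all conditions; per-pH threshold exceedances of in-distribution
    # compounds (expected at ~5% per pH by construction of the 95th
    # percentile) are not escalated to the overall flag.
    aggregate: all
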