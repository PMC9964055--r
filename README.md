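# qsrrkit

Retention-time QSRR modeling for reversed-phase liquid chromatography
(RPLC): pH-dependent molecular descriptors, feature selection, a tuned
five-learner lineup, two-level stacking, and a k-nearest-neighbour
applicability domain — with a seeded synthetic-data generator so the whole
pipeline is testable end to end without proprietary chromatographic data.

## Who this is for

Analytical chemists and cheminformaticians who want to predict small-
molecule retention times across mobile-phase pH conditions from molecular
descriptors, on the small datasets (tens of compounds, hundreds of
descriptors) that dominate this field — and who need the modeling
hygiene that regime demands: leak-free standardization, cross-validated
selection and tuning, external validation, and an explicit applicability
domain for new compounds.

## The core methods

**pH-dependent descriptors.** A molecule's descriptors at pH `x` are the
microspecies-fraction-weighted average over its protonation states,
`d_j(pH) = Σ_s f_s(pH) d_{j,s}`, with fractions from the sequential
Henderson–Hasselbalch ladder (or supplied externally), plus logD at that
pH as an extra descriptor.

**Model lineup.** MLR and RBF-kernel SVR coupled with correlation-based
(CFS, Hall's merit, greedy forward search) and recursive-feature-
elimination (RFE, CV-scored sizes with a one-SE parsimony rule) selection;
LASSO, random forest and gradient boosting on all descriptors. Every
model is tuned by exhaustive grid search under seeded 10-fold CV
minimizing RMSE.

**Stacking.** A linear meta-learner combines the five base learners'
predictions; the meta-training matrix is built out-of-fold by default (a
leaky train-on-external variant is retained, with warnings, for fidelity
experiments).

**Applicability domain.** Each query compound's mean Euclidean distance to
its k = 5 nearest training compounds in standardized descriptor space is
compared with the 95th percentile of the training compounds' own
leave-self-out distances; beyond the threshold, the prediction is flagged
`Out` and should not be trusted.

## Worked example

The bundled configuration runs a complete synthetic study — 97 compounds,
239 block-correlated descriptors, five pH conditions, one planted
structural outlier forced into the 10-compound external set:

```r
library(qsrrkit)

run <- run_qsrr(system.file("extdata", "config_demo.yaml",
                            package = "qsrrkit"),
                out_dir = "results")
run
#> <qsrr_run> 5 pH conditions, 67 train / 10 external compounds
#>   mean ranks (external RMSE):
#>    model mean_rank
#>  SVR_CFS       1.2
#>  SVR_RFE       2.4
#>      GBM       3.2
#>       RF       3.6
#>    Stack       5.8
#>  MLR_CFS       6.2
#>    Lasso       6.4
#>  MLR_RFE       7.2
```

The mean rank averages each model's within-pH rank by external RMSE over
the five pH conditions (1 = best). On this draw the kernel and tree
learners lead — the synthetic truth contains an interaction term that
linear models cannot represent.

```r
dplyr::select(run$ad_report, compound_id, distance_pH2.7,
              threshold_pH2.7, applicability)
#> # A tibble: 10 x 4
#>    compound_id distance_pH2.7 threshold_pH2.7 applicability
#>  1 C002                  18.2            20.2 In
#>  2 C004                 155.0            20.2 Out     <- planted outlier
#>  3 C027                  17.5            20.2 In
#>  ...
```

`C004` is the planted structural outlier: its mean 5-NN distance
(155, against a threshold of ~20) puts it far outside the training cloud
at every pH, so its predictions are flagged unreliable — exactly the
behaviour the AD filter exists to provide. `autoplot(run)`,
`plot_residuals(run)` and `autoplot(run$ad_report)` draw the
observed-vs-predicted, residual and AD panels from the same tibbles.

## Package layout

- `R/simulate.R` — synthetic-data generator with full ground-truth oracle
- `R/speciation.R` — microspecies fractions, weighted descriptors
- `R/preprocess.R` — retention/zero-variance filters, autoscaling, split
- `R/feature_selection.R` — CFS, RFE, embedded LASSO, consensus
- `R/learners.R`, `R/models.R` — learner registry, grid search, importances
- `R/stacking.R` — out-of-fold stacked ensemble
- `R/ad.R` — kNN applicability domain and report
- `R/metrics.R`, `R/evaluation.R`, `R/pipeline.R` — metrics, nested CV,
  rank aggregation, `run_qsrr()` driver, benchmark
- `vignettes/qsrr-retention-modeling.Rmd` — the methods vignette
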