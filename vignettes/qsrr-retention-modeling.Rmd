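---
title: "Retention-time QSRR modeling with qsrrkit: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention-time QSRR modeling with qsrrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsrrkit)
```

## The problem

In reversed-phase liquid chromatography (RPLC), the retention time of a
small molecule is governed mainly by its lipophilicity, which in turn
depends on the molecule's protonation state and therefore on the pH of the
mobile phase. Quantitative structure-retention relationship (QSRR) models
predict retention from molecular descriptors, so that chromatographic
method development can start from in-silico screens rather than
trial-and-error gradient runs. The datasets in this domain are small —
typically under a hundred compounds, measured at a handful of pH
conditions, against a couple of hundred descriptors — which makes every
modeling decision (feature selection, tuning, validation, ensembling,
applicability assessment) a decision about overfitting.

qsrrkit implements the complete workflow for this setting:

1. pH-dependent descriptor matrices from microspecies-weighted averaging,
2. data cleaning and leak-free standardization,
3. filter (CFS), wrapper (RFE) and embedded (LASSO/tree) feature selection,
4. five base learners tuned by cross-validated grid search,
5. a two-level stacked ensemble with a linear meta-learner,
6. a k-nearest-neighbour applicability domain (AD), and
7. evaluation: cross-validated and external RMSE/R², cross-pH rank
   aggregation, residual reports.

A seeded synthetic-data generator reproduces the statistical structure of
such studies so every stage is testable without proprietary data.

## pH-dependent descriptors

A molecule with ionizable sites exists as a pH-dependent mixture of
protonation states. Descriptors computed for a single state misrepresent
the mixture, so per-state descriptor vectors are averaged with the state
population fractions as weights:

$$d_j(\mathrm{pH}) = \sum_s f_s(\mathrm{pH})\, d_{j,s}, \qquad
  f_s \ge 0,\; \sum_s f_s = 1.$$

`speciate()` computes the fractions from a *sequential macrostate ladder*
(Henderson–Hasselbalch): with pKa values sorted ascending, the state that
has lost $j$ protons has relative weight $10^{\,j\cdot\mathrm{pH} -
\sum_{i\le j}\mathrm{p}K_{a,i}}$, normalized over $j = 0..m$. Weights are
accumulated on the log10 scale with a max-shift so extreme pH cannot
overflow. The ladder is the standard reproducible approximation when full
microstate enumeration (a vendor-software capability) is unavailable;
because some workflows have access to microstate fractions,
`weighted_descriptors()` also accepts user-supplied fractions directly.
logD — the pH-dependent distribution coefficient — is consumed as an input
column per pH, not computed: predicting it well requires calibrated
commercial models, and pretending otherwise would give a false sense of
accuracy. Computing the underlying per-species descriptors from SMILES is
out of scope for the core package; profiles arrive as JSON or CSV.

## Cleaning, standardization, and the external split

Three cleaning rules, in order:

* **Retention filter** (`filter_low_retention()`): compounds eluting below
  2 min at *every* pH ride the solvent front and are removed. The rule is
  conjunctive — one pH above threshold keeps the compound.
* **Zero-variance filter** (`remove_zero_variance()`): constant descriptors
  are dropped (they carry no information and break autoscaling).
* **Autoscaling** (`standardize()`): mean-centering then unit-variance
  scaling, with parameters estimated on training compounds only and reused
  verbatim for external compounds. The external set therefore never
  influences any fitted quantity — asserted by a leakage spy in the tests.

`split_dataset()` draws a seeded external test set (default 10 compounds)
shared across all pH conditions, optionally stratified by retention
quartile, and optionally forcing named compounds (e.g. a known structural
outlier) into the external set. Retention is modeled on the log scale by
default and back-transformed to minutes for reporting: a 0–20 min gradient
produces right-skewed retention with multiplicative errors, and reported
per-compound errors in minutes then match how practitioners read
chromatograms. The transform is a configuration switch (`transform =
"none"` disables it), not a claim about any particular historical dataset.

## Feature selection

**CFS** (`cfs_select()`) runs a greedy forward search over Hall's merit
$$M(S) = \frac{k\,\overline{r}_{cf}}{\sqrt{k + k(k-1)\overline{r}_{ff}}},$$
with $\overline{r}_{cf}$ the mean absolute feature–target correlation in
the subset and $\overline{r}_{ff}$ the mean absolute pairwise correlation.
The search stops when no candidate strictly increases the merit; ties are
broken lexicographically by feature name so results are reproducible. A
plain $|r| \ge \tau$ threshold filter is available via `min_correlation`.

**RFE** (`rfe_select()`) ranks features by the wrapped learner's own
importance (absolute coefficients for linear learners, impurity for trees,
seeded permutation importance for kernel SVR), drops to each candidate
subset size directly (the caret-style sizes grid, far cheaper than
one-at-a-time elimination), and scores each size by k-fold CV RMSE.
The winning size is chosen with a one-standard-error rule: the smallest
size whose CV RMSE is within one SE of the minimum. The raw argmin is
unsuitable as a default because the CV curve is nearly flat beyond the
true support — extra noise features cost little at moderate n — so the
argmin drifts into oversized subsets; measured on sparse recovery
benchmarks the argmin's median support precision is ~0.33 against ~1.0
for the 1-SE rule at identical recall. `size_rule = "min"` restores the
strict argmin (exact ties to the smaller size).

**Embedded selection** lives in the learners: `lasso_select()` keeps the
nonzero coefficients at the CV-chosen penalty (1-SE rule by default, for
the same parsimony reason; prediction models keep the RMSE-minimizing
penalty), and `embedded_importances()` extracts ranked importances from
fitted LASSO/RF/GBM models. `consensus_features()` intersects the
selections of all methods (embedded lists truncated to their top 20) —
on retention data this intersection characteristically lands on
lipophilicity-type descriptors.

## Base learners and tuning

Five algorithms, each wrapped behind a uniform interface
(`model_config()` + `grid_search()`): multiple linear regression (only
after CFS/RFE — with more descriptors than compounds OLS is not
identifiable), LASSO (glmnet), RBF-kernel support vector regression
(e1071), random forest (ranger) and gradient-boosted trees (xgboost).
Hyperparameters are tuned by exhaustive grid search under seeded k-fold CV
(default 10-fold), minimizing the mean per-fold RMSE; ties go to the first
grid point in deterministic order, and the winner is refit on all rows.
Default grids:

| algorithm | grid |
|---|---|
| LASSO | $\lambda$ log-spaced $10^{-4}..10^{1}$, 25 points |
| SVR (RBF) | cost $\{0.25..8\}$ × $\gamma$ = scale heuristic ×$\{0.25..4\}$ × $\epsilon \in \{0.01, 0.1, 0.2\}$ |
| RF | 500 trees, mtry $\in \{p/3, \sqrt p, p/2\}$ |
| GBR | trees 100..1000 (step 150) × depth 1–3 × rate $\{0.01, 0.05, 0.1\}$ |

The SVR kernel width uses the scale heuristic $1/(p\,\overline{\mathrm{Var}})$
computed **on the model's own feature subset**. This matters: a width
calibrated to the full 239-column space is an order of magnitude too small
for a 20-feature post-RFE subset and cripples the kernel. Configs
therefore cannot fix an absolute $\gamma$ sensibly across feature sources;
leaving SVR on its default grid is the recommended (and default) choice.

## Stacking

`stack_fit()` builds the two-level ensemble: level 1 is the model lineup
(default bases: MLR+RFE, LASSO, SVR+RFE, RF, GBM), level 2 an ordinary
linear regression on their predictions. Two constructions of the
meta-training matrix are provided:

* **out_of_fold** (default): bases are refit on k−1 folds with their
  chosen hyperparameters and predict the held-out fold, so the meta-learner
  trains only on predictions from models that never saw the compound.
* **external**: the meta-learner is trained on base predictions of the
  designated external set. This reproduces a historically used but leaky
  construction — the external compounds shape the meta-coefficients, so
  external metrics of such a stack are optimistically biased. The mode
  always emits a warning and exists for fidelity experiments; the bias is
  asserted directionally in the test suite.

Collinear base predictions make the meta normal equations rank-deficient;
the fit then falls back to the minimum-norm (pseudoinverse) solution with
a warning — predictions are unchanged by how weight is split between
duplicated bases.

`stacking_benchmark()` measures the stack against the external-best single
base model over independent synthetic replicates. A finding worth stating
honestly: under the default study conditions (67 training compounds, 239
descriptors, 10-compound external set), the out-of-fold stack is *not*
reliably within 5% of the best single base. Two effects drive this. The
post-hoc best of five external-RMSE estimates on 10 compounds is a
selection-biased, optimistically low comparator; and with all bases trained
on the same 67 compounds their errors are so correlated that even an
oracle convex combination fit on the external answers improves on the best
base by at most ~5%. The stack's mean cross-pH *rank* is competitive, but
the pointwise dominance property should not be expected at this sample
size, and the package does not claim it.

## Applicability domain

`ad_distances()` computes each query compound's mean Euclidean distance to
its k nearest training compounds in the standardized descriptor space
(k = 5 by default); training compounds are scored leave-self-out, else a
k = 1 threshold would be identically zero. `ad_threshold()` takes the 95th
percentile (linear interpolation between order statistics, the common
default) of the training self-distances; `ad_classify()` flags a compound
`Out` when its distance strictly exceeds the threshold — a distance equal
to the threshold is `In`. By construction ~5% of in-distribution queries
fall `Out`; the test suite checks this calibration (5% ± 2 points over
2,000 queries) and that a 10-sd structural outlier is caught in ≥95% of
replicates.

`ad_report()` assembles the per-pH table (distance, threshold, flag per pH
plus the stacking model's back-transformed per-compound errors when run
through `run_qsrr()`). Because descriptor matrices differ across pH only
through microspecies re-weighting, per-pH distances are strongly
correlated, and the aggregate flag is configurable: `"any"` (default;
conservative: out anywhere ⇒ out overall) or `"all"` (a compound is
outside the domain only when out at every pH — the signature of a true
structural outlier, and the setting used by the bundled demo so that the
~5% per-pH false-out rate is not escalated).

## The synthetic-data generator

`qsrr_simulate()` emulates the statistical shape of a small pH-resolved
chromatographic study; its defaults are the study conditions the rest of
the package is tested under:

* 97 compounds × 239 descriptors at pH 2.7/3.5/5.0/6.5/8.0;
* equicorrelated Gaussian descriptor blocks (width 10, ρ = 0.7) — the
  simplest structure exhibiting descriptor multicollinearity; per-pH
  matrices differ by a small jitter (sd 0.05) mimicking microspecies
  re-weighting;
* a sparse true model on log-retention: 8 informative descriptors, plus
  one pairwise interaction whose standard deviation is half that of the
  linear term, so kernel/tree learners have a real, measurable edge over
  purely linear fits;
* coefficients drift across pH by a multiplicative random walk (10% per
  step);
* Gaussian noise (sd 0.12 log-units, putting the best achievable CV R²
  near the low-0.9s, comparable to well-tuned models on real data of this
  size);
* 20/97 of compounds elute below 2 min at every pH (so the default run
  reproduces a 97 → 77 → 67 + 10 flow);
* one structural outlier whose descriptors are shifted 10 sd from the
  cloud and whose descriptor-retention relationship is broken — the
  "miconazole-like" compound the AD must catch.

Noiseless regular compounds land exactly inside the 0–20 min gradient by a
per-pH affine rescaling of the latent scale; the oracle (true coefficients,
intercepts, interaction, per-compound offsets for the special compounds)
is returned with the data, so `oracle_predict()` reproduces noiseless
retention to machine precision and parameter-recovery tests can score any
selector. A single root seed drives deterministically derived per-stage
streams; identical seeds give bit-identical datasets.

What the generator does *not* emulate: real descriptor marginals (counts,
heavy tails, mixed scales), chemically structured correlation,
non-Gaussian retention noise, or any actual chemistry. Passing tests
demonstrate the pipeline's statistical machinery is correct and calibrated
under a known truth — not that any particular accuracy will be achieved on
real compounds.

## Numerical and reproducibility choices

* Every randomized step takes an integer seed; sub-stage streams are
  derived deterministically from a root seed, so adding a stage never
  perturbs another stage's draws.
* Tie-breaks are deterministic everywhere: grid order for grid search,
  lexicographic feature names for selectors, ascending size for RFE.
* `run_qsrr()` writes CSVs at full precision; two runs from the same
  config are byte-identical (asserted in the tests with the bundled
  `config_demo.yaml`, which completes in about half a minute per run on a
  single core — 5 pH conditions with compact grids).
* Degenerate inputs fail loudly with classed errors naming the offending
  field: constant targets (undefined correlation/R²), zero-variance
  columns at standardization, k ≥ n for the AD, subset sizes beyond p.

## Worked example

```{r example, eval = FALSE}
library(qsrrkit)

run <- run_qsrr(system.file("extdata", "config_demo.yaml",
                            package = "qsrrkit"),
                out_dir = "results")

run$ranks                    # cross-pH mean ranks by external RMSE
run$ad_report                # per-compound applicability report
autoplot(run)                # observed vs predicted, per pH
plot_residuals(run)          # residuals in minutes, per pH
autoplot(run$ad_report)      # distances vs thresholds
```

## Known limitations

* The macrostate ladder is an approximation; molecules with interacting
  ionizable sites need externally supplied microstate fractions.
* MLR is restricted to post-selection feature sets by design; there is no
  PLS or neural-network learner, and no leverage/bounding-box AD variant.
* The stacking dominance property discussed above does not hold pointwise
  at n ≈ 67/10; treat the stack as a strong, stable member of the lineup
  rather than a guaranteed winner.
* Grid-search defaults are deliberately generous; for repeated runs on
  small data, the compact grids used by `stacking_benchmark_settings()`
  and the demo config are an order of magnitude faster at little cost.
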