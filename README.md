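# fsestab

Stability-aware feature-selection ensembles for prognostic prediction in
longitudinal cohorts.

## What problem this solves

Clinical prognostic models — the motivating case is predicting which mild
cognitive impairment (MCI) patients will convert to dementia — are learnt
from wide batteries of baseline test scores and comparatively few
patients.  A useful feature panel must be (i) predictive, (ii) *stable*
under data perturbation (so the selected tests are reproducible and
interpretable), and (iii) not hostage to the choice of any single
feature-selection algorithm.  `fsestab` is for biostatisticians and ML
practitioners who need all three at once.

The package provides:

* a **time-window labeller** that turns longitudinal follow-up records
  into horizon-specific learning examples: converters (cMCI) have a
  dementia diagnosis at time *t* ≤ *w*; stable patients (sMCI) still carry
  an MCI diagnosis at *t* ≥ *w*; everyone else is excluded with a reason;
* a **heterogeneous ranking ensemble** (ReliefF, MIM, CMIM, MRMR,
  chi-squared, SVM-RFE, LL21) combined by the mean rank aggregator;
* **Kuncheva-index stability**, the chance-corrected similarity between
  equal-size feature subsets

  Sim(A, B) = (r·m − k²) / (k·(m − k)),   r = |A ∩ B|,

  averaged over all subset pairs across cross-validation folds;
* the **robustness–performance trade-off (RPT)** that picks the subset
  size k (and optionally the classifier) maximising

  RPT = (β² + 1)·s·p / (β²·s + p),

  where s is stability, p = α·AUC + γ·min(sensitivity, specificity) is the
  composite predictability (α = γ = 0.5 by default), and β weights the two
  (β = 0.1 favours stability, β = 10 favours performance);
* a leakage-safe repeated **stratified-CV engine** (per-fold missing-value
  filtering at 20%, mean/mode imputation, SMOTE gated at 70% majority
  share) with Friedman/Wilcoxon selector comparisons;
* a **synthetic-cohort generator** with known informative features and
  conversion times, so the whole pipeline is testable without restricted
  clinical data;
* a CLI (`inst/exec/fsestab`) with subcommands `simulate`, `windows`,
  `rank`, `aggregate`, `stability`, `select`, `evaluate`, `report`.

## Worked example

```r
library(fsestab)

spec <- synthetic_spec(n_patients = 200, n_informative = 5, n_redundant = 3,
                       n_noise = 12, effect_size = 0.8, missing_rate = 0.15,
                       seed = 42)
cohort <- generate_cohort(spec)
cohort
#> <cohort> 200 patients, 20 baseline features

wd <- build_windowed_dataset(cohort, window_years = 3)
wd
#> <windowed_dataset> 3-year window: 168 examples (91 sMCI / 77 cMCI, 54%/46%), 32 excluded

cfg <- cv_config(repetitions = 2, folds = 5, master_seed = 42, windows = 3,
                 classifiers = list(classifier_spec("NB"),
                                    classifier_spec("LOGREG")),
                 compare_base_methods = FALSE)
res <- run_experiment(cohort, cfg)
res
#> <experiment_result> 1 window(s)
#>   window_3: 168 examples, best pair LOGREG with k = 5 (RPT 0.709)

bp <- res$window_3$best_pair$beta_10
curve <- res$window_3$selectors$ENSEMBLE$curves[[bp$classifier]]
round(curve[curve$k == bp$k, ], 3)
#>   k  auc sensitivity specificity performance stability rpt_0.1 rpt_1 rpt_10
#> 5 5 0.78       0.642       0.759       0.711     0.526   0.527 0.605  0.709
```

Reading the output: of 200 simulated patients, 168 are labelled for the
3-year horizon (the other 32 lack usable follow-up for that window).
Across 2 × 5 cross-validation folds the ensemble consensus was evaluated
at every subset size; at β = 10 the best pair is ridge logistic regression
with the top k = 5 consensus features, giving mean test AUC 0.78,
sensitivity 0.64, specificity 0.76, composite performance 0.71 and
selection stability 0.53 at that size.  At this deliberately small scale
the 5-feature panel captures 3 of the 5 truly informative features; the
package's test suite shows that at the reference condition (400 patients,
3 × 3 CV) the chosen panel recovers at least 8 of 10 informative features
in ≥ 9 of 10 seeds.

The same pipeline runs from the shell:

```sh
Rscript inst/exec/fsestab simulate --out sim --n-patients 200 --seed 42
Rscript inst/exec/fsestab windows --assessments sim/assessments.csv \
    --features sim/features.csv --windows 2,3,4 --out win
Rscript inst/exec/fsestab select --data win/window_3.csv --out sel \
    --classifier NB --folds 5 --repetitions 2 --seed 42
```

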