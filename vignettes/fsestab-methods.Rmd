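---
title: "Stability-aware feature-selection ensembles: models and methods"
author: "fsestab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stability-aware feature-selection ensembles: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsestab)
```

## The problem

Prognostic models for conversion from mild cognitive impairment (MCI) to
dementia are typically learnt from a large battery of neuropsychological
test scores observed at baseline, with the outcome defined by later
clinical follow-up.  Two difficulties dominate: the feature battery is
wide relative to the number of patients, and the cohort is heterogeneous in
*when* patients convert.  `fsestab` addresses both: it builds
time-homogeneous learning examples with a time-window labeller, and selects
a reduced feature panel with a heterogeneous ranking ensemble whose subset
size is chosen by trading off *selection stability* against
*classification performance*.

## Time-window labelling

For a horizon $w$ (years), a patient is a **converter (cMCI)** if any
follow-up with a dementia diagnosis occurs at time $t \le w$, and
**stable (sMCI)** if an MCI diagnosis is still recorded at some $t \ge w$.
All other patients are excluded for that window, with the reason retained:

* *conversion after window* — the first dementia record falls beyond $w$.
  Conversion happened at some unobserved earlier time, so the narrow
  window cannot label the patient either way.  A patient first seen
  demented at 2.5 years is therefore a converter for a 3-year window but
  excluded from a 2-year window.
* *insufficient follow-up* — follow-up simply never reaches $w$.

Stability of the diagnosis is demanded *at or beyond* the limit: an MCI
record slightly before $w$ is not evidence of stability at $w$.  Boundary
comparisons use $\le$/$\ge$ with times rounded to 3 decimals, so an
assessment exactly at the window limit counts as within it.  These choices
make converter labels monotone: widening the window can only turn sMCI or
excluded patients into converters, never the reverse.

Baseline admission rules are enforced at load time: a usable record has an
MCI diagnosis at baseline and at least one follow-up at $t > 0$; diagnosis
strings are matched through a trimmed, case-insensitive alias table
("AD" and "dementia" both mean dementia).  Same-day duplicate assessments
are rejected rather than silently merged, since no principled tie rule
exists for contradictory same-day diagnoses.

## The feature-selection ensemble

Within each training fold, seven ranking-based selectors are available:
ReliefF, mutual-information maximisation (MIM), conditional mutual
information maximisation (CMIM), minimum-redundancy maximum-relevance
(MRMR), chi-squared, SVM-RFE, and an $\ell_{2,1}$-regularised
logistic-loss ranker (LL21).  Their rankings are combined by the **mean
rank aggregator**: each feature's consensus score is the mean of its
1-based positions across rankings, lower meaning more relevant, with ties
broken by feature name.  The reported weight is $(m - \bar p + 1)/m$ so
that higher weight is more relevant.

Numerical conventions for the base rankers (defaults, all exposed):

* mutual-information quantities are estimated on equal-frequency
  discretizations of numeric features into $\min(10, \lceil\sqrt n\rceil)$
  bins; features with at most that many distinct values keep their own
  levels.  Entropies are in bits.
* the chi-squared score uses the same discretization, guaranteeing
  non-negativity.
* ReliefF uses 10 nearest hits/misses, every example as a reference
  point, range-normalised numeric differences and 0/1 nominal mismatches.
  With all examples as references it is deterministic; seed-dependence
  only appears if reference subsampling is enabled.
* SVM-RFE eliminates one feature per iteration from a linear SVM with
  $C = 1$; nominal features are one-hot expanded and scored by their
  weight-block sum of squares.
* LL21 minimises a two-class softmax loss with a per-feature row-block
  $\ell_{2,1}$ penalty by proximal gradient descent (tolerance $10^{-6}$,
  at most 500 iterations), with the regularisation strength taken from a
  small fixed grid by training loss; features are ranked by block norm.
* every score tie is broken by ascending feature name, so all rankings
  are reproducible.

### Screening unstable members

A selector whose subsets churn across folds degrades the consensus.  The
self-stability of each method (mean collection stability of its top-$k$
subsets across folds, averaged over $k = 1,\dots,m-1$) is computed by
`stability_report()`, and `screen_unstable_methods()` retains methods at
or above a cutoff.  The default cutoff is 0.5: recursive-elimination SVM
rankings typically profile around 0.2–0.3 while the filter and sparse
methods sit around 0.7–0.9, and any cutoff between those clusters makes
the same decision; 0.5 is the midpoint and is exposed as a parameter.
Consequently the default ensemble is ReliefF, MIM, CMIM, MRMR,
chi-squared and LL21, with SVM-RFE available but not enrolled.

## Stability

Similarity between two size-$k$ subsets drawn from $m$ features is the
chance-corrected Kuncheva index
$$ Sim(A,B) = \frac{r m - k^2}{k\,(m-k)}, \qquad r = |A \cap B|, $$
bounded by $[-1, 1]$, with expectation 0 for independent random subsets.
The stability of $n$ subsets is the mean over all $n(n-1)/2$ unordered
pairs.  The index is undefined at $k = 0$ and $k = m$, where the subsets
are forced equal; there the package returns 1 by convention *with a
warning*, and profile averages simply run $k = 1,\dots,m-1$ so the
convention never enters an average silently.

## Choosing the subset size (and classifier)

For $k = 1,\dots,m$ the classifier is trained on each fold's top-$k$
features and evaluated on the fold's test split.  Predictability is the
composite
$$ \mathrm{performance} = \alpha\,\mathrm{AUC} +
   \gamma\,\mathcal F(\mathrm{sens}, \mathrm{spec}), $$
with $\alpha = \gamma = 0.5$ and $\mathcal F = \min$ by default: AUC alone
is insensitive to the sensitivity/specificity trade-off under class
imbalance, and the minimum targets the weaker of the two.  Stability at
$k$ is the collection stability of the folds' top-$k$ subsets.  The two
are combined F-measure style,
$$ \mathrm{RPT} = \frac{(\beta^2 + 1)\, s\, p}{\beta^2 s + p}, $$
which lies between $\min(s,p)$ and $\max(s,p)$, equals their harmonic mean
at $\beta = 1$, tends to $s$ as $\beta \to 0$ and to $p$ as
$\beta \to \infty$.  The chosen subset size maximises RPT (ties to the
smaller $k$); the grid $\beta \in \{0.1, 1, 10\}$ is the default, with
$\beta = 10$ the recommended operating point since stability curves
plateau high and would otherwise dominate.  Because the Kuncheva index can
be negative, RPT is ill-behaved at $s \le 0$; the package reports RPT $= 0$
there, with a warning, rather than clipping stability to an artificial
floor.

When several classifiers are run, `select_best_pair()` returns the
(classifier, $k$) pair with the highest RPT at the chosen $\beta$, ties
resolved by the fixed order NB, logistic regression, RBF-SVM,
polynomial-SVM, decision tree, then smaller $k$.  The reported feature
subset is the top-$k$ of the consensus ranking aggregated over *all*
folds' per-fold consensus rankings; when per-fold missing-value filtering
makes fold pools differ, each fold ranking is completed to the full pool
by appending its filtered-out features at the tail before aggregation.

Classifier defaults (all exposed): Gaussian naive Bayes;
depth-unlimited CART tree; SVMs with $C = 1$, RBF $\gamma = 1/m$,
polynomial degree 3; ridge logistic regression with $C = 1$.  AUC is the
rank-based (Mann–Whitney) area, identical to the trapezoidal ROC area;
hard predictions use the 0.5 probability threshold or the SVM decision
sign.

## Leakage-safe preprocessing

All preprocessing is fitted on the training split of each fold only:

* features with a missing-value fraction **strictly above** 20% are
  dropped (20 missing in 100 rows is kept);
* remaining missing values are imputed with the training mean (numeric)
  or training mode (nominal, ties alphabetical);
* SMOTE oversampling of the minority class to parity is applied **only**
  when the majority share is strictly above 70% — an exact 70/30 split
  does not trigger it.  The gate is measured as the majority-class
  proportion.  Synthetic examples are convex combinations of a minority
  example and one of its $k = 5$ nearest minority neighbours in a one-hot
  encoding, with nominal coordinates rounded back to the nearest
  category; originals are never altered.  Degenerate minorities lower the
  neighbour count to class size $-$ 1, and a singleton minority falls
  back to duplication with a warning.

The cross-validation engine (`run_experiment()`) repeats stratified
$c$-fold assignment with per-repetition reshuffling; child seeds derive
from the master seed by a fixed counter scheme, so the whole experiment is
a pure function of the cohort and the master seed.  Per-fold composite
performance vectors (length repetitions × folds) feed the selector
comparison: a Friedman omnibus test across selectors, followed — when
significant at 0.05 — by pairwise Wilcoxon signed-rank tests of the
ensemble against each alternative with Bonferroni correction over the
comparisons actually performed; with exactly two selectors the omnibus
test is skipped for a single Wilcoxon.

## The synthetic cohort

`generate_cohort()` provides ground-truth-known data shaped like a
longitudinal neuropsychological cohort: a configurable number of
informative, redundant (correlation $\rho$ with an informative parent)
and noise features; a fraction of features discretized to 3-level nominal
scores; MCAR missingness; annual follow-ups with ±0.1-year jitter and
geometric dropout (at least one follow-up is always kept).  Conversion
follows a discrete-time logistic hazard,
$h = \mathrm{logit}^{-1}\big(\mathrm{logit}(h_0) + e\sqrt{p}\,z\big)$,
where $z$ is the standardized mean of the informative features, $p$ their
count and $e$ the effect size; the $\sqrt p$ factor calibrates the
per-feature group shift between eventual converters and non-converters to
be of order $e$.  The defaults — 400 patients, 10 informative features at
effect 0.8, 10 redundant at $\rho = 0.8$, 30 noise, 15% MCAR missingness,
base hazard 0.10 per visit — are the package's reference condition and are
not tuned per analysis.

What the generator does *not* emulate: realistic score distributions with
floors/ceilings, informative (non-MCAR) missingness, correlated noise
blocks, or interval-censored conversion times.  Tests passing on this
generator therefore demonstrate correctness of the machinery and
recoverability under a known signal, not clinical performance on real
cohorts.

## Problem sizes used by the test-suite

The package's own verification uses deliberately scaled runs: the
end-to-end recovery check runs the reference synthetic condition through a
3-repetition × 3-fold CV with a single Gaussian-NB classifier over ten
master seeds, asking that at $\beta = 10$ the selected subset contain at
least 8 of the 10 informative features and that the ensemble's composite
performance be at least that of the all-features baseline in at least 9 of
the 10 seeds.  Monte-Carlo properties (chance-level AUC at zero effect,
monotone AUC in effect size, near-zero stability of random rankings) use
10–20 seeds at cohort sizes of 120–150.  These sizes are the package's
choice of a desk-scale experiment; all of them are ordinary function
arguments and scale up unchanged.

## Known limitations

* Conversion times are treated as first-observed dementia visits; no
  interval-censored survival modelling is attempted, and no imputation of
  conversion times between visits.
* The Kuncheva index requires equal subset sizes, which is why only
  ranking-based selectors (not subset-based ones) are supported.
* The LL21 regularisation path is a small fixed grid; a full path with
  cross-validated selection is out of scope.
* `alpha + gamma` is only required to be at most 1, not exactly 1, so the
  composite performance lives in $[0, \alpha + \gamma]$.
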