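---
title: "Building and validating an IHC-based prognostic classifier for resected CRCLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and validating an IHC-based prognostic classifier for resected CRCLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crclmcart)
```

## The problem

About half of colorectal cancer patients develop liver metastases (CRCLM);
after hepatic resection, five-year survival varies widely and the
established clinicopathological risk factors (short primary-to-metastasis
interval, nodal primary, metastasis diameter above 5 cm, multiple
metastases, CEA above 200 ng/ml) separate outcomes only coarsely.
Immunohistochemical (IHC) expression of proteins involved in tumour
progression is a candidate source of sharper prognostic information.  This
package implements, end to end, a pipeline that turns per-patient ordinal
IHC scores into a small decision-tree classifier of overall survival (OS),
with honest, selection-aware significance:

1. **Per-marker screening** (`mccv_screen()`): Monte-Carlo cross-validation
   with survival-ROC cutoff optimisation and stepwise multivariate Cox
   models, summarised by the cross-validated average hazard rate ratio
   (HRR\_av) and an opposite-direction stability proportion.
2. **Tree construction** (`build_cart()`): CART over dichotomised candidate
   markers predicting three-year survival, selected by 10-fold
   cross-validated misclassification.
3. **Class grouping** (`class_hrrs()`, `group_classes()`): leaf classes
   lettered A, B, C, ... are compared against the best-surviving class by
   Cox regression and merged into prognostic classes I (HRR < 2) and II
   (HRR ≥ 2).
4. **Inference** (`classifier_hrr()`, `permutation_corrected_p()`,
   `compare_models()`, `subgroup_analysis()`): Kaplan-Meier/logrank,
   univariate and covariate-adjusted classifier HRRs, permutation-corrected
   p-values that re-run the whole construction on outcome-permuted data,
   analysis of deviance against the clinicopathological model, and
   subgroup analyses.
5. **Primary-tumour transfer** (`pair_correlations()`,
   `apply_classifier_primary()`): concordance of matched primary/metastasis
   scores, and pruning of discordant markers before applying the classifier
   to primary-tumour expression.

Because patient-level data of this kind are typically not shareable, the
package ships a calibrated synthetic-cohort generator; every stage is
tested against cohorts whose generative truth is known.

## Data model

A cohort is one row per patient: OS in months from CRCLM resection, a death
indicator, the five binary clinical risk factors, subgroup labels (systemic
therapy, colon vs rectum), and per-marker IHC scores.  Each score has an
intensity channel (0 negative - 3 strong) and a frequency channel (0:
0-25% - 3: 76-100% positive cells), for the metastasis and optionally the
matched primary tumour.  `cohort_columns()` documents the file format
(UTF-8 CSV, empty field = missing).

Exclusion rules (`apply_exclusions()`) are layered per analysis: survival
analyses drop patients with unknown survival or under two months of
follow-up (early postoperative deaths reflect surgical risk, not tumour
biology); three-year analyses additionally drop patients censored at or
before 36 months, whose three-year status is undefined; classifier analyses
additionally drop patients missing a required marker.  A death at exactly
36.0 months counts as a three-year failure (the boundary convention is a
package choice; results are insensitive to it because observed times are
continuous).

"High" expression means score ≥ threshold, with thresholds between adjacent
ordinal categories (1, 2 or 3).  The direction is a convention chosen so
that "high expression associated with poor prognosis" reads naturally; a
protective marker simply gets an HRR below 1.

## Screening

For each of 500 random splits (2/3 training, 1/3 validation, stratified on
event status), the training set chooses the marker's cutoff and the
validation set estimates its effect:

* **Cutoff** (`survival_roc_cutoff()`): cumulative-case/dynamic-control
  sensitivity and specificity at 36 months, from Kaplan-Meier survival
  within the high- and low-score groups — with no censoring this reduces
  exactly to classifying the died-by-36-months label, which is how the
  tests oracle it.  The threshold maximising |Youden's J| is selected.  The
  absolute value matters: for a protective marker the died-by-horizon ROC
  runs below the diagonal, J is negative everywhere, and maximising signed
  J would systematically pick the *least* informative threshold (we
  observed exactly this failure mode on the calibrated protective marker
  before taking |J|).
* **Effects**: a univariate Cox model of high vs low, and a multivariate
  model where the five clinical factors undergo stepwise backward
  elimination (drop the largest Wald p while it exceeds 0.1) with the
  marker forced in.  Ties are handled by the Efron approximation.

Splits with degenerate validation sets (single expression group, no
events) or non-convergent fits (monotone likelihood, |log HRR| > 15) are
dropped from both numerator and denominator and logged; by default at
least half the splits must survive.

HRR\_av is the *arithmetic* mean of the valid per-split HRRs — the literal
reading of "averaging the HRRs"; it is slightly biased away from the
geometric centre (Jensen), which is inherent to the summary rather than an
estimation artefact.  The stability statistic is the proportion of
validation HRRs pointing against HRR\_av — P(HRR < 1) when HRR\_av > 1 and
P(HRR > 1) otherwise; splits at exactly 1 count in neither direction.
Candidates are markers with an opposite-direction proportion of at most
0.10, a bound that separates the strong screening profiles (proportions
≤ 0.09) from unstable ones in practice.  Per marker, the channel (intensity
or frequency) with the larger |log HRR\_av| is carried forward; exact ties
prefer intensity and are logged.  No multiplicity correction is applied at
this stage — the permutation correction downstream accounts for the whole
selection path.

Each split draws its own child seed from the master seed, so split *k* is
reproducible regardless of how many splits run or in what order.

## Tree, classes, groups

Candidate markers are dichotomised at their *modal* cutoff across valid
splits (the screening yields one cutoff per split; the mode is the
package's choice of a single deployable threshold).  The tree is grown by
Gini impurity with a minimum leaf of 10 patients (rpart), the
cost-complexity pruning sequence is evaluated by 10-fold cross-validated
misclassification of the three-year outcome, and the subtree with minimal
CV error is kept, ties resolved toward the smaller tree.  The minimum-CV
rule is the literal "lowest misclassification error rate"; the 1-SE rule is
available (`select = "1se"`) but not the default.  Two consequences are
worth knowing:

* fold assignment comes from rpart's internal randomisation (seeded, but
  *not* stratified on the label — a deliberate simplification; rpart's
  pruning machinery is reused rather than re-implemented);
* under a null cohort the min-CV rule retains noise splits in a sizeable
  minority of datasets (the classic motivation for 1-SE).  The null
  safeguard is therefore *not* "the tree is always a stump" but "the
  construction is degenerate": either a stump, or a grouping in which no
  class reaches the HRR threshold.  Measured over null datasets, 20/20
  constructions are degenerate, and 99.5% of null permutations inside the
  permutation test.

Leaves are lettered A, B, C, ... depth-first with the low branch first, so
the letters read off the tree in the order the class definitions are
stated.  Class HRRs are estimated against the class with the highest
Kaplan-Meier survival at 36 months (ties: lexicographically first), which
in the canonical tree is class A.  Classes with HRR below 2.0 join the
reference in group I; classes at or above 2.0 form group II (equality goes
to II; the published grouping prints both "< 2.0" and "> 2.0" and leaves
equality open).  If all classes land on one side the classifier is flagged
non-discriminative.

## Permutation-corrected significance

Because the classifier is *selected* on the same data it is tested on, the
raw logrank p is optimistic.  The correction permutes the outcome pair
(time, event) jointly across patients — keeping the marker/covariate
dependence structure intact — and re-runs the full construction (tree on
the permuted three-year labels, class HRRs, grouping, logrank) on each of
n\_perm datasets; degenerate permuted constructions contribute p = 1
(conservative).  The corrected p is the fraction of permuted p-values
smaller than the original.  Three estimators are reported:

* `p_corrected` — the strict proportion count/n\_perm (the printed
  definition);
* `p_corrected_add_one` — (count + 1)/(n\_perm + 1), the classic
  permutation estimator that never returns 0;
* `p_corrected_randomized` — the randomised tie-broken rank of the
  observed dataset among its permutations, which is *exactly* uniform
  under the null.  Ties matter here: under exchangeability most permuted
  constructions are degenerate with p = 1, so the strict estimator has
  atoms and is super-uniform (conservative).  Calibration checks in the
  test suite therefore assert uniformity of the randomised variant; the
  strict variant is what an analyst should report.

Screening cutoffs are *not* re-optimised inside permutations by default —
the construction that is re-run is the tree/grouping step, matching the
computationally feasible reading of re-determining "the optimal
classifier"; `strict = TRUE` additionally re-optimises each marker's
cutoff on every permuted dataset (single-pass survival ROC) for use at
reduced n\_perm.  The default n\_perm for exploratory runs is 1000; 10000
matches the reference procedure.  Subgroup analyses apply the classifier
exactly as fitted (no refit) and permute outcomes within the stratum — the
within-stratum scheme is an assumption, flagged as such.

Model comparison against the clinicopathological model is the analysis of
deviance between nested Cox models (clinical factors vs clinical factors +
classifier): chi-square = difference in -2 log partial likelihood on the
added degrees of freedom.

## Primary-tumour transfer

Concordance between matched primary and metastasis expression is Pearson's
r on the 0-3 scores (the convention for these ordinal scores; treat it as a
linear-association summary, not an estimate of a latent correlation).  A
marker whose concordance fails r > 0 and p < 0.05 is pruned from the tree
by collapsing its split — two leaf children merge into one leaf that keeps
the combined class label (e.g. B/C).  The remaining classes are re-assigned
from primary-tumour scores, their HRRs re-estimated, and re-grouped at the
2.0 threshold.  On the canonical AURKA/PTGS2/MMP9 tree, pruning MMP9 merges
B and C; both merged-B/C and D then sit above the threshold, so group II
becomes exactly "AURKA high" — the single-marker reduction emerges from
re-grouping rather than being hard-coded, and `apply_classifier_primary()`
verifies by exhaustive enumeration whether the final grouping coincides
with a single marker's rule.

## The synthetic generator

`synthetic_config()` draws ordinal scores per marker and channel from
configurable category distributions, survival from a proportional-hazards
model with exponential baseline (a Weibull shape is available; Cox
machinery is baseline-agnostic, so constant baseline is the simplest
assumption satisfying proportional hazards), independent exponential
censoring, and an administrative cap at 120 months (ten years of
follow-up).  The linear predictor sums per-marker effects applied at the
true cutoff plus clinical effects — or, alternatively, a per-class
log-hazard over the classes of a supplied tree.  Missingness is applied
per channel, completely at random; real missingness (failed cores,
non-evaluable stains) is likely not MCAR, which is a stated limitation.
Matched primary/metastasis scores come from a Gaussian copula: a bivariate
normal latent pair thresholded at the category quantiles.  Because the
observable quantity is the Pearson correlation of the *ordinal* scores,
`implied_ordinal_correlation()` computes the exact ordinal-scale r implied
by a latent correlation (by bivariate-normal rectangle probabilities) and
`calibrate_pair_correlation()` inverts it, so profiles can target observed
correlations directly.

Two calibrated profiles encode published effect sizes as generative truth:

* `profile_markers()` — nine markers with log HRRs set to the log of the
  multivariate screening values (AURKA 1.66, PTGS2 1.59, SLC2A1 0.65, ...),
  uniform score distributions (the marginal score distributions are not
  recoverable from published summaries; uniform keeps every threshold
  admissible and is documented as arbitrary), true cutoff 2 on the
  intensity channel, clinical factors with prevalence 0.4 and HRR 1.5,
  baseline 0.0035/month with censoring 0.004/month — about 40% five-year
  survival and ~60-75% observed deaths, typical of resected CRCLM cohorts.
* `profile_classes()` — hazards driven directly by the four classes of the
  canonical tree.  The class log-hazards were calibrated once by large-n
  (200 000) simulation so the *marginal* two-group Cox HRR of classes II
  vs I equals 2.79 (B = 1.2, C = 2.52, D = 3.15): because group I and II
  are mixtures, the marginal coefficient is not a simple function of the
  class effects and has to be solved numerically.  The `adjusted` variant
  switches the five clinical hazards on and targets an adjusted HRR of
  3.57 (C = 3.22, D = 4.025); it also lowers the baseline hazard to
  0.005/month, because with five clinical hazards stacked on top of the
  original baseline every class became majority-dead by three years and no
  tree could be learned from the three-year outcome.  The
  `target = "primary"` variant generates matched pairs whose hazard
  follows high primary-tumour AURKA with HRR 2.59, for the reduced
  classifier.  Cross-lesion correlations are calibrated to AURKA 0.34,
  PTGS2 0.20, MMP9 -0.04 on the ordinal scale.

What passing tests on these cohorts shows — and does not show: the
pipeline recovers known generative structure under proportional hazards,
MCAR missingness, independent markers and exchangeable censoring.  Real
IHC data add inter-observer scoring noise, correlated markers, core
dropout and non-proportional hazards, none of which the generator
emulates; test results validate the *software* and the *statistical
machinery*, not clinical performance.

## Problem sizes and expected recovery

The validation suite runs at the scale of the cohorts the method is meant
for: screening recovery on a single cohort of n = 500 with 500 splits;
classifier recovery on n = 1000 over ten seeds; permutation calibration on
200 null cohorts of n = 300 with 200 permutations each; oracle equivalences
on small exhaustive cases.  Two quantitative caveats, measured during
development and worth restating:

* A dichotomised marker's log HRR at n = 500 has sampling sd ≈ 0.12, so a
  *single* cohort's screening HRR\_av lands within ±20% of generative truth
  with probability ≈ 0.87-0.90 per marker; individual cohorts (including
  fixed-seed test cohorts) can and do miss the band for one marker while
  the same code recovers the truth at n = 5000.
* Marginal dichotomised-marker HRRs are attenuated a few percent relative
  to the generative conditional effects when other prognostic markers are
  omitted from the model (non-collapsibility of the Cox model), and the
  arithmetic HRR averaging adds a small Jensen term.  Recovery assertions
  use the generative value as the centre with these effects inside the
  tolerance, not re-centred targets.

## Known limitations

* The exact time-dependent ROC estimator and the train/validation ratio of
  the reference procedure are not recoverable from published descriptions;
  both are configuration (`train_fraction`, horizon), defaulting to the
  choices above.
* CART consumes dichotomised scores (consistent with cutoff screening
  feeding the tree); ordinal-input trees are not implemented.
* HRR point estimates are not corrected for selection optimism — only the
  p-values are; reported HRRs may be somewhat optimistic, which is a
  property of the procedure, not a bug.
* No surrogate splits: a patient missing a marker queried on their path is
  excluded (and logged) rather than rerouted.
* Collapsing a pruned marker whose split sits above further splits merges
  by keeping the larger branch (with a warning); the canonical use case
  only ever collapses a terminal split.
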