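---
title: "Developing agreement-based EUS criteria for malignant lymphadenopathy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing agreement-based EUS criteria for malignant lymphadenopathy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(euscrit)
library(dplyr)
```

## The problem

Endoscopic ultrasonography (EUS) is the standard imaging modality for lymph
nodes in the mediastinum and abdomen, and EUS-guided fine-needle aspiration
(EUS-FNA) provides the tissue diagnosis. Imaging criteria are still needed —
to decide which nodes to puncture, and to interpret negative cytology. The
conventional four-item criteria (long axis > 10 mm, round shape, sharp/clear
border, hypoechoic pattern) rest on categorical image features that different
experts read differently. This package implements a criteria-development
pipeline that takes inter-rater agreement seriously: features are screened by
multi-rater kappa *before* they are allowed into a diagnostic score, size
cutoffs are derived by ROC analysis, and the resulting three-item score
(long axis > 20 mm, short axis > 10 mm, round-or-oval shape with long-short
ratio > 0.5) is evaluated head-to-head against the four-item criteria.

The pipeline operates on two tables: a *lesion table* (one row per node:
axes in mm, location, final benign/malignant diagnosis) and a *ratings
table* (one row per lesion × rater × feature categorical assessment; five
raters and six features — shape, border, margin, echogenicity, homogeneity,
hilum — by default). Because the underlying patient-level data of the
development study are not machine-readable, the package also ships a
synthetic cohort generator with the study's statistical structure, so that
every stage is testable.

## Agreement screening

For $N$ lesions rated by $R$ raters into $k$ categories, with $n_{ij}$ the
number of raters placing lesion $i$ in category $j$, Fleiss' multi-rater
kappa is

$$\kappa = \frac{\bar P - \bar P_e}{1 - \bar P_e},\qquad
P_i = \frac{\sum_j n_{ij}^2 - R}{R(R-1)},\qquad
\bar P_e = \sum_j p_j^2,$$

where $p_j$ are the pooled category marginals. $P_i$ is the fraction of
agreeing rater pairs for lesion $i$, so $\kappa$ is chance-corrected
pairwise agreement. The development study names only "multi-rater kappa
statistics"; Fleiss' fixed-marginal generalisation is the standard choice
for more than two raters and is what `fleiss_kappa()` implements. When all
ratings fall into a single category, $\bar P_e = 1$ and kappa is undefined;
this is raised as an explicit error, never coerced to 0, 1 or `NaN`.

Confidence intervals are percentile bootstrap over lesions (raters kept
intact within each resampled lesion; `B = 2000` by default, seeded).
The interval method of the development study is not recoverable — several of
its printed intervals are inconsistent with any standard method (e.g.
$\kappa = 0.33$ with CI 0.17–0.38) — so no numerical reproduction of those
intervals is attempted, and the bootstrap is documented as this package's
choice. Verbal interpretation uses the Landis–Koch bands
(`landis_koch()`), with $\kappa \le 0$ split into "less than chance"
(strictly negative) and "slight".

Features enter the criteria only if $\kappa$ strictly exceeds 0.4
(`select_features()`), the lower edge of "moderate" — under the study's
reported kappas (0.44, 0.22, −0.02, 0.33, 0.34, 0.22) this retains shape
alone.

## Consensus features

A finding is attributed to a lesion when at least 3 of the 5 raters agree
(`consensus_features()`, `min_votes = 3`). With five raters and the
four-category shape vocabulary, a cell can lack any 3-vote category; such
cells are *indeterminate* (`NA`). Two design rules follow:

* The criteria only ever consume shape as "round or oval"; shape is
  therefore also binarised per rater (round/oval vs other) and
  majority-voted, which with an odd rater count always yields a decision
  (`shape_round_or_oval`).
* For the four-item criteria's "round shape" item, an indeterminate
  consensus means the finding *round* was not agreed by three raters — the
  item is `FALSE`, not missing. This keeps every predicate total.

Cells missing any rater are excluded from both kappa and consensus
(complete-case; `complete_cells()` reports the affected cells).

## Size cutoffs

`youden_cutoff()` maximises the Youden index $J = \text{sens} +
\text{spec} - 1$ over every midpoint between consecutive distinct observed
values, with "positive" meaning *strictly greater* than the cutoff; ties in
$J$ break toward the higher cutoff (higher specificity). Midpoints make the
search provably exhaustive over achievable operating points. The raw cutoff
is then rounded to a clinical grid (`clinical_round()`, default 5 mm,
halves up): this maps the development study's ROC cutoffs 19.7 mm and
10.7 mm to the clinically used 20 mm and 10 mm (nearest-integer rounding
would give 11 mm for the short axis, contradicting clinical use). Strict
`>` is used for all size items, matching the class-count tables that the
published percentages derive from; `strict = FALSE` switches to `>=`.

## Head-to-head evaluation

Scores are item counts (0–3 and 0–4). `roc_scores()` builds one operating
point per distinct threshold (positive = score ≥ t) and computes the AUC
both as the trapezoidal area and as the tie-corrected Mann–Whitney
statistic (half credit for ties); the two are mathematically identical and
asserted equal to $10^{-12}$ at run time. `delong_test()` compares the two
correlated AUCs by DeLong's placement-value method; identical scores give
zero variance and are flagged degenerate with $p = 1$. The accuracy table
(`performance_table()`, `diagnostic_metrics()`) reports confusion counts,
sensitivity, specificity, accuracy, PPV and NPV at the "at least 2 items"
and "all items" thresholds, each with a Wilson score interval
(`prop.test` without continuity correction). The development study's
printed metric intervals are likewise not reproducible by any standard
binomial method, so Wilson is documented as this package's choice and the
intervals are not validation targets. `ppv_npv_from_sens_spec()` is the
audit identity: it reconstructs integer confusion counts from a printed
sensitivity/specificity pair (round half up) and recomputes
accuracy/PPV/NPV; all published accuracy-table rows reconstruct exactly to
the printed decimal under it.

## The synthetic cohort generator

`simulate_cohort()` draws, per lesion: diagnosis (Bernoulli, prevalence
30/68), long axis from a class-conditional normal (malignant
25.3 ± 11.3 mm, benign 16.8 ± 8.1 mm) truncated below at 3 mm, long-short
ratio from a class-conditional normal (0.66 ± 0.21 vs 0.59 ± 0.17)
truncated to (0.05, 1], short axis as long × ratio (so axis ordering holds
by construction), true shape from the class-conditional prevalence vectors
(8/30, 14/30, 0, 8/30 malignant; 4/38, 18/38, 5/38, 11/38 benign), and the
five binary features from per-class prevalences of the malignant-looking
category. The published summaries give only means ± SD, so the truncated
normal family is a package choice; truncation prevents non-physical sizes
and shifts the population means slightly (malignant long axis 25.96 mm, not
25.3 — tests assert against the analytic truncated means). The binary
feature prevalences are *free parameters* (the study does not report them);
the defaults 0.7/0.3 encode a generic malignancy signal.

`simulate_ratings()` adds rater noise by symmetric uniform confusion: each
rater reports the true category with probability $1-\varepsilon$, else a
uniformly random different category. The closed-form population kappa under
this model is available as `kappa_uniform_confusion()` and is the oracle
for parameter-recovery tests. The default $\varepsilon = 0.25$ was chosen
so the downstream kappas land in the fair-to-moderate band typical of
expert EUS reading — for a four-category shape at $\varepsilon = 0.25$ the
closed form gives $\kappa \approx 0.44$.

Deliberately **not** modelled: correlation between features beyond the
shape–ratio criterion coupling, rater-specific skill or bias, and any
skewness of the size distributions. The last point matters for
interpretation: a normal with the benign study moments implies
$P(\text{long} > 20\,\text{mm}) \approx 0.36$ and
$P(\text{short} > 10\,\text{mm}) \approx 0.48$, while the study observed
23.7% and 31.6% — real size distributions are right-skewed. Passing tests
on this generator therefore show the pipeline's statistics are correct
under the stated model, not that the model reproduces every observed
exceedance rate.

Because of exactly that mismatch, the replicated head-to-head comparison
(`headtohead_experiment()`) does not go through the moment-based
generator: it simulates cohorts of 30 malignant / 38 benign lesions whose
per-item class-conditional marginals *are* the published rates
(`study_item_rates()`: long > 20 mm 19/30 vs 9/38, short > 10 mm 24/30 vs
12/38, round-or-oval with ratio > 0.5 18/30 vs 13/38; for the four-item
criteria long > 10 mm 27/30 vs 32/38 and round 8/30 vs 4/38). The study
does not report class-conditional rates for clear border or dark
echogenicity; consistent with the near-chance AUC it reports for the
four-item criteria, these are held class-equal at 0.5 (present but
uninformative). Under those marginals the three-item criteria beat the
four-item criteria in essentially every replicate, with mean AUCs close to
the published 0.82 vs 0.52.

## Numerical and degenerate-input conventions

* Category labels are case-insensitive on input, canonical lower-case
  internally; axes arriving in the wrong order are swapped with a warning
  (the source is human-entered), a header-only file is an empty table.
* Undefined kappa and undefined metrics (empty denominators) are explicit
  error/`NA`-plus-flag states. Degenerate bootstrap resamples are redrawn
  up to a retry cap, then flagged.
* A 2×2 table uses Pearson chi-square without continuity correction when
  all expected counts are ≥ 5, else Fisher's exact test; a zero margin
  returns $p = 1$ flagged degenerate. Rank-sum tests are exact for two
  untied groups of ≤ 10, else normal approximation with tie and continuity
  correction.
* All randomness flows through explicit seeds (cohort, raters and
  bootstrap seeds are separate, so noise can vary on a fixed cohort);
  `run_pipeline()` derives its stage seeds from one master seed and embeds
  the full run record in every artifact.

## Problem sizes used by the test suite

The suite verifies the statistics against independent oracles at sizes
chosen to keep Monte-Carlo error well below the asserted tolerances:
exhaustive kappa enumeration at ≤ 4 lesions × 3 raters; noise-model
recovery at 2,000–5,000 lesions (tolerances 0.03–0.05); generator moments
at 10,000 lesions; bootstrap coverage with 100 replications of n = 500 at
B = 1,000; DeLong-vs-bootstrap agreement on a 20-lesion paired instance at
B = 10,000 (at 6 lesions the stratified bootstrap variance is itself
biased ~30% low, so a slightly larger instance is the smallest fair test);
and 100 replicate cohorts for the head-to-head direction.

## A full run

```{r, eval = FALSE}
report <- run_pipeline(pipeline_config(seed = 1), out_dir = "run1")
report$agreement          # per-feature kappa, CI, Landis-Koch label
report$cutoffs            # Youden + rounded size cutoffs
report$performance        # accuracy table for both criteria
glance(report$delong)     # paired AUC comparison
plot_roc_comparison(report$roc_new, report$roc_old)
```

## Limitations

The generator emulates one published cohort; its defaults are not a
general model of lymphadenopathy. Criteria performance estimated on
simulated cohorts inherits the independence assumptions above, and no
cross-validation of cutoff selection is attempted (the development study
derived cutoffs on the full cohort). Weighted kappa, Krippendorff's alpha
and rater-specific agreement decompositions are out of scope.
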