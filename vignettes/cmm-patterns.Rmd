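---
title: "Discovering cardiometabolic multimorbidity patterns with patient-similarity networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering cardiometabolic multimorbidity patterns with patient-similarity networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmmnet)
```

## The model

`cmmnet` treats pattern discovery in cardiometabolic multimorbidity (CMM)
as community detection on a *patient*-similarity network. Each multimorbid
subject (at least two of hypertension, dyslipidemia, diabetes, chronic
kidney disease, hyperuricemia) carries a feature vector of demographics,
lifestyle variables (smoking, six physical-activity durations, ~30 daily
nutrient intakes) and an aging-related biochemical panel. Continuous
features are z-scored on the cohort's own mean and population SD;
categoricals are one-hot encoded. Standardization before cosine similarity
is essential: on raw, all-positive intake scales every pairwise cosine
saturates near 1 and any threshold in the working range would be vacuous.

Edges connect pairs whose cosine similarity is at least a threshold *t*
(the comparator is `>=`; the cutoff side is not standardized anywhere, and
an inclusive rule keeps the complete graph reachable at *t* = −1).
Adjacency is binary after thresholding: the modularity formula is stated
for an adjacency matrix, and the threshold already encodes the weight
information. A weighted variant (`weighted = TRUE`) is available for
sensitivity analysis.

A note on reading the source study: its prose describes "diseases as
nodes", but its results partition all 2,306 subjects into four communities
with a modularity of 0.748 — impossible on a 5-node disease graph. The
patient-level network is the only reading consistent with the reported
results, and is what this package implements.

## Community detection

Modularity with resolution γ is

$$Q(\gamma) = \frac{1}{2m}\sum_{ij}\Big[A_{ij} - \gamma\frac{k_ik_j}{2m}\Big]\delta(c_i,c_j),$$

evaluated exactly by `modularity_q()` (γ = 1 recovers the classical form).
The optimizer `louvain()` is a native two-phase multilevel scheme: greedy
single-node moves to the neighboring community with the largest positive
gain, then aggregation of communities into super-nodes carrying self-loops
(internal edge mass appears as $A_{ii} = 2w_{\text{self}}$ so Q is
preserved under aggregation — asserted in the tests), repeated until no
move improves. Determinism given a seed comes from three choices: the
sweep order is shuffled by the seed; a move that merely ties the current
community is rejected; ties among competing candidates go to the lowest
community label. `brute_force_best_partition()` enumerates all set
partitions (Bell-number many, refused above 10 nodes) as an independent
oracle; the test suite checks the heuristic never exceeds the oracle and
attains it on unambiguous block structures.

The operating point is selected by `grid_search()` over thresholds 0.3–0.7
and resolutions 0.5–1.5, step 0.05 (the grid step is not published; 0.05
is chosen so the published optimum, threshold 0.5 and resolution 1, is a
grid point). Because γ rescales the objective itself, cells are compared
on Q evaluated *at γ = 1* on the detected partition; γ only shapes the
Louvain search. Ties break toward more included nodes (an explicitly
stated consideration of the source analysis), then lower threshold. The
package reports both Q at γ = 1 and Q at the selected γ, since the
published single value does not say which convention it used.

**Included nodes.** A thresholded similarity graph routinely leaves a few
nodes with no edges. They stay in the node list (and form singleton
communities, since every node must be assigned), but downstream pattern
analysis — characterization, classification, odds models — covers only the
*included* (non-isolated) nodes, mirroring "maximizing the number of
included nodes" as a stated selection concern. The pipeline records how
many subjects were excluded this way.

## The synthetic cohort: a stated world

`synth_config()` defaults describe the published 2,306-subject cohort:
group weights are the exact subgroup sizes 471/127/1463/245 over 2306 (the
rounded printed weights 0.204/0.055/0.634/0.106 sum to 0.999 and would
violate the configuration's own sum-to-one invariant); per-group disease
prevalences, categorical frequencies and the means/SDs of all continuous
features are the published per-pattern summaries. Disease flags are drawn
per-group Bernoulli; raw diagnostic measurements are then back-filled by
uniform draws strictly inside/outside each guideline cutoff so that
`flag_diseases()` applied to a record's own raw columns reproduces its
stored flags exactly (an invariant the tests assert). Printed comparators
are implemented literally: strict `>` for blood pressure and uric acid,
`>=` for lipid/glucose/ACR cutoffs, strict `<` for HDL-C and eGFR.
Duration qualifiers ("more than 3 months") become boolean persistence
flags, because single-visit data cannot verify duration; a low eGFR is
assumed persistent when the flag is absent. Gaussian draws are clipped at
documented physiologic floors (intakes and activity at 0, age to [20, 80],
BMI to [14, 70], and so on).

What the generator does *not* emulate: joint physiology. The biomarker
panel (e.g. fasting glucose in mg/dL) is drawn independently of the
back-filled diagnostic measurements (mmol/L); survey weights, missingness
and measurement error are absent (the emulated analysis was unweighted and
complete-case). A green recovery test therefore establishes that the
*pipeline* recovers planted structure — not that real survey data carries
such structure.

The `separation` parameter scales each group mean's deviation from the
weight-averaged grand mean. At `separation = 1` (the published marginals)
subgroup structure in cosine space is weak — within-group median cosine
≈ 0.10 against a between-group median ≈ −0.07 — which is exactly why the
recovery experiments use a declared strong-separation world:
four equal groups, `separation = 6`, where within-group similarity
(median ≈ 0.6) cleanly exceeds between-group similarity across the whole
threshold grid and exact recovery (ARI = 1) is the correct expectation.
This regime was fixed before the acceptance measurements and is not a
tuning knob. Because flags are marginal Bernoulli draws, the ≥2-diseases
filter shifts within-group prevalences upward; tests compare detected
prevalences against the *exact conditional* expectation obtained by
enumerating the 32 flag combinations, not against the raw rates.

## Characterization

`chi_square_test()` is the plain Pearson statistic without continuity
correction — that convention reproduces every published contingency χ² to
the printed three decimals. `anova_oneway()` accepts raw data or n/mean/SD
summaries; the summary path uses the sample (n−1) SD convention, the one
under which the published BMI row reproduces its printed F (8.369; the
reconstruction gives 8.377, within rounding of summaries printed to three
decimals). The published Age row duplicates the BMI F exactly and is
inconsistent with its own summaries (reconstruction ≈ 11.6); it is treated
as a typesetting duplication and excluded from acceptance. Bonferroni
post-hoc tests are pooled-variance pairwise t tests with p multiplied by
the number of pairs per variable (the family is not stated upstream; per
variable across the six pairs is the documented choice).

Pattern naming is rule-based and label-permutation invariant: highest
hypertension prevalence → HPG; lowest CKD prevalence → KDLG; of the
remainder the larger is MDHG and the last UADCG. Any collision (ties, one
pattern winning two rules, a pattern count other than four) falls back to
generic `Pattern-k` names with a logged note rather than guessing.

## Classifier benchmark

None of the usual classifier packages are assumed at runtime, so the
families are native: multinomial (softmax) logistic regression by
Newton–Raphson (with a ridge of 1e-4 for stability on separable data), KNN
(k = 5), random forest (100 Gini CART trees, mtry = √p, bootstrap
resampling) and gradient boosting (100 rounds of depth-3 squared-error
trees on softmax gradients, shrinkage 0.1) over a compiled CART, and a
linear squared-hinge SVM. XGBoost runs only if the optional package is
present; otherwise the family appears in the report as `skipped` — never
silently dropped. Stratified 70/30 splitting preserves per-class
proportions within one record; scaling is refit on training rows only and
test rows are projected through the stored transform (the leakage guard is
asserted in tests). Disease flags are *excluded* from classifier features
by default — they define the labels' world and the published importance
ranking lists only non-disease features — while the similarity graph
*includes* them; both are flags on `build_feature_matrix()`.

Point metrics come from the confusion matrix: accuracy is trace/total (the
printed accuracy formula omits FP from the denominator; that literal form
is kept behind `paper_literal = TRUE` for audit, corrected by default);
precision/recall/F1 are one-vs-rest per class, macro-averaged by default
with weighted averages also emitted (the upstream averaging convention is
unstated). AUC is one-vs-rest, rank-based, macro-averaged. The published
Table-4 metrics themselves (e.g. logistic-regression accuracy 0.954) are
not reproducible without the restricted survey extract and are recorded as
documentation, not asserted.

## Odds models

Published OR tables report one row per covariate with no adjustment set,
and some printed magnitudes (a vitamin-B6 OR of 321) are only plausible as
per-unit, single-covariate fits. The default is therefore *univariable*
multinomial logits — one model per covariate, reference pattern UADCG —
with a `joint = TRUE` flag preserved for sensitivity analysis. Continuous
covariates stay on their raw per-unit scale, and the emitted table records
that scale. Categorical references follow the published footnote: Male,
College graduate or above, Living with partner, and the smoked-100+
flag. Wald 95% intervals are `exp(β ± 1.96·se)` from the inverse observed
information. Separation (non-convergence, runaway coefficients, exploded
standard errors) marks entries `flagged = TRUE` instead of reporting
silent infinities.

Two simulation conventions deserve a note. CI *coverage* under the null is
a per-interval property, so the acceptance check counts coverage across
all replicate × contrast intervals (nominal 95%, required ≥ 93%). The
spec-sheet example that every null OR lands in [0.9, 1.1] only holds when
class sizes are balanced — with a 5.5% reference pattern the sampling SE of
log-OR alone is ≈ 0.07–0.09 — so the unit test reads that example under a
balanced null, and the planted-effect recovery test (true OR 1.5,
n = 5,000) asserts the band on the mean across 20 seeds, whose Monte-Carlo
SE is well inside it.

## Numerical and degenerate-input choices

* Population (ddof = 0) SD for z-scoring, switchable to sample SD.
* Zero-variance features are dropped with a warning, not an error;
  zero-norm rows have undefined cosine and never receive edges.
* Modularity on an edgeless graph, χ² on a degenerate margin, ANOVA with
  all-zero within-variance and equal means, and the brute-force oracle
  above 10 nodes all refuse with explicit messages.
* Louvain gain comparisons use a 1e-12 tolerance; stored Q always equals a
  from-scratch `modularity_q()` recomputation to 1e-12.
* All stochastic entry points (generator, detector, splitter, learners)
  take explicit seeds; identical seeds yield byte-identical artifacts, and
  the pipeline manifest carries the seeds and file hashes (timestamps live
  in a separate file so manifests stay reproducible).

## Known limitations

The generator reproduces marginal summaries, not joint distributions or
survey design. Binary-adjacency modularity on thresholded graphs can favor
fragmenting high thresholds when planted structure is weak; the grid
search reports the full grid table so such regimes are visible. The
published modularity (0.748), classifier table and OR tables depend on the
original restricted extract and unstated preprocessing; the package
substitutes property-based checks (oracle dominance, hand-derived Q
values, planted recovery, closed-form OR identities, CI coverage) for
them, which is what a green acceptance run does — and does not — establish.
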