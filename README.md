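# cmmnet — network-based cardiometabolic multimorbidity patterns

`cmmnet` stratifies multimorbid patients into **cardiometabolic
multimorbidity (CMM) patterns**. CMM is the co-occurrence of at least two of
hypertension, dyslipidemia, diabetes, chronic kidney disease (CKD) and
hyperuricemia in one person; identifying recurring *patterns* of such
co-occurrence — and the demographic, lifestyle and biochemical profiles that
go with them — is the basis for targeted health management. The package is
aimed at epidemiologists and biostatisticians who want the full pipeline
(disease flagging → similarity graph → community detection →
characterization → classification → odds models) reproducible offline on
synthetic cohorts.

## Method

Each patient is a node carrying a standardized feature vector
(z-scored continuous variables, one-hot categoricals). Edges connect
patients whose **cosine similarity**

    sim(A, B) = A · B / (‖A‖ ‖B‖)

reaches a threshold *t*. Communities of the resulting graph are found with a
native **Louvain** optimizer of resolution-parameterized modularity

    Q(γ) = (1/2m) Σ_ij [ A_ij − γ k_i k_j / 2m ] δ(c_i, c_j)

and the operating point is chosen by a grid search over
*t* ∈ [0.3, 0.7] and γ ∈ [0.5, 1.5] that maximizes Q (evaluated at γ = 1 so
cells are comparable), breaking ties toward more included nodes, then lower
threshold. Detected patterns are characterized with Pearson χ² tests,
one-way ANOVA (raw-data or published Mean/SD summary input), Bonferroni
post-hoc comparisons and deterministic rule-based names (HPG, UADCG, MDHG,
KDLG). Pattern labels then feed a six-family classifier benchmark
(random forest, gradient boosting, SVM, KNN, multinomial logistic
regression, optional XGBoost — the first five implemented natively) and
univariable multinomial logistic models reporting odds ratios against a
reference pattern with Wald 95% CIs.

A synthetic cohort generator with planted subgroup structure emulates the
published 2,306-subject cohort marginals (group weights 471/127/1463/245
over 2306, per-group disease prevalences, feature means/SDs), derives
disease flags from back-filled raw measurements through the guideline
cutoffs (e.g. SBP > 140 mmHg; uric acid > 420 µmol/L men / > 357 women),
and applies the ≥ 2-diseases inclusion filter.

## Worked example

```r
library(cmmnet)

cfg    <- synth_config(n_patients = 800, group_weights = rep(0.25, 4),
                       separation = 6, seed = 1)   # strong planted structure
cohort <- generate_cohort(cfg)
cmm    <- filter_cmm(cohort)        # 800 -> 516 multimorbid subjects
fm     <- build_feature_matrix(cmm)
gs     <- grid_search(fm, seed = 1)
gs
#> grid search optimum: threshold = 0.55 resolution = 0.5
#>  modularity (gamma=1) = 0.71 | communities = 4 | retained nodes = 516

prof <- pattern_profile(cmm[gs$included, ],
                        factor(gs$partition$membership[gs$included]))
prof$names
#>      1       2       3       4
#> "KDLG" "UADCG"  "HPG"  "MDHG"
prof$prevalence$pattern_sizes
#> [1] 151 100 141 124
prof$disease_tests$hypertension
#> $statistic 6.460179   $df 3   $p_value 0.09124626
```

The four detected communities recover the four planted subgroups exactly
(ARI = 1 here); the prevalence table matches the planted conditional rates
within binomial error, and the naming rules assign each community its
pattern name from its own disease profile. The summary-statistics ANOVA
entry point reproduces published Mean (SD) tables:

```r
anova_oneway(summaries = data.frame(
  n = c(471, 127, 1463, 245),
  mean = c(31.044, 29.598, 29.130, 29.312),
  sd = c(7.841, 6.802, 7.107, 7.189)))$F
#> [1] 8.377014       # printed value 8.369, agreement within rounding
```

The whole pipeline (nine stages, with artifacts and a reproducible JSON
manifest) runs as:

```r
run_pipeline(pipeline_config(synth = cfg, out_dir = "run1", seed = 1))
```

or from the shell: `Rscript -e 'cmmnet::cmm_cli()' all --config run.yaml`.

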