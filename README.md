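# rfdissect

Dissecting a mixed transcriptional response into **receptor-driven
primary targets** and **metabolite-driven side effects** from time-course
expression data.

When a ligand such as benzo[a]pyrene activates a xenobiotic receptor
(the aryl hydrocarbon receptor, Ahr), the observed expression response
superimposes direct receptor targets on genes perturbed downstream by
reactive metabolites (e.g. the DNA-adduct-forming BPDE). `rfdissect`
separates the two using the temporal structure of the response and
auxiliary evidence that isolates each mechanism. It is aimed at
computational toxicologists and transcriptomics analysts working with
small, dense exposure time courses.

## Method

For genes passing a differential-expression screen (per-gene two-way
ANOVA with factors time and dose plus pooled one-sample t-tests, BH
adjustment, FDR < 0.05, and a 2-fold-change filter), expression is
interpolated onto an hourly grid as the average of linear and natural
cubic spline interpolants — 25 values per dose, with the 0 h ratio
anchored at 0. Training labels come from external evidence: genes whose
orthologs respond to the metabolite alone (two studies, p-values
combined by Fisher's method, X = −2Σlog pᵢ ~ χ²₂ₖ, then BH) are
*side effects*; genes responding in an early 0–4 h course but not to the
metabolite are *primary*. A balanced Random Forest (stratified bootstrap
of 20 genes per class per tree, mtry = 5; 5000 trees for Breiman
proximity-outlier removal at the pooled 95th percentile, 1000 trees for
the final fit) predicts the class of every screened gene; predictions
are *confident* when the vote proportion exceeds 0.8, the level that
label-permuted forests do not reach. The forest's proximity P (co-leaf
frequency) gives a supervised dissimilarity D = 1 − P; PAM k-medoids
with silhouette-based selection of k clusters the confident genes,
a second-stage forest filters genes whose own-cluster vote falls below a
permuted-label null and scores per-cluster time-point importance, and a
one-sided two-sample Kolmogorov–Smirnov test — training genes excluded —
validates clusters against Fisher-combined receptor-mutant perturbation
p-values.

A synthetic-data generator plants the study's signal structure (a
3 h-peaking primary induction pulse and two anticorrelated 24 h
undulations over two doses, plus matched auxiliary p-value tables and an
ortholog map) so the whole pipeline can be exercised against known
ground truth.

## Worked example

```r
library(rfdissect)

res <- run_pipeline(pipeline_config(seed = 1))
str(res$manifest)
#> List of 17
#>  $ seed                : int 1
#>  $ n_genes             : int 1260
#>  $ n_de                : int 657
#>  $ n_labeled_primary   : int 37
#>  $ n_labeled_side      : int 548
#>  $ n_train_primary     : int 34
#>  $ n_train_side        : int 521
#>  $ oob_error           : num 0
#>  $ tau                 : num 0.8
#>  $ n_confident         : int 575
#>  $ n_predicted_primary : int 50
#>  $ n_predicted_side    : int 525
#>  $ n_unclassified      : int 82
#>  $ best_k              : int 3
#>  $ cluster_sizes       : int [1:3] 50 293 232
#>  $ n_retained          : int 575
#>  $ retained_per_cluster: int [1:3] 50 293 232
```

Of 1260 simulated genes, 657 pass the differential-expression screen;
auxiliary evidence labels 37 primary and 548 side-effect genes (34/521
after outlier removal); the balanced forest classifies 575 genes
confidently (50 primary, 525 side effects; 82 remain unclassifiable at
the 0.8 vote threshold).

```r
res$kselect$avg_widths
#>         2         3         4         5         6         7         8
#> 0.5137363 0.6912110 0.5569483 0.4649817 0.3991361 0.4264775 0.3528998
```

The average silhouette width over the forest dissimilarity peaks at
**k = 3** — the planted number of transcriptional programs (primary
pulse and the two anticorrelated side undulations).

```r
subset(res$enrichment, select = c(set_id, n_in, n_out, ks_statistic, p_value, direction))
#>   set_id n_in n_out ks_statistic      p_value direction
#> 1      1   19    43  0.842105263 1.384448e-10  enriched
#> 2      2   22    40  0.004545455 9.830806e-01  depleted
#> 3      3   21    41  0.024390244 9.651163e-01  depleted
```

With training genes excluded, only the primary-responder cluster is
enriched for simulated receptor-mutant perturbation p-values
(KS p ≈ 1.4e−10) — the classifier's predictions, not its labels, carry
the receptor signal.

Individual stages are exposed as functions
(`differential_expression()`, `interpolate_profiles()`,
`derive_labels()`, `train_forest()`, `predict_all()`,
`compute_proximity()`, `select_k()`, `cluster_confidence()`,
`ks_enrichment()`, ...) and accept real data in plain TSV matrices; see
the methods vignette (`vignettes/dissecting-time-course-responses.Rmd`)
for the model, its assumptions, and every numerical choice.

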