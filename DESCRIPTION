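Package: rfdissect
Title: Dissecting Primary Receptor Targets from Metabolite Side Effects in
    Expression Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Separates a mixed transcriptional response into
    receptor-driven primary targets and metabolite-driven side effects
    from time-course expression data. Provides differential-expression
    screening with two-way ANOVA and pooled t-tests, hybrid
    linear/natural-spline interpolation onto an hourly grid, training
    label derivation from auxiliary-study p-values via Fisher's method,
    a balanced Random Forest classifier with Breiman proximity-based
    outlier removal and permutation-calibrated vote confidence,
    proximity-weighted PAM clustering with silhouette-based selection of
    the cluster number and a second-stage cluster-confidence forest, and
    Kolmogorov-Smirnov enrichment validation against receptor-mutant
    perturbation evidence. Includes a synthetic-data generator with
    planted transcriptional programs for end-to-end testing against
    known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    randomForest,
    cluster,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
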