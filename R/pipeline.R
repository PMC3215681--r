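#' Pipeline configuration
#'
#' Bundles the stage parameters of the end-to-end analysis: either a
#' simulation block or real input tables, the differential-expression
#' thresholds, the forest configuration, the clustering search range and
#' null rule, and one master seed from which every stage's randomness is
#' derived.
#'
#' @param sim A [sim_config()], or NULL when real inputs are supplied to
#'   [run_pipeline()].
#' @param fdr,fold Differential-expression thresholds.
#' @param rf An [rf_config()].
#' @param k_range Candidate cluster counts for silhouette selection.
#' @param null_rule Cluster-confidence null summary ("mean"/"quantile").
#' @param dropout Ortholog-map dropout fraction used in simulation.
#' @param calibrate Calibrate the vote threshold by permutation instead
#'   of using `rf$vote_threshold` directly.
#' @param alpha Label-derivation FDR threshold.
#' @param seed Master seed; overrides the seeds in `sim` and `rf`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(), fdr = 0.05, fold = 2,
                            rf = rf_config(), k_range = 2:8,
                            null_rule = "mean", dropout = 0.05,
                            calibrate = FALSE, alpha = 0.05, seed = 1L) {
  if (fdr <= 0 || fdr >= 1 || fold < 1)
    stop("pipeline_config: invalid DE thresholds", call. = FALSE)
  if (!is.null(sim)) {
    stopifnot(inherits(sim, "sim_config"))
    sim$seed <- sub_seed(seed, "sim")
  }
  rf$seed <- sub_seed(seed, "rf")
  structure(list(sim = sim, fdr = fdr, fold = fold, rf = rf,
                 k_range = k_range, null_rule = null_rule,
                 dropout = dropout, calibrate = calibrate, alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full primary-target / side-effect dissection pipeline
#'
#' Executes, in order: data simulation (or ingestion of supplied inputs),
#' differential-expression screening, hourly-grid interpolation, training
#' label derivation from the auxiliary p-value tables, balanced Random
#' Forest training with proximity-based outlier removal and a final
#' forest, vote-threshold calibration (optional), class prediction for
#' all DE genes, proximity computation over the confidently classified
#' genes, PAM clustering with silhouette-based k selection, second-stage
#' cluster-confidence filtering with per-cluster time-point importance,
#' and KS enrichment of clusters and of the unclassified genes for
#' Fisher-combined receptor-mutant perturbation p-values.
#'
#' The returned manifest records gene counts at every filtering stage,
#' and the whole run is a pure function of the configuration.
#'
#' @param cfg A [pipeline_config()].
#' @param inputs Optional list with real inputs instead of simulation:
#'   `tc` (ratio matrix), `tables` (list bpde1, bpde2, early, mutant1,
#'   mutant2), `map` (ortholog map). Exactly one of `cfg$sim` / `inputs`
#'   must be active.
#' @return List with every intermediate (`tc`, `truth`, `de`, `features`,
#'   `labels`, `training`, `model`, `tau`, `predictions`, `proximity`,
#'   `kselect`, `clusters`, `confidence`, `importance`, `enrichment`,
#'   `unclassified`, `perturb_p`) plus `manifest`.
#' @export
run_pipeline <- function(cfg, inputs = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$sim) == is.null(inputs))
    stop("run_pipeline: exactly one of cfg$sim and inputs must be given",
         call. = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if (!is.null(cfg$sim)) {
    sim <- stage("simulate", simulate_time_courses(cfg$sim))
    tc <- sim$tc; truth <- sim$truth
    tables <- stage("simulate", simulate_study_pvalues(truth, cfg$sim))
    map <- stage("simulate",
                 simulate_ortholog_map(truth, cfg$dropout,
                                       seed = sub_seed(cfg$seed, "map")))
  } else {
    tc <- inputs$tc; truth <- inputs$truth
    tables <- inputs$tables; map <- inputs$map
  }

  de <- stage("differential_expression",
              differential_expression(tc, fdr = cfg$fdr, fold = cfg$fold))
  de_genes <- de$gene_id[de$significant]
  if (length(de_genes) < 2)
    stop("pipeline stage 'differential_expression' failed: fewer than 2 ",
         "differentially expressed genes", call. = FALSE)
  features <- stage("interpolate", interpolate_profiles(tc, de_genes))

  labels <- stage("derive_labels",
                  derive_labels(tables$bpde1, tables$bpde2, tables$early,
                                map, alpha = cfg$alpha))
  lab <- stats::setNames(labels$label, labels$gene_id)
  lab <- lab[names(lab) %in% de_genes & lab != "unlabeled"]
  n_lab <- table(factor(lab, levels = c("primary", "side_effect")))
  if (any(n_lab < cfg$rf$per_class_sampsize))
    stop("pipeline stage 'train' failed: class '",
         names(n_lab)[which.min(n_lab)], "' has only ",
         min(n_lab), " labeled DE genes (need >= ",
         cfg$rf$per_class_sampsize, ")", call. = FALSE)

  cfg_init <- cfg$rf; cfg_init$seed <- sub_seed(cfg$seed, "rf_initial")
  initial <- stage("train",
                   train_forest(features, lab, cfg_init,
                                ntree = cfg$rf$ntree_initial))
  scores <- stage("outlier_filter",
                  outlier_scores(initial$rf$proximity, lab))
  training <- stage("outlier_filter",
                    filter_outliers(scores, lab, cfg$rf$outlier_percentile))
  cfg_final <- cfg$rf; cfg_final$seed <- sub_seed(cfg$seed, "rf_final")
  model <- stage("train",
                 train_forest(features, training, cfg_final,
                              ntree = cfg$rf$ntree_final))

  tau <- if (cfg$calibrate) {
    cfg_cal <- cfg$rf; cfg_cal$seed <- sub_seed(cfg$seed, "calibrate")
    stage("calibrate",
          calibrate_vote_threshold(features, training, cfg_cal))$tau
  } else cfg$rf$vote_threshold

  predictions <- stage("predict", predict_all(model, features, tau))
  confident <- predictions$gene_id[predictions$confident]
  if (length(confident) < max(3, max(cfg$k_range) + 1))
    stop("pipeline stage 'proximity' failed: too few confident genes (",
         length(confident), ")", call. = FALSE)
  prox <- stage("proximity", compute_proximity(model, features, confident))

  kselect <- stage("cluster", select_k(prox$D, cfg$k_range))
  clusters <- kselect$fits[[as.character(kselect$best_k)]]$assignment
  cfg_conf <- cfg$rf; cfg_conf$seed <- sub_seed(cfg$seed, "confidence")
  confidence <- stage("cluster_confidence",
                      cluster_confidence(features, clusters, cfg_conf,
                                         null_rule = cfg$null_rule))
  importance <- stage("importance", timepoint_importance(confidence))

  perturb_p <- stats::setNames(
    fisher_combine2(tables$mutant1$p[match(de_genes, tables$mutant1$gene_id)],
                    tables$mutant2$p[match(de_genes, tables$mutant2$gene_id)]),
    de_genes)
  enrichment <- stage("enrichment",
                      ks_enrichment(clusters, perturb_p,
                                    training_genes = names(training)))
  unclassified <- stage("enrichment",
                        unclassified_enrichment(predictions, perturb_p,
                                                names(training)))

  manifest <- list(
    seed = cfg$seed,
    n_genes = nrow(tc),
    n_de = length(de_genes),
    n_labeled_primary = unname(n_lab["primary"]),
    n_labeled_side = unname(n_lab["side_effect"]),
    n_train_primary = sum(training == "primary"),
    n_train_side = sum(training == "side_effect"),
    oob_error = model$oob_error,
    tau = tau,
    n_confident = length(confident),
    n_predicted_primary = sum(predictions$confident &
                                predictions$predicted_class == "primary"),
    n_predicted_side = sum(predictions$confident &
                             predictions$predicted_class == "side_effect"),
    n_unclassified = sum(!predictions$confident),
    best_k = kselect$best_k,
    cluster_sizes = as.integer(table(clusters)),
    n_retained = sum(confidence$retained),
    retained_per_cluster = as.integer(table(clusters[confidence$retained])))

  list(tc = tc, truth = truth, de = de, features = features,
       labels = labels, training = training, scores = scores,
       initial_model = initial, model = model, tau = tau,
       predictions = predictions, proximity = prox, kselect = kselect,
       clusters = clusters, confidence = confidence,
       importance = importance, perturb_p = perturb_p,
       enrichment = enrichment, unclassified = unclassified,
       manifest = manifest)
}
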