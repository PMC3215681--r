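#' Random Forest configuration
#'
#' Parameters of the balanced two-class forest and its confidence
#' calibration. Defaults follow the study design: an initial 5000-tree
#' forest for outlier detection, a 1000-tree final forest, `mtry = 5`
#' candidate features per split, a stratified bootstrap of 20 genes per
#' class per tree (to neutralize the heavy class imbalance), outlier
#' removal above the pooled 95th percentile, and a 0.8 vote-proportion
#' confidence threshold (the level permuted-label forests do not exceed).
#'
#' @param ntree_initial Trees in the outlier-detection forest.
#' @param ntree_final Trees in the final forest.
#' @param mtry Features sampled (without replacement) at each split.
#' @param per_class_sampsize Genes drawn per class (with replacement) per tree.
#' @param outlier_percentile Pooled quantile above which training genes
#'   are dropped as outliers.
#' @param vote_threshold Vote proportion above which a prediction counts
#'   as confident; in (0.5, 1].
#' @param n_permutations Label permutations for null calibration.
#' @param seed Integer seed.
#' @return An `rf_config` list.
#' @export
rf_config <- function(ntree_initial = 5000L, ntree_final = 1000L, mtry = 5L,
                      per_class_sampsize = 20L, outlier_percentile = 0.95,
                      vote_threshold = 0.8, n_permutations = 10L, seed = 1L) {
  if (vote_threshold <= 0.5 || vote_threshold > 1)
    stop("rf_config: vote_threshold must lie in (0.5, 1]", call. = FALSE)
  if (ntree_initial < 1 || ntree_final < 1 || mtry < 1 || per_class_sampsize < 1)
    stop("rf_config: counts must be positive", call. = FALSE)
  if (outlier_percentile <= 0 || outlier_percentile >= 1)
    stop("rf_config: outlier_percentile must lie in (0, 1)", call. = FALSE)
  structure(list(ntree_initial = as.integer(ntree_initial),
                 ntree_final = as.integer(ntree_final),
                 mtry = as.integer(mtry),
                 per_class_sampsize = as.integer(per_class_sampsize),
                 outlier_percentile = outlier_percentile,
                 vote_threshold = vote_threshold,
                 n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed)),
            class = "rf_config")
}

as_label_factor <- function(labels) {
  if (is.data.frame(labels)) {
    keep <- labels$label != "unlabeled"
    labels <- stats::setNames(labels$label[keep], labels$gene_id[keep])
  }
  y <- factor(labels)
  if (is.null(names(y)) || any(names(y) == ""))
    stop("labels must be named by gene id", call. = FALSE)
  y
}

#' Train a balanced Random Forest on interpolated expression features
#'
#' Each tree is grown to purity on a stratified bootstrap of
#' `per_class_sampsize` genes per class drawn with replacement, so the
#' minority class carries equal weight in every tree. Out-of-bag votes
#' (accumulated only from trees whose bootstrap excluded the gene) give
#' an unbiased error estimate; the proximity among training genes is
#' recorded for outlier screening.
#'
#' @param features Genes x feature matrix (rows named by gene id).
#' @param labels Named vector/factor of class labels, or a label table
#'   from [derive_labels()] (unlabeled genes are dropped).
#' @param cfg An [rf_config()].
#' @param ntree Number of trees; defaults to `cfg$ntree_final`.
#' @return A `tox_forest`: list with the fitted `randomForest` object
#'   (`rf`), `training_genes`, `oob_votes`, `oob_error`, `cfg`.
#' @export
train_forest <- function(features, labels, cfg = rf_config(),
                         ntree = cfg$ntree_final) {
  y <- as_label_factor(labels)
  missing <- setdiff(names(y), rownames(features))
  if (length(missing))
    stop("train_forest: labeled gene(s) missing from features: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  sizes <- table(y)
  if (any(sizes < cfg$per_class_sampsize))
    stop("train_forest: class '", names(sizes)[which.min(sizes)],
         "' has fewer than per_class_sampsize (", cfg$per_class_sampsize,
         ") members", call. = FALSE)
  if (cfg$mtry > ncol(features))
    stop("train_forest: mtry exceeds the number of features", call. = FALSE)
  x <- features[names(y), , drop = FALSE]
  set.seed(cfg$seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = ntree, mtry = cfg$mtry,
    replace = TRUE, strata = y,
    sampsize = rep(cfg$per_class_sampsize, nlevels(y)),
    proximity = TRUE, importance = TRUE, norm.votes = TRUE)
  structure(list(rf = rf,
                 training_genes = names(y),
                 labels = y,
                 oob_votes = rf$votes,
                 oob_error = unname(rf$err.rate[ntree, "OOB"]),
                 cfg = cfg),
            class = "tox_forest")
}

#' Breiman's proximity-based outlier score
#'
#' For training gene n in a set of N genes, the raw outlyingness is
#' `N / sum_k P(n,k)^2` over the other genes k of n's own class: a gene
#' whose proximities to its class are uniformly small scores high. Raw
#' scores are standardized within class by subtracting the class median
#' and dividing by the class median absolute deviation, clipping negative
#' values at zero. A class whose deviation is zero (all raw scores equal)
#' gets all-zero scores; a singleton class has no defined score and gets
#' 0 with a warning.
#'
#' @param P Proximity matrix restricted to the labeled training genes.
#' @param labels Named label vector/factor over the same genes.
#' @param standardize Return standardized (default) or raw scores.
#' @return Named numeric vector of outlier scores.
#' @export
outlier_scores <- function(P, labels, standardize = TRUE) {
  y <- as_label_factor(labels)
  genes <- names(y)
  stopifnot(all(genes %in% rownames(P)))
  P <- P[genes, genes, drop = FALSE]
  n <- length(genes)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    same <- which(y == y[i])
    same <- setdiff(same, i)
    if (length(same) == 0) {
      raw[i] <- NA_real_
      next
    }
    raw[i] <- n / sum(P[i, same]^2)
  }
  names(raw) <- genes
  if (anyNA(raw)) {
    warning("outlier_scores: singleton class; score set to 0")
    raw[is.na(raw)] <- 0
  }
  if (!standardize) return(raw)
  out <- raw
  for (cl in levels(y)) {
    idx <- which(y == cl)
    med <- stats::median(raw[idx])
    dev <- stats::median(abs(raw[idx] - med))
    out[idx] <- if (dev == 0) 0 else pmax(0, (raw[idx] - med) / dev)
  }
  out
}

#' Remove high-outlier-score genes from the training set
#'
#' Genes scoring strictly above the pooled (both-class)
#' `outlier_percentile` quantile of the scores are dropped. The threshold
#' is computed from the full score vector, so re-applying the filter to
#' its own output removes nothing further; when all scores are equal
#' (e.g. all zero) nothing is removed.
#'
#' @param scores Named score vector from [outlier_scores()].
#' @param labels Named label vector/factor (subset of `names(scores)`).
#' @param outlier_percentile Pooled quantile, in (0, 1).
#' @return The label factor restricted to retained genes.
#' @export
filter_outliers <- function(scores, labels, outlier_percentile = 0.95) {
  y <- as_label_factor(labels)
  if (!all(names(y) %in% names(scores)))
    stop("filter_outliers: scores missing for some labeled genes", call. = FALSE)
  cut <- stats::quantile(scores, outlier_percentile, type = 7, names = FALSE)
  keep <- names(y)[scores[names(y)] <= cut]
  droplevels(y[keep])
}

#' Calibrate the confident-vote threshold by label permutation
#'
#' Trains `n_permutations` forests with randomly permuted training labels
#' and predicts on all genes; the largest vote proportion any permuted
#' forest produces is the calibrated threshold: real predictions voting
#' above it exceed anything seen under the no-signal null.
#'
#' @param features Full genes x feature matrix (training and test genes).
#' @param labels Named training label vector/factor or label table.
#' @param cfg An [rf_config()]; permuted forests use `ntree_final` trees.
#' @return List: `tau` (the threshold), `per_permutation` max votes.
#' @export
calibrate_vote_threshold <- function(features, labels, cfg = rf_config()) {
  if (cfg$n_permutations < 1)
    stop("calibrate_vote_threshold: n_permutations must be >= 1", call. = FALSE)
  y <- as_label_factor(labels)
  maxes <- numeric(cfg$n_permutations)
  for (i in seq_len(cfg$n_permutations)) {
    set.seed(sub_seed(cfg$seed, paste0("calibrate", i)))
    perm <- stats::setNames(sample(as.character(y)), names(y))
    cfg_i <- cfg
    cfg_i$seed <- sub_seed(cfg$seed, paste0("calibrate_fit", i))
    model <- train_forest(features, perm, cfg_i, ntree = cfg$ntree_final)
    pred <- predict_all(model, features, tau = cfg$vote_threshold)
    maxes[i] <- max(pred$vote_proportion)
  }
  list(tau = max(maxes), per_permutation = maxes)
}

#' Predict classes and vote confidence for all genes
#'
#' Training genes receive their out-of-bag votes (so their confidence is
#' not inflated by memorization); all other genes receive full-forest
#' votes. The predicted class is the vote majority; a gene is confident
#' when its winning vote proportion strictly exceeds `tau`. Exact 0.5
#' ties go to the lexicographically smaller class name and are flagged.
#'
#' @param model A `tox_forest` from [train_forest()].
#' @param features Genes x feature matrix covering every gene to predict.
#' @param tau Confidence threshold (default: the model's configured one).
#' @return data.frame: `gene_id`, `predicted_class`, `vote_proportion`,
#'   `confident`, `source` ("training"/"test"), `tie`.
#' @export
predict_all <- function(model, features, tau = model$cfg$vote_threshold) {
  stopifnot(inherits(model, "tox_forest"))
  classes <- sort(levels(model$labels))
  genes <- rownames(features)
  votes <- matrix(NA_real_, nrow = length(genes), ncol = length(classes),
                  dimnames = list(genes, classes))
  train <- intersect(genes, model$training_genes)
  test <- setdiff(genes, train)
  if (length(train)) {
    ov <- model$oob_votes[train, classes, drop = FALSE]
    if (any(!is.finite(ov))) {
      warning("predict_all: some training genes were never out of bag; ",
              "using full-forest votes for them")
      bad <- rownames(ov)[apply(!is.finite(ov), 1, any)]
      ov[bad, ] <- stats::predict(model$rf, features[bad, , drop = FALSE],
                                  type = "vote", norm.votes = TRUE)[, classes]
    }
    votes[train, ] <- ov
  }
  if (length(test)) {
    if (!all(test %in% rownames(features)))
      stop("predict_all: gene(s) missing features", call. = FALSE)
    votes[test, ] <- stats::predict(model$rf, features[test, , drop = FALSE],
                                    type = "vote",
                                    norm.votes = TRUE)[, classes, drop = FALSE]
  }
  win <- max.col(votes, ties.method = "first")  # first = smaller class name
  vote_prop <- votes[cbind(seq_along(genes), win)]
  data.frame(
    gene_id = genes,
    predicted_class = classes[win],
    vote_proportion = vote_prop,
    confident = vote_prop > tau,
    source = ifelse(genes %in% train, "training", "test"),
    tie = abs(vote_prop - 0.5) < .Machine$double.eps^0.5 &
      length(classes) == 2,
    stringsAsFactors = FALSE)
}

#' Random Forest proximity among a set of genes
#'
#' The proximity of two genes is the fraction of trees in which they land
#' in the same terminal node, with every gene passed down every tree.
#' The returned dissimilarity D = 1 - P is the input for proximity-
#' weighted clustering.
#'
#' @param model A `tox_forest`.
#' @param features Genes x feature matrix.
#' @param genes Subset of genes (non-empty) over which to compute P.
#' @return List: `P` (symmetric, unit diagonal), `D = 1 - P`, `genes`.
#' @export
compute_proximity <- function(model, features, genes = rownames(features)) {
  stopifnot(inherits(model, "tox_forest"))
  if (length(genes) == 0)
    stop("compute_proximity: empty gene set", call. = FALSE)
  if (!all(genes %in% rownames(features)))
    stop("compute_proximity: gene(s) missing from features", call. = FALSE)
  pr <- stats::predict(model$rf, features[genes, , drop = FALSE],
                       proximity = TRUE)
  P <- pr$proximity[genes, genes, drop = FALSE]
  P <- (P + t(P)) / 2
  diag(P) <- 1
  list(P = P, D = 1 - P, genes = genes)
}
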