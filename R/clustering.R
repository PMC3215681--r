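check_dissimilarity <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("dissimilarity must be a square matrix", call. = FALSE)
  if (any(abs(D - t(D)) > 1e-8) || any(D < 0) || any(abs(diag(D)) > 1e-12))
    stop("dissimilarity must be symmetric, non-negative, with zero diagonal",
         call. = FALSE)
  invisible(D)
}

#' PAM (k-medoids) clustering of a dissimilarity matrix
#'
#' Partitioning around medoids: the BUILD phase greedily seeds k medoids
#' minimizing total dissimilarity, the SWAP phase applies the best
#' strictly improving (medoid, non-medoid) exchange until none remains,
#' and every point is assigned to its nearest medoid. The procedure is
#' deterministic. Delegates to `cluster::pam` on the dissimilarity.
#'
#' @param D Square symmetric non-negative dissimilarity with zero diagonal.
#' @param k Number of clusters, 2 <= k < n.
#' @return List: `assignment` (named integer cluster ids), `medoids`
#'   (ids of the medoid of each cluster), `cost` (total dissimilarity of
#'   points to their medoids), and the underlying `pam` fit.
#' @export
pam_cluster <- function(D, k) {
  check_dissimilarity(D)
  n <- nrow(D)
  if (k < 2 || k >= n)
    stop("pam_cluster: k must satisfy 2 <= k < n", call. = FALSE)
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("i", seq_len(n))
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE)
  medoid_idx <- fit$id.med
  assignment <- fit$clustering
  cost <- sum(D[cbind(seq_len(n), medoid_idx[assignment])])
  list(assignment = assignment, medoids = rownames(D)[medoid_idx],
       cost = cost, fit = fit)
}

# Direct silhouette widths for an assignment on a dissimilarity matrix.
# a(i): mean dissimilarity to own cluster (excluding self); b(i): smallest
# mean dissimilarity to another cluster; singletons score 0.
silhouette_widths <- function(D, assignment) {
  n <- nrow(D)
  cl <- as.integer(factor(assignment))
  ks <- sort(unique(cl))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(ks, cl[i]),
                    function(kk) mean(D[i, cl == kk]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  stats::setNames(s, rownames(D))
}

#' Select the number of clusters by average silhouette width
#'
#' Runs PAM for every k in `k_range` and picks the k whose mean
#' silhouette width is largest (ties go to the smaller k).
#'
#' @param D Dissimilarity matrix.
#' @param k_range Candidate cluster counts (default 2..8), within [2, n-1].
#' @return List: `best_k`, `avg_widths` (named by k), `fits` (the
#'   [pam_cluster()] result per k), `silhouette` (per-gene widths at
#'   `best_k`).
#' @export
select_k <- function(D, k_range = 2:8) {
  check_dissimilarity(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2) || any(k_range >= nrow(D)))
    stop("select_k: k_range must lie within [2, n-1]", call. = FALSE)
  fits <- lapply(k_range, function(k) pam_cluster(D, k))
  widths <- vapply(fits, function(f)
    mean(silhouette_widths(D, f$assignment)), numeric(1))
  names(widths) <- k_range
  best <- which.max(widths)  # first max -> smaller k on ties
  list(best_k = k_range[best], avg_widths = widths,
       fits = stats::setNames(fits, k_range),
       silhouette = silhouette_widths(D, fits[[best]]$assignment))
}

#' Cluster-confidence filtering with a second-stage Random Forest
#'
#' Fits a forest predicting cluster membership from the expression
#' features (stratified per-tree sampling, equal per cluster) and records
#' each gene's out-of-bag vote proportion for its own cluster. A null
#' distribution of own-cluster votes is built from forests trained on
#' permuted cluster labels; genes voting below the null's expectation
#' (its mean by default, or a quantile) fit their cluster no better than
#' chance and are flagged for exclusion.
#'
#' @param features Genes x feature matrix.
#' @param clusters Named cluster assignment (>= 2 clusters).
#' @param cfg An [rf_config()]; clusters smaller than
#'   `per_class_sampsize` shrink the per-tree sample with a warning.
#' @param null_rule "mean" (default) or "quantile".
#' @param null_quantile Quantile used when `null_rule = "quantile"`.
#' @return List: `cluster_vote` (own-cluster OOB vote per gene),
#'   `retained` (logical), `threshold`, `null_votes`, `forest`.
#' @export
cluster_confidence <- function(features, clusters, cfg = rf_config(),
                               null_rule = c("mean", "quantile"),
                               null_quantile = 0.95) {
  null_rule <- match.arg(null_rule)
  y <- factor(clusters)
  names(y) <- names(clusters)
  if (nlevels(y) < 2)
    stop("cluster_confidence: need >= 2 clusters", call. = FALSE)
  sizes <- table(y)
  samp <- min(cfg$per_class_sampsize, min(sizes))
  if (samp < cfg$per_class_sampsize)
    warning("cluster_confidence: smallest cluster (", min(sizes),
            ") below per_class_sampsize; shrinking per-tree sample to ", samp)
  fit_one <- function(yy, seed) {
    set.seed(seed)
    randomForest::randomForest(
      x = features[names(yy), , drop = FALSE], y = yy,
      ntree = cfg$ntree_final, mtry = cfg$mtry,
      replace = TRUE, strata = yy, sampsize = rep(samp, nlevels(yy)),
      importance = TRUE)
    }
  own_vote <- function(rf, yy)
    rf$votes[cbind(seq_along(yy), match(as.character(yy), colnames(rf$votes)))]
  rf <- fit_one(y, sub_seed(cfg$seed, "cluster_confidence"))
  vote <- stats::setNames(own_vote(rf, y), names(y))
  null_votes <- unlist(lapply(seq_len(cfg$n_permutations), function(i) {
    set.seed(sub_seed(cfg$seed, paste0("cluster_null_perm", i)))
    yp <- stats::setNames(sample(y), names(y))
    own_vote(fit_one(yp, sub_seed(cfg$seed, paste0("cluster_null_fit", i))), yp)
  }))
  threshold <- if (null_rule == "mean") mean(null_votes) else
    stats::quantile(null_votes, null_quantile, names = FALSE)
  list(cluster_vote = vote, retained = vote >= threshold,
       threshold = threshold, null_votes = null_votes, forest = rf)
}

#' Per-cluster permutation importance of the time-point features
#'
#' For each feature, the class-specific permutation importance of the
#' cluster-confidence forest: the mean decrease in own-cluster out-of-bag
#' accuracy when that feature is permuted. High values mark the (dose,
#' hour) positions that define a cluster's identity.
#'
#' @param confidence Result of [cluster_confidence()] (or a fitted
#'   `randomForest` with `importance = TRUE`).
#' @return Matrix clusters x features of raw mean accuracy decreases.
#' @export
timepoint_importance <- function(confidence) {
  rf <- if (inherits(confidence, "randomForest")) confidence else
    confidence$forest
  if (is.null(rf$importance))
    stop("timepoint_importance: forest was fitted without importance",
         call. = FALSE)
  cls <- colnames(rf$votes)
  t(rf$importance[, cls, drop = FALSE])
}
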