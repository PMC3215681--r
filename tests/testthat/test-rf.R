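small_cfg <- function(seed = 1, ...) {
  rf_config(ntree_initial = 300L, ntree_final = 200L, mtry = 3L,
            per_class_sampsize = 15L, n_permutations = 3L, seed = seed, ...)
}

test_that("a separable toy is learned almost perfectly; permuted labels are not", {
  toy <- make_separable_features(seed = 2)
  m <- train_forest(toy$x, toy$y, small_cfg(seed = 4))
  expect_lte(m$oob_error, 0.05)
  expect_equal(unname(rowSums(m$oob_votes)), rep(1, 100), tolerance = 1e-12)
  set.seed(5)
  yperm <- stats::setNames(sample(toy$y), names(toy$y))
  mp <- train_forest(toy$x, yperm, small_cfg(seed = 4))
  expect_gt(mp$oob_error, 0.35)
  expect_lt(mp$oob_error, 0.65)
})

test_that("training guards reject unusable configurations", {
  toy <- make_separable_features(n_per_class = 10, seed = 3)
  expect_error(train_forest(toy$x, toy$y, small_cfg()),
               "fewer than per_class_sampsize")
  big_mtry <- rf_config(mtry = 99L, per_class_sampsize = 5L)
  expect_error(train_forest(toy$x, toy$y, big_mtry), "mtry exceeds")
  expect_error(rf_config(vote_threshold = 0.4), "vote_threshold")
})

test_that("Breiman raw outlier scores equal the direct formula", {
  P <- matrix(c(1.0, 0.9, 0.8, 0.1,
                0.9, 1.0, 0.7, 0.2,
                0.8, 0.7, 1.0, 0.3,
                0.1, 0.2, 0.3, 1.0), 4, 4,
              dimnames = list(paste0("g", 1:4), paste0("g", 1:4)))
  y <- stats::setNames(c("a", "a", "a", "a"), paste0("g", 1:4))
  raw <- outlier_scores(P, y, standardize = FALSE)
  expect_equal(unname(raw["g1"]), 4 / (0.9^2 + 0.8^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(unname(raw["g4"]), 4 / (0.1^2 + 0.2^2 + 0.3^2), tolerance = 1e-12)
  # lowering a gene's within-class proximities raises its raw score
  P2 <- P
  P2["g1", c("g2", "g3", "g4")] <- P2[c("g2", "g3", "g4"), "g1"] <-
    P["g1", c("g2", "g3", "g4")] / 2
  raw2 <- outlier_scores(P2, y, standardize = FALSE)
  expect_gt(raw2["g1"], raw["g1"])
})

test_that("outlier standardization zeroes constant classes and warns on singletons", {
  P <- matrix(0.5, 6, 6); diag(P) <- 1
  rownames(P) <- colnames(P) <- paste0("g", 1:6)
  y <- stats::setNames(rep(c("a", "b"), each = 3), rownames(P))
  s <- outlier_scores(P, y)
  expect_equal(unname(s), rep(0, 6))
  y1 <- stats::setNames(c("a", "a", "a", "b"), paste0("g", 1:4))
  expect_warning(s1 <- outlier_scores(P[1:4, 1:4], y1), "singleton")
  expect_equal(unname(s1["g4"]), 0)
})

test_that("outlier filtering removes scores strictly above the pooled quantile", {
  set.seed(11)
  sc <- stats::setNames(sample(seq(0.01, 1, length.out = 100)),
                        paste0("g", 1:100))
  y <- stats::setNames(rep(c("a", "b"), 50), names(sc))
  kept <- filter_outliers(sc, y, 0.95)
  expect_identical(length(kept), 95L)
  expect_true(all(sc[names(kept)] <= sort(sc, decreasing = TRUE)[5]))
  # all-zero scores: nothing removed
  z <- stats::setNames(rep(0, 100), names(sc))
  expect_identical(length(filter_outliers(z, y, 0.95)), 100L)
  # 20 distinct scores: exactly the top one removed
  sc20 <- stats::setNames(seq_len(20) / 20, paste0("g", 1:20))
  y20 <- stats::setNames(rep(c("a", "b"), 10), names(sc20))
  kept20 <- filter_outliers(sc20, y20, 0.95)
  expect_identical(sort(names(kept20)), sort(names(sc20)[1:19]))
  # idempotent against the same score vector
  again <- filter_outliers(sc, kept, 0.95)
  expect_identical(sort(names(again)), sort(names(kept)))
})

test_that("vote-threshold calibration stays within (0.5, 1] and errors without permutations", {
  set.seed(6)
  x <- matrix(rnorm(60 * 8), 60, 8,
              dimnames = list(paste0("g", 1:60), paste0("f", 1:8)))
  y <- stats::setNames(rep(c("primary", "side_effect"), each = 20),
                       paste0("g", 1:40))
  cfg <- small_cfg(seed = 8)
  cal <- calibrate_vote_threshold(x, y, cfg)
  expect_gte(cal$tau, 0.5)
  expect_lte(cal$tau, 1)
  expect_length(cal$per_permutation, cfg$n_permutations)
  # structureless features: no permuted forest reaches unanimity
  expect_lt(cal$tau, 1)
  cfg0 <- cfg; cfg0$n_permutations <- 0L
  expect_error(calibrate_vote_threshold(x, y, cfg0), "n_permutations")
})

test_that("predictions use OOB votes for training genes and apply the strict threshold", {
  toy <- make_separable_features(seed = 12)
  train_ids <- sample(rownames(toy$x), 60)
  m <- train_forest(toy$x, toy$y[train_ids], small_cfg(seed = 9))
  pred <- predict_all(m, toy$x, tau = 0.8)
  expect_setequal(pred$gene_id, rownames(toy$x))
  expect_identical(pred$source[match(train_ids, pred$gene_id)],
                   rep("training", 60))
  expect_identical(pred$confident, pred$vote_proportion > 0.8)
  expect_true(all(pred$vote_proportion >= 0.5 - 1e-12))
  # exact 0.5 ties go to the lexicographically smaller class and are flagged
  ties <- abs(pred$vote_proportion - 0.5) < 1e-12
  if (any(ties))
    expect_true(all(pred$predicted_class[ties] == "primary" & pred$tie[ties]))
  # training genes carry OOB votes, not refitted ones
  ov <- m$oob_votes
  win <- pmax(ov[, 1], ov[, 2])
  expect_equal(pred$vote_proportion[match(rownames(ov), pred$gene_id)],
               unname(win), tolerance = 1e-12)
})

test_that("proximity is a unit-diagonal symmetric co-leaf frequency", {
  toy <- make_separable_features(n_per_class = 25, seed = 13)
  # two clones and a third gene differing in the split feature
  x <- toy$x
  x["g2", ] <- x["g1", ]
  m <- train_forest(x, toy$y, small_cfg(seed = 10))
  pr <- compute_proximity(m, x)
  expect_equal(pr$P, t(pr$P))
  expect_equal(unname(diag(pr$P)), rep(1, nrow(x)))
  expect_true(all(pr$P >= 0 & pr$P <= 1))
  expect_equal(pr$D, 1 - pr$P)
  # identical feature vectors always share a leaf
  expect_equal(unname(pr$P["g1", "g2"]), 1)
  # and are at least as close to each other as to any differing gene
  expect_true(all(pr$P["g1", "g2"] >= pr$P["g1", ] - 1e-12))
  # a one-tree forest puts every pair either together or apart
  m1 <- train_forest(x, toy$y, small_cfg(seed = 11), ntree = 1)
  p1 <- compute_proximity(m1, x)$P
  expect_true(all(p1 %in% c(0, 1)))
  # a two-tree forest can only produce 0, 1/2, 1
  m2 <- train_forest(x, toy$y, small_cfg(seed = 12), ntree = 2)
  p2 <- compute_proximity(m2, x)$P
  expect_true(all(abs(p2 - round(p2 * 2) / 2) < 1e-12))
  expect_error(compute_proximity(m, x, character(0)), "empty")
  expect_error(compute_proximity(m, x, "nope"), "missing")
})
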