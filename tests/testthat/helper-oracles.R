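# Independent oracles used to cross-check the package's computations.
# These deliberately avoid the code paths (and, where possible, the
# library calls) used by the implementation.

# Natural cubic spline through (x, y), evaluated at xout, via the
# textbook tridiagonal solve for the knot second derivatives.
oracle_natural_spline <- function(x, y, xout) {
  n <- length(x)
  h <- diff(x)
  A <- matrix(0, n, n)
  b <- numeric(n)
  A[1, 1] <- 1
  A[n, n] <- 1
  for (i in 2:(n - 1)) {
    A[i, i - 1] <- h[i - 1]
    A[i, i] <- 2 * (h[i - 1] + h[i])
    A[i, i + 1] <- h[i]
    b[i] <- 6 * ((y[i + 1] - y[i]) / h[i] - (y[i] - y[i - 1]) / h[i - 1])
  }
  m <- solve(A, b)  # second derivatives, m[1] = m[n] = 0
  vapply(xout, function(t) {
    i <- findInterval(t, x, rightmost.closed = TRUE)
    i <- min(max(i, 1), n - 1)
    dx <- x[i + 1] - t
    dx2 <- t - x[i]
    (m[i] * dx^3 + m[i + 1] * dx2^3) / (6 * h[i]) +
      (y[i] / h[i] - m[i] * h[i] / 6) * dx +
      (y[i + 1] / h[i] - m[i + 1] * h[i] / 6) * dx2
  }, numeric(1))
}

# Exhaustive k-medoids: minimum total dissimilarity over all C(n, k)
# medoid sets.
oracle_kmedoids_cost <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  sets <- utils::combn(n, k)
  for (j in seq_len(ncol(sets))) {
    cost <- sum(apply(D[, sets[, j], drop = FALSE], 1, min))
    if (cost < best) best <- cost
  }
  best
}

# One-sided two-sample KS statistic D+ = sup_t (F_x(t) - F_y(t)),
# computed directly from the empirical CDFs on the pooled support.
oracle_ks_plus <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Fx <- vapply(grid, function(t) mean(x <= t), numeric(1))
  Fy <- vapply(grid, function(t) mean(y <= t), numeric(1))
  max(Fx - Fy)
}

# Chi-square upper tail at x with 2k df via the closed-form series for
# even degrees of freedom: exp(-x/2) * sum_{j<k} (x/2)^j / j!.
oracle_chisq_upper_even <- function(x, k) {
  j <- 0:(k - 1)
  exp(-x / 2) * sum((x / 2)^j / factorial(j))
}

# Balanced two-way ANOVA with replication by explicit sums of squares.
oracle_anova2 <- function(y, dose, time) {
  dose <- factor(dose); time <- factor(time)
  N <- length(y)
  gm <- mean(y)
  cell <- interaction(dose, time)
  m_d <- tapply(y, dose, mean); n_d <- table(dose)
  m_t <- tapply(y, time, mean); n_t <- table(time)
  m_c <- tapply(y, cell, mean); n_c <- table(cell)
  ss_dose <- sum(n_d * (m_d - gm)^2)
  ss_time <- sum(n_t * (m_t - gm)^2)
  ss_cell <- sum(n_c * (m_c - gm)^2)
  ss_int <- ss_cell - ss_dose - ss_time
  ss_err <- sum((y - m_c[cell])^2)
  df_d <- nlevels(dose) - 1
  df_t <- nlevels(time) - 1
  df_i <- df_d * df_t
  df_e <- N - nlevels(cell)
  F_d <- (ss_dose / df_d) / (ss_err / df_e)
  F_t <- (ss_time / df_t) / (ss_err / df_e)
  F_i <- (ss_int / df_i) / (ss_err / df_e)
  list(F_dose = F_d, F_time = F_t, F_inter = F_i,
       p_dose = stats::pf(F_d, df_d, df_e, lower.tail = FALSE),
       p_time = stats::pf(F_t, df_t, df_e, lower.tail = FALSE),
       p_inter = stats::pf(F_i, df_i, df_e, lower.tail = FALSE))
}

# Block-structured dissimilarity: within-block `within`, between `between`.
make_blob_D <- function(sizes, within = 0.1, between = 0.9) {
  lab <- rep(seq_along(sizes), sizes)
  n <- length(lab)
  D <- matrix(between, n, n)
  for (g in seq_along(sizes)) D[lab == g, lab == g] <- within
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("g", seq_len(n))
  D
}

# Random symmetric dissimilarity with zero diagonal.
random_D <- function(n, seed) {
  set.seed(seed)
  M <- matrix(stats::runif(n * n), n, n)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  rownames(D) <- colnames(D) <- paste0("g", seq_len(n))
  D
}

# Two-class toy feature matrix separable on the first feature.
make_separable_features <- function(n_per_class = 50, n_feat = 10, gap = 4,
                                    sd = 0.5, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(stats::rnorm(n * n_feat, 0, sd), n, n_feat)
  x[seq_len(n_per_class), 1] <- x[seq_len(n_per_class), 1] + gap
  rownames(x) <- paste0("g", seq_len(n))
  colnames(x) <- paste0("f", seq_len(n_feat))
  y <- stats::setNames(rep(c("primary", "side_effect"), each = n_per_class),
                       rownames(x))
  list(x = x, y = y)
}

# Blob-structured dissimilarity with symmetric jitter: clusterable data
# on which BUILD+SWAP k-medoids attains the exhaustive optimum.
jittered_blob_D <- function(sizes, seed, within = 0.15, between = 0.8,
                            jitter = 0.1) {
  D <- make_blob_D(sizes, within, between)
  set.seed(seed)
  n <- nrow(D)
  J <- matrix(stats::runif(n * n, -jitter, jitter), n, n)
  J <- (J + t(J)) / 2
  D <- pmax(D + J, 0)
  diag(D) <- 0
  D
}
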