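make_tc <- function(values, genes = paste0("g", seq_len(nrow(values)))) {
  cols <- as.vector(outer(1:3, as.vector(outer(c(2, 4, 12, 24), c("low", "high"),
    function(t, d) paste(d, t, sep = "_"))), function(r, dt) paste(dt, r, sep = "_")))
  stopifnot(ncol(values) == length(cols))
  dimnames(values) <- list(genes, cols)
  values
}

test_that("vehicle subtraction matches cells and flags design mismatches", {
  set.seed(1)
  treated <- make_tc(matrix(rnorm(2 * 24), 2))
  expect_equal(subtract_vehicle(treated, treated),
               treated * 0, ignore_attr = FALSE)
  zero <- treated * 0
  expect_equal(subtract_vehicle(treated, zero), treated)
  # vehicle shared across doses, keyed time_rep
  veh <- matrix(rnorm(2 * 12), 2,
                dimnames = list(rownames(treated),
                                as.vector(outer(c(2, 4, 12, 24), 1:3, paste,
                                                sep = "_"))))
  out <- subtract_vehicle(treated, veh)
  expect_equal(out[, "low_4_2"], treated[, "low_4_2"] - veh[, "4_2"])
  expect_equal(out[, "high_4_2"], treated[, "high_4_2"] - veh[, "4_2"])
  # simple arithmetic
  t2 <- treated; t2[1, 1:2] <- c(3, 5)
  v2 <- treated * 0; v2[1, 1:2] <- c(1, 1.5)
  expect_equal(unname(subtract_vehicle(t2, v2)[1, 1:2]), c(2, 3.5))
  # missing cell
  expect_error(subtract_vehicle(treated, veh[, -1]), "lacks cell")
  expect_error(subtract_vehicle(treated,
                                veh[1, , drop = FALSE]), "gene sets differ")
})

test_that("exon summarization averages constituent exons", {
  m <- matrix(c(0, 0, 6, 1, 3, 5), nrow = 3,
              dimnames = list(c("e1", "e2", "e3"), c("c1", "c2")))
  map <- data.frame(exon_id = c("e1", "e2", "e3"),
                    gene_id = c("gA", "gA", "gA"))
  out <- summarize_exons(m, map)
  expect_equal(unname(out["gA", ]), c(mean(c(0, 0, 6)), mean(c(1, 3, 5))))
  # single-exon gene passes through
  map2 <- data.frame(exon_id = c("e1", "e2", "e3"),
                     gene_id = c("gA", "gA", "gB"))
  out2 <- summarize_exons(m, map2)
  expect_equal(out2["gB", ], m["e3", ])
  expect_equal(unname(out2["gA", "c1"]), 0)
  expect_error(summarize_exons(m, map2[-1, ]), "unmapped exon")
  dup <- rbind(map2, data.frame(exon_id = "e1", gene_id = "gC"))
  expect_error(summarize_exons(m, dup), "more than one gene")
})

test_that("ANOVA F statistics match an explicit sums-of-squares oracle", {
  set.seed(42)
  tc <- make_tc(matrix(rnorm(5 * 24, sd = 1) +
                         rep(c(2, 0, 0, 0, 1), 24), 5))
  des <- do.call(rbind, strsplit(colnames(tc), "_"))
  suppressWarnings(de <- differential_expression(tc))
  for (i in 1:5) {
    o <- oracle_anova2(tc[i, ], dose = des[, 1], time = des[, 2])
    expect_equal(de$p_dose[i], o$p_dose, tolerance = 1e-10)
    expect_equal(de$p_time[i], o$p_time, tolerance = 1e-10)
    expect_equal(de$p_interaction[i], o$p_inter, tolerance = 1e-10)
  }
})

test_that("DE calling applies both the FDR and the fold-change filter", {
  set.seed(7)
  base <- matrix(rnorm(40 * 24, sd = 0.2), 40)
  # gene 1: strong consistent shift at high dose (passes both filters)
  base[1, 13:24] <- base[1, 13:24] + 3
  # gene 2: highly significant dose effect but under 2-fold
  base[2, 13:24] <- base[2, 13:24] + 0.5
  # gene 3: exactly zero everywhere
  base[3, ] <- 0
  tc <- make_tc(base)
  suppressWarnings(de <- differential_expression(tc, fdr = 0.05, fold = 2))
  expect_true(de$significant[1])
  expect_true(de$q_dose[2] < 0.05)
  expect_lt(de$max_abs_log2[2], 1)
  expect_false(de$significant[2])  # fold filter blocks it
  expect_false(de$significant[3])
  expect_equal(de$p_time[3], 1)   # degenerate gene reported as p = 1
})

test_that("a gene with zero variance everywhere triggers a warning", {
  m <- make_tc(matrix(0, 1, 24))
  expect_warning(differential_expression(m), "zero residual variance")
})

test_that("BH adjustment is monotone and bounded by the p-values", {
  set.seed(3)
  tc <- make_tc(matrix(rnorm(50 * 24), 50))
  de <- differential_expression(tc)
  for (eff in c("time", "dose", "interaction")) {
    p <- de[[paste0("p_", eff)]]
    q <- de[[paste0("q_", eff)]]
    expect_true(all(q >= p - 1e-12))
    expect_true(all(q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))
  }
})

test_that("interpolation reproduces knots, anchors t = 0, and averages the
           linear and natural-spline interpolants", {
  # single gene with chosen replicate means
  knots <- c(low_2 = 1, low_4 = 3, low_12 = 0, low_24 = 0,
             high_2 = 0, high_4 = 0, high_12 = 0, high_24 = 0)
  vals <- rep(knots, each = 3)
  tc <- matrix(vals, nrow = 1,
               dimnames = list("g1", paste(rep(names(knots), each = 3),
                                           1:3, sep = "_")))
  colnames(tc) <- sub("(low|high)_([0-9]+)_([0-9]+)", "\\1_\\2_\\3",
                      colnames(tc))
  feat <- interpolate_profiles(tc)
  expect_identical(ncol(feat), 50L)
  expect_equal(unname(feat[1, "low_h0"]), 0)
  expect_equal(unname(feat[1, "high_h0"]), 0)
  # exact at knots
  expect_equal(unname(feat[1, "low_h2"]), 1)
  expect_equal(unname(feat[1, "low_h4"]), 3)
  expect_equal(unname(feat[1, "low_h12"]), 0)
  expect_equal(unname(feat[1, "low_h24"]), 0)
  # hybrid value at t = 3: mean of linear (2.0) and the natural spline
  x <- c(0, 2, 4, 12, 24); y <- c(0, 1, 3, 0, 0)
  spl3 <- oracle_natural_spline(x, y, 3)
  expect_equal(unname(feat[1, "low_h3"]), (2 + spl3) / 2, tolerance = 1e-10)
  # all-zero dose stays zero
  expect_true(all(feat[1, paste0("high_h", 0:24)] == 0))
})

test_that("interpolation equals the linear interpolant on collinear knots", {
  slope_knots <- c(2, 4, 12, 24) / 6
  vals <- rep(rep(slope_knots, 2), each = 3)
  tc <- matrix(vals, nrow = 1,
               dimnames = list("g1",
                 paste(rep(paste(rep(c("low", "high"), each = 4),
                                 c(2, 4, 12, 24), sep = "_"), each = 3),
                       1:3, sep = "_")))
  feat <- interpolate_profiles(tc)
  expect_equal(unname(feat[1, paste0("low_h", 0:24)]), (0:24) / 6,
               tolerance = 1e-10)
})

test_that("design times beyond the 24 h grid are rejected", {
  tc <- matrix(rnorm(12), 1,
               dimnames = list("g1",
                 paste(rep(c("low", "high"), each = 6),
                       rep(c(2, 26, 4), 2), rep(1:2, 6)[1:6], sep = "_")))
  expect_error(interpolate_profiles(tc), "beyond 24 h")
})
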