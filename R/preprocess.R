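#' @importFrom stats p.adjust pchisq pt qnorm quantile runif rnorm rbeta
NULL

# Parse `dose_time_rep` column names into a design data.frame.
tc_design <- function(tc) {
  parts <- strsplit(colnames(tc), "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("malformed design column name(s): ",
         paste(colnames(tc)[bad], collapse = ", "), call. = FALSE)
  data.frame(dose = vapply(parts, `[`, "", 1L),
             time = as.numeric(vapply(parts, `[`, "", 2L)),
             rep = as.integer(vapply(parts, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# Per-gene replicate means over (dose, time) cells. Returns genes x cells
# matrix with `dose_time` column names.
cell_means <- function(tc) {
  des <- tc_design(tc)
  cell <- paste(des$dose, des$time, sep = "_")
  groups <- split(seq_len(ncol(tc)), factor(cell, levels = unique(cell)))
  out <- vapply(groups, function(j) rowMeans(tc[, j, drop = FALSE]),
                numeric(nrow(tc)))
  if (nrow(tc) == 1) out <- matrix(out, nrow = 1, dimnames = list(rownames(tc), names(groups)))
  out
}

#' Subtract vehicle-control expression from treated expression
#'
#' Converts absolute log2 expression into log2 treatment/vehicle ratios by
#' subtracting, for each (time, replicate/batch), the matched vehicle
#' value. The vehicle matrix may either share the treated matrix's full
#' `dose_time_rep` design, or carry one `time_rep` column per (time,
#' batch) shared across doses (the usual case: one DMSO series per batch).
#'
#' @param treated Genes x design matrix of log2 expression, columns
#'   `dose_time_rep`.
#' @param vehicle Matching vehicle matrix (same genes), columns either
#'   `dose_time_rep` or `time_rep`.
#' @return A time-course matrix of log2 ratios with `treated`'s design.
#' @export
subtract_vehicle <- function(treated, vehicle) {
  if (!setequal(rownames(treated), rownames(vehicle)))
    stop("subtract_vehicle: treated and vehicle gene sets differ", call. = FALSE)
  vehicle <- vehicle[rownames(treated), , drop = FALSE]
  des <- tc_design(treated)
  key <- paste(des$time, des$rep, sep = "_")
  if (identical(sort(colnames(vehicle)), sort(colnames(treated)))) {
    vcols <- colnames(treated)
  } else {
    missing <- setdiff(unique(key), colnames(vehicle))
    if (length(missing))
      stop("subtract_vehicle: vehicle lacks cell(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    vcols <- key
  }
  out <- treated - vehicle[, vcols, drop = FALSE]
  if (any(!is.finite(out)))
    stop("subtract_vehicle: non-finite ratio produced", call. = FALSE)
  out
}

#' Summarize exon-level expression to gene level
#'
#' Gene expression is the arithmetic mean of the gene's constituent exons,
#' per design cell.
#'
#' @param exon_matrix Exons x design matrix.
#' @param exon_to_gene data.frame with columns `exon_id`, `gene_id`;
#'   every exon in the matrix must map to exactly one gene.
#' @return Genes x design matrix.
#' @export
summarize_exons <- function(exon_matrix, exon_to_gene) {
  stopifnot(all(c("exon_id", "gene_id") %in% colnames(exon_to_gene)))
  if (anyDuplicated(exon_to_gene$exon_id))
    stop("summarize_exons: exon mapped to more than one gene: ",
         exon_to_gene$exon_id[duplicated(exon_to_gene$exon_id)][1], call. = FALSE)
  idx <- match(rownames(exon_matrix), exon_to_gene$exon_id)
  if (anyNA(idx))
    stop("summarize_exons: unmapped exon(s): ",
         paste(utils::head(rownames(exon_matrix)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  gene <- exon_to_gene$gene_id[idx]
  sums <- rowsum(exon_matrix, group = gene)
  counts <- as.vector(table(gene)[rownames(sums)])
  sums / counts
}

#' Differential-expression screen on a log2-ratio time course
#'
#' Per gene, a fixed-effects two-way ANOVA with time and dose as factors
#' (replicates as the error stratum) gives p-values for the two main
#' effects and their interaction; per dose, a one-sample t-test of all
#' that dose's ratios (time points pooled) against 0 gives a marginal
#' response p-value. Each p-value family is Benjamini-Hochberg adjusted
#' across genes separately. A gene is called significant when any of the
#' five adjusted p-values falls below `fdr` and its largest absolute
#' replicate-mean log2 ratio over (dose, time) cells reaches `log2(fold)`.
#'
#' Genes whose ratios have zero variance everywhere have no defined ANOVA
#' F statistic; their p-values are reported as 1 with a warning.
#'
#' @param tc Time-course ratio matrix (columns `dose_time_rep`), with at
#'   least 2 replicates per cell, 2 time levels and 2 dose levels.
#' @param fdr FDR threshold applied to the adjusted p-values.
#' @param fold Fold-change threshold (on the natural scale; 2 means a
#'   max absolute log2 ratio of at least 1).
#' @return data.frame with per-gene p/q-values for the three ANOVA
#'   effects and two pooled t-tests, `max_abs_log2`, and `significant`.
#' @export
differential_expression <- function(tc, fdr = 0.05, fold = 2) {
  des <- tc_design(tc)
  if (length(unique(des$dose)) != 2 || length(unique(des$time)) < 2)
    stop("differential_expression: need 2 dose levels and >= 2 time levels",
         call. = FALSE)
  if (min(table(paste(des$dose, des$time))) < 2)
    stop("differential_expression: need >= 2 replicates per cell", call. = FALSE)
  genes <- rownames(tc)
  dose <- factor(des$dose)
  time <- factor(des$time)

  Y <- t(tc)
  fit <- stats::aov(Y ~ dose * time)
  sums <- summary(fit)
  pv <- vapply(sums, function(s) {
    tab <- s[["Pr(>F)"]]
    if (is.null(tab)) tab <- as.data.frame(s)[["Pr(>F)"]]
    tab[1:3]
  }, numeric(3))
  # summary.maov names rows dose, time, dose:time in formula order
  p_dose <- pv[1, ]; p_time <- pv[2, ]; p_inter <- pv[3, ]
  degenerate <- !is.finite(p_dose) | !is.finite(p_time) | !is.finite(p_inter)
  if (any(degenerate)) {
    warning(sum(degenerate),
            " gene(s) with undefined ANOVA F (zero residual variance); p set to 1")
    p_dose[degenerate] <- 1; p_time[degenerate] <- 1; p_inter[degenerate] <- 1
  }

  pooled_t <- function(d) {
    x <- tc[, des$dose == d, drop = FALSE]
    vapply(seq_len(nrow(x)), function(i) {
      xi <- x[i, ]
      if (stats::sd(xi) == 0) return(if (all(xi == 0)) 1 else 0)
      stats::t.test(xi, mu = 0)$p.value
    }, numeric(1))
  }
  dose_levels <- unique(des$dose)
  p_t_low <- pooled_t(dose_levels[1])
  p_t_high <- pooled_t(dose_levels[2])

  means <- cell_means(tc)
  max_abs_log2 <- apply(abs(means), 1, max)

  out <- data.frame(
    gene_id = genes,
    p_time = unname(p_time), p_dose = unname(p_dose),
    p_interaction = unname(p_inter),
    q_time = p.adjust(p_time, "BH"), q_dose = p.adjust(p_dose, "BH"),
    q_interaction = p.adjust(p_inter, "BH"),
    p_t_low = p_t_low, p_t_high = p_t_high,
    q_t_low = p.adjust(p_t_low, "BH"), q_t_high = p.adjust(p_t_high, "BH"),
    max_abs_log2 = unname(max_abs_log2),
    stringsAsFactors = FALSE)
  out$significant <- (out$q_time < fdr | out$q_dose < fdr |
                        out$q_interaction < fdr |
                        out$q_t_low < fdr | out$q_t_high < fdr) &
    out$max_abs_log2 >= log2(fold)
  rownames(out) <- NULL
  out
}

#' Hybrid linear/spline interpolation of time courses onto an hourly grid
#'
#' For each gene and dose, the replicate-mean log2 ratios at the design
#' times, anchored at (0, 0) (expression is assumed equal to vehicle at
#' time 0), are interpolated onto integer hours 0..24 as the average of
#' the simple linear interpolant and a natural cubic spline through the
#' same knots. This yields 25 values per dose, i.e. a 50-length feature
#' vector per gene (low dose hours 0..24, then high dose).
#'
#' @param tc Time-course ratio matrix; design times must not exceed 24 h.
#' @param genes Subset of genes to interpolate (default: all).
#' @return Genes x 50 feature matrix, columns `<dose>_h<hour>`.
#' @export
interpolate_profiles <- function(tc, genes = rownames(tc)) {
  if (!all(genes %in% rownames(tc)))
    stop("interpolate_profiles: unknown gene(s): ",
         paste(utils::head(setdiff(genes, rownames(tc)), 5), collapse = ", "),
         call. = FALSE)
  des <- tc_design(tc)
  if (max(des$time) > 24)
    stop("interpolate_profiles: design times beyond 24 h are not covered by the grid",
         call. = FALSE)
  grid <- 0:24
  means <- cell_means(tc[genes, , drop = FALSE])
  mean_des <- do.call(rbind, strsplit(colnames(means), "_", fixed = TRUE))
  doses <- unique(des$dose)
  out <- matrix(NA_real_, nrow = length(genes), ncol = 2 * length(grid),
                dimnames = list(genes,
                                paste0(rep(doses, each = length(grid)),
                                       "_h", rep(grid, 2))))
  for (d in doses) {
    sel <- mean_des[, 1] == d
    kt <- c(0, as.numeric(mean_des[sel, 2]))
    ord <- order(kt)
    for (i in seq_along(genes)) {
      ky <- c(0, means[i, sel])[ord]
      lin <- stats::approx(kt[ord], ky, xout = grid)$y
      spl <- stats::spline(kt[ord], ky, xout = grid, method = "natural")$y
      out[i, paste0(d, "_h", grid)] <- (lin + spl) / 2
    }
  }
  out
}
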