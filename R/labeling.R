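#' Combine independent p-values with Fisher's method
#'
#' The statistic X = -2 * sum(log(p_i)) follows a chi-square distribution
#' with 2k degrees of freedom under the joint null; the combined p-value
#' is its upper-tail probability at X.
#'
#' @param p Numeric vector of p-values, all in (0, 1], non-empty.
#' @return The combined p-value.
#' @export
fisher_combine <- function(p) {
  if (length(p) == 0) stop("fisher_combine: empty p-value list", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("fisher_combine: p-values must lie in (0, 1]", call. = FALSE)
  stats::pchisq(-2 * sum(log(p)), df = 2 * length(p), lower.tail = FALSE)
}

# Row-wise Fisher combination of two p-value vectors.
fisher_combine2 <- function(p1, p2) {
  stats::pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
}

#' Derive two-class training labels from auxiliary-study p-values
#'
#' Implements the label rules for separating receptor-driven primary
#' responders from metabolite-driven side effects. For every target gene
#' whose ortholog appears in both metabolite-exposure (BPDE) studies, the
#' two BPDE p-values are combined by Fisher's method and BH-adjusted
#' across genes; the early-exposure study's p-values are BH-adjusted
#' across its genes separately. A gene is labeled `side_effect` when its
#' combined BPDE FDR is below `alpha` (the metabolite does not bind the
#' receptor, so perturbation marks downstream effects), and `primary`
#' when its early-course FDR is below `alpha` while its BPDE FDR is above
#' `alpha`. Genes without an ortholog in the map cannot satisfy either
#' rule (the primary rule requires observed BPDE non-significance) and
#' remain `unlabeled`.
#'
#' When the ortholog map sends several source genes to one target, the
#' smallest combined BPDE p-value is kept with a warning.
#'
#' @param bpde1,bpde2 data.frames (`gene_id`, `p`) keyed by source ids.
#' @param early data.frame (`gene_id`, `p`) keyed by target ids.
#' @param ortholog_map data.frame (`source_id`, `target_id`).
#' @param alpha FDR threshold for both rules (default 0.05).
#' @return data.frame: `gene_id`, `label` in {primary, side_effect,
#'   unlabeled}, `combined_bpde_p`, `combined_bpde_q`, `early_p`,
#'   `early_q` (NA where not applicable).
#' @export
derive_labels <- function(bpde1, bpde2, early, ortholog_map, alpha = 0.05) {
  shared <- intersect(bpde1$gene_id, bpde2$gene_id)
  shared <- shared[shared %in% ortholog_map$source_id]
  map <- ortholog_map[ortholog_map$source_id %in% shared, , drop = FALSE]
  comb <- data.frame(
    gene_id = map$target_id,
    combined_bpde_p = fisher_combine2(
      bpde1$p[match(map$source_id, bpde1$gene_id)],
      bpde2$p[match(map$source_id, bpde2$gene_id)]),
    stringsAsFactors = FALSE)
  if (anyDuplicated(comb$gene_id)) {
    warning("derive_labels: multiple orthologs map to the same target; ",
            "keeping the smallest combined p-value")
    comb <- comb[order(comb$combined_bpde_p), , drop = FALSE]
    comb <- comb[!duplicated(comb$gene_id), , drop = FALSE]
  }
  comb$combined_bpde_q <- p.adjust(comb$combined_bpde_p, "BH")

  early_q <- p.adjust(early$p, "BH")
  genes <- union(comb$gene_id, early$gene_id)
  i_b <- match(genes, comb$gene_id)
  i_e <- match(genes, early$gene_id)
  out <- data.frame(
    gene_id = genes,
    combined_bpde_p = comb$combined_bpde_p[i_b],
    combined_bpde_q = comb$combined_bpde_q[i_b],
    early_p = early$p[i_e],
    early_q = early_q[i_e],
    stringsAsFactors = FALSE)
  out$label <- "unlabeled"
  out$label[!is.na(out$combined_bpde_q) & out$combined_bpde_q < alpha] <-
    "side_effect"
  out$label[!is.na(out$combined_bpde_q) & out$combined_bpde_q > alpha &
              !is.na(out$early_q) & out$early_q < alpha] <- "primary"
  out[, c("gene_id", "label", "combined_bpde_p", "combined_bpde_q",
          "early_p", "early_q")]
}
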