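#' Kolmogorov-Smirnov enrichment of gene sets for small p-values
#'
#' For each set (e.g. cluster), compares the perturbation p-values of the
#' set's genes against those of all other genes in the universe with a
#' two-sample KS test, one-sided towards the set's p-values being
#' stochastically smaller (enrichment); the two-sided p-value is reported
#' alongside. Genes used to train the classifier are excluded before
#' anything is computed, so the result reflects genuine predictive
#' ability rather than label recall. Sets with fewer than two eligible
#' genes (or an empty background) are flagged untestable with p = 1.
#'
#' @param sets Named vector mapping gene id to set id.
#' @param perturb_p Named vector of combined perturbation p-values
#'   covering every gene in `sets`.
#' @param training_genes Gene ids to exclude.
#' @return data.frame per set: `set_id`, `n_in`, `n_out`, `ks_statistic`,
#'   `p_value` (one-sided), `p_two_sided`, `direction`, `testable`.
#' @export
ks_enrichment <- function(sets, perturb_p, training_genes = character()) {
  if (!all(names(sets) %in% names(perturb_p)))
    stop("ks_enrichment: perturbation p-values missing for some genes",
         call. = FALSE)
  eligible <- setdiff(names(sets), training_genes)
  res <- lapply(sort(unique(as.character(sets))), function(sid) {
    inside <- eligible[as.character(sets[eligible]) == sid]
    outside <- setdiff(eligible, inside)
    row <- data.frame(set_id = sid, n_in = length(inside),
                      n_out = length(outside), ks_statistic = NA_real_,
                      p_value = 1, p_two_sided = 1,
                      direction = NA_character_, testable = FALSE,
                      stringsAsFactors = FALSE)
    if (length(inside) < 2 || length(outside) < 2) return(row)
    x <- perturb_p[inside]; y <- perturb_p[outside]
    # alternative = "greater": ECDF of x above that of y, i.e. x smaller
    one <- suppressWarnings(stats::ks.test(x, y, alternative = "greater"))
    two <- suppressWarnings(stats::ks.test(x, y, alternative = "two.sided"))
    row$ks_statistic <- unname(one$statistic)
    row$p_value <- one$p.value
    row$p_two_sided <- two$p.value
    dminus <- suppressWarnings(
      stats::ks.test(x, y, alternative = "less")$statistic)
    row$direction <- if (unname(one$statistic) >= unname(dminus))
      "enriched" else "depleted"
    row$testable <- TRUE
    row
  })
  do.call(rbind, res)
}

#' Enrichment of unclassifiable genes for perturbation evidence
#'
#' Applies the KS enrichment procedure with the non-confident genes as
#' the set and the confidently classified genes as the background. A
#' significant result indicates that genes the classifier cannot place
#' (e.g. indirect downstream targets it was never trained on) still carry
#' receptor-perturbation signal.
#'
#' @param predictions Prediction table from [predict_all()].
#' @param perturb_p Named vector of combined perturbation p-values.
#' @param training_genes Gene ids to exclude.
#' @return One-row data.frame in the [ks_enrichment()] format
#'   (`set_id = "unclassified"`).
#' @export
unclassified_enrichment <- function(predictions, perturb_p,
                                    training_genes = character()) {
  sets <- stats::setNames(
    ifelse(predictions$confident, "confident", "unclassified"),
    predictions$gene_id)
  res <- ks_enrichment(sets, perturb_p, training_genes)
  row <- res[res$set_id == "unclassified", , drop = FALSE]
  if (nrow(row) == 0)
    row <- data.frame(set_id = "unclassified", n_in = 0L,
                      n_out = sum(sets == "confident"),
                      ks_statistic = NA_real_, p_value = 1, p_two_sided = 1,
                      direction = NA_character_, testable = FALSE,
                      stringsAsFactors = FALSE)
  rownames(row) <- NULL
  row
}
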