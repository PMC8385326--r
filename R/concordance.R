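#' Per-gene mean paired treatment change
#'
#' For every gene, the mean over patients of week-14 minus screening
#' log2-CPM, within one arm, using only complete same-segment pairs.
#'
#' @param log2cpm genes x samples log2-CPM matrix (named columns).
#' @param meta per-sample metadata.
#' @param arm `"treatment"` or `"placebo"`.
#' @param active_screening_only restrict to pairs with active screening
#'   segments.
#' @return Tibble `gene, log2fc` with the number of pairs as attribute
#'   `n_pairs`.
#' @export
treatment_change_per_gene <- function(log2cpm, meta, arm,
                                      active_screening_only = TRUE) {
  pairs <- paired_samples(meta, active_screening_only)
  pairs <- pairs[pairs$arm == arm, ]
  if (nrow(pairs) < 2) {
    stop_sigtrace(sprintf("fewer than 2 complete pairs in the %s arm.", arm))
  }
  delta <- log2cpm[, pairs$week14_id, drop = FALSE] -
    log2cpm[, pairs$screening_id, drop = FALSE]
  out <- tibble(gene = rownames(log2cpm), log2fc = unname(rowMeans(delta)))
  attr(out, "n_pairs") <- nrow(pairs)
  out
}

#' Correlate treatment-induced and activity-associated fold changes
#'
#' Pearson correlation between per-gene treatment log2 fold changes and
#' per-gene disease-activity log2 fold changes over a gene subset, with a
#' two-sided test.
#'
#' @param pairs tibble with columns `gene, fc_treatment, fc_activity`.
#' @param gene_subset optional character vector restricting the genes used
#'   (must leave at least 3).
#' @param method correlation flavour, `"pearson"` (default, matching
#'   linear fold-change axes) or `"spearman"`.
#' @return One-row tibble `r, p_value, n`.
#' @export
correlate_changes <- function(pairs, gene_subset = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(all(c("gene", "fc_treatment", "fc_activity") %in%
                  colnames(pairs)))
  if (!is.null(gene_subset)) {
    pairs <- pairs[pairs$gene %in% gene_subset, ]
  }
  pairs <- pairs[is.finite(pairs$fc_treatment) &
                   is.finite(pairs$fc_activity), ]
  if (nrow(pairs) < 3) stop_sigtrace("need at least 3 genes to correlate.")
  if (sd(pairs$fc_treatment) == 0 || sd(pairs$fc_activity) == 0) {
    stop_sigtrace("zero variance in one fold-change axis.")
  }
  ct <- suppressWarnings(cor.test(pairs$fc_treatment, pairs$fc_activity,
                                  method = method))
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = nrow(pairs))
}

#' Treatment-vs-activity concordance analysis
#'
#' Builds the per-gene fold-change pair — mean paired treatment change in
#' the chosen arm against the disease-activity coefficient from the
#' screening-only active-vs-inactive model — and correlates the two over
#' either the treatment-modulated gene set (default) or all filtered
#' genes.
#'
#' @param study a [bulk_study()].
#' @param arm `"treatment"` or `"placebo"`.
#' @param activity_fit optional precomputed `de_fit` from
#'   [de_active_vs_inactive()].
#' @param gene_subset `"modulated"` (restrict to
#'   [call_treatment_modulated()] output, supplied via `modulated_genes`)
#'   or `"all"`.
#' @param modulated_genes character vector of treatment-modulated genes
#'   (required when `gene_subset = "modulated"`).
#' @param active_screening_only see [paired_samples()].
#' @return A list of class `concordance_result` with `pairs` (per-gene
#'   tibble) and `summary` (`r, p_value, n, arm`).
#' @export
concordance_analysis <- function(study, arm = "treatment",
                                 activity_fit = NULL,
                                 gene_subset = c("modulated", "all"),
                                 modulated_genes = NULL,
                                 active_screening_only = TRUE) {
  gene_subset <- match.arg(gene_subset)
  activity_fit <- activity_fit %||% de_active_vs_inactive(study)
  lc <- log2cpm(study$counts)
  tc <- treatment_change_per_gene(lc, study$meta, arm,
                                  active_screening_only)
  at <- activity_fit$table
  pairs <- inner_join(
    dplyr::rename(tc, fc_treatment = "log2fc"),
    dplyr::rename(at[, c("gene", "log2fc")], fc_activity = "log2fc"),
    by = "gene"
  )
  subset_genes <- if (gene_subset == "modulated") {
    if (is.null(modulated_genes)) {
      stop_sigtrace("`modulated_genes` required when gene_subset = 'modulated'.")
    }
    modulated_genes
  } else NULL
  summ <- correlate_changes(pairs, subset_genes)
  summ$arm <- arm
  summ$gene_subset <- gene_subset
  structure(list(pairs = pairs, summary = summ),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result>\n")
  print(x$summary)
  invisible(x)
}
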