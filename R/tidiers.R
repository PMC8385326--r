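#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_hline geom_vline
#'   geom_boxplot geom_jitter geom_smooth labs theme_bw facet_wrap
#'   scale_color_manual position_jitterdodge
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a moderated differential-expression fit
#'
#' @param x a `de_fit`.
#' @param ... unused.
#' @return Per-gene tibble: `gene, log2fc, t, p_value, fdr, stratum`.
#' @export
tidy.de_fit <- function(x, ...) {
  mutate(x$table, stratum = x$stratum)
}

#' @rdname tidy.de_fit
#' @return `glance()`: one-row tibble with gene counts, hit counts and the
#'   shrinkage hyperparameters.
#' @export
glance.de_fit <- function(x, ...) {
  tibble(
    stratum = x$stratum, n_genes = nrow(x$table),
    n_signif_fdr05 = sum(x$table$fdr < 0.05),
    df_residual = x$df_residual, df_prior = x$df_prior,
    s2_prior = x$s2_prior
  )
}

#' Tidy a signature arm comparison
#'
#' @param x a `signature_comparison`.
#' @param ... unused.
#' @return The per-signature comparison tibble.
#' @export
tidy.signature_comparison <- function(x, ...) x$comparison

#' @rdname tidy.signature_comparison
#' @export
glance.signature_comparison <- function(x, ...) {
  tibble(
    n_signatures = nrow(x$comparison),
    n_signif_fdr05 = sum(x$comparison$fdr < 0.05),
    n_patients = length(unique(x$deltas$patient_id))
  )
}

#' Tidy a concordance result
#'
#' @param x a `concordance_result`.
#' @param ... unused.
#' @return The per-gene fold-change pair tibble.
#' @export
tidy.concordance_result <- function(x, ...) x$pairs

#' @rdname tidy.concordance_result
#' @export
glance.concordance_result <- function(x, ...) x$summary

#' Volcano plot of a differential-expression fit
#'
#' @param object a `de_fit`.
#' @param fc_cut,fdr_cut thresholds highlighted in red.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.de_fit <- function(object, fc_cut = 1.5, fdr_cut = 0.05, ...) {
  d <- mutate(object$table,
              hit = abs(.data$log2fc) >= log2(fc_cut) & .data$fdr < fdr_cut)
  ggplot(d, aes(x = .data$log2fc, y = -log10(.data$p_value),
                color = .data$hit)) +
    geom_point(size = 0.7, alpha = 0.7) +
    scale_color_manual(values = c(`FALSE` = "grey40", `TRUE` = "red"),
                       guide = "none") +
    geom_vline(xintercept = c(-log2(fc_cut), log2(fc_cut)),
               linetype = "dashed", linewidth = 0.3) +
    labs(x = "log2 fold change", y = "-log10 p",
         title = sprintf("stratum: %s", object$stratum)) +
    theme_bw()
}

#' Paired score changes by arm
#'
#' @param object a `signature_comparison`.
#' @param ... unused.
#' @return A ggplot of per-patient deltas by arm, faceted by signature.
#' @export
autoplot.signature_comparison <- function(object, ...) {
  ggplot(object$deltas, aes(x = .data$arm, y = .data$delta,
                            color = .data$location)) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_boxplot(outlier.shape = NA, color = "grey30") +
    geom_jitter(width = 0.15, size = 1) +
    facet_wrap(~signature) +
    labs(x = NULL, y = "week 14 - screening score") +
    theme_bw()
}

#' Concordance scatter of fold changes
#'
#' @param object a `concordance_result`.
#' @param ... unused.
#' @return A ggplot of treatment vs activity log2 fold changes per gene.
#' @export
autoplot.concordance_result <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$fc_activity, y = .data$fc_treatment)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_hline(yintercept = 0, linewidth = 0.3) +
    geom_vline(xintercept = 0, linewidth = 0.3) +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                linewidth = 0.5, color = "red") +
    labs(x = "activity log2FC (active vs inactive)",
         y = sprintf("%s-arm log2FC (week 14 - screening)",
                     object$summary$arm),
         subtitle = sprintf("r = %.2f, n = %d", object$summary$r,
                            object$summary$n)) +
    theme_bw()
}
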