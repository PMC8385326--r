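#' Counts per million and log2-CPM
#'
#' `cpm()` scales each column to counts per million of its library size.
#' `log2cpm()` uses the damped form `log2((count + 0.5) / (libsize + 1) *
#' 1e6)`, which keeps zeros finite and stabilizes low counts.
#'
#' @param counts genes x samples nonnegative matrix.
#' @param libsizes per-sample library sizes (default: column sums).
#' @return Matrix of the same shape.
#' @examples
#' cpm(matrix(10, 1, 1), libsizes = 1e6)
#' @export
cpm <- function(counts, libsizes = colSums(counts)) {
  if (any(libsizes <= 0)) {
    stop_sigtrace("library sizes must be positive.")
  }
  sweep(counts, 2, libsizes, "/") * 1e6
}

#' @rdname cpm
#' @export
log2cpm <- function(counts, libsizes = colSums(counts)) {
  if (any(libsizes <= 0)) {
    stop_sigtrace("library sizes must be positive.")
  }
  log2(sweep(counts + 0.5, 2, libsizes + 1, "/") * 1e6)
}

#' Expression-based gene inclusion filter
#'
#' Keeps genes detected above `min_reads` counts (strictly) in more than
#' `min_samples` samples (strictly). The defaults reproduce the
#' ">10 reads in >31 samples" rule; `min_samples` should be scaled to the
#' cohort at hand.
#'
#' @param counts genes x samples count matrix.
#' @param min_reads count threshold (strict).
#' @param min_samples sample-count threshold (strict).
#' @return Named integer vector of retained gene row indices.
#' @export
filter_genes <- function(counts, min_reads = 10, min_samples = 31) {
  keep <- rowSums(counts > min_reads) > min_samples
  which(keep)
}

# column names of design columns removed by the QR pivot, used in error
# messages about aliased covariates
aliased_columns <- function(design) {
  qrd <- qr(design)
  if (qrd$rank == ncol(design)) return(character())
  colnames(design)[qrd$pivot[-seq_len(qrd$rank)]]
}

#' Precision weights from the mean-variance trend
#'
#' Fits a gene-wise linear model to log2-CPM values, smooths the
#' square-root residual standard deviation against average log2 count with
#' lowess, and converts the per-observation predicted standard deviation
#' into an inverse-fourth-power precision weight. This is the standard
#' variance-modelling transformation for count-derived log expression.
#'
#' @param counts filtered genes x samples count matrix.
#' @param design samples x coefficients model matrix (full rank).
#' @param span lowess span for the trend.
#' @param lib_size optional library sizes (default column sums).
#' @return A list of class `voom_fit`: `E` (log2-CPM matrix), `weights`
#'   (same shape, all positive), `trend` (tibble of the lowess input), and
#'   the design.
#' @export
voom_weights <- function(counts, design, span = 0.5, lib_size = NULL) {
  counts <- as.matrix(counts)
  design <- as.matrix(design)
  if (nrow(design) != ncol(counts)) {
    stop_sigtrace("design rows must match count columns.")
  }
  bad <- aliased_columns(design)
  if (length(bad) > 0) {
    stop_sigtrace(sprintf("design is rank-deficient; aliased columns: %s.",
                          paste(bad, collapse = ", ")),
                  class = "sigtrace_design_error")
  }
  lib <- lib_size %||% colSums(counts)
  y <- log2(sweep(counts + 0.5, 2, lib + 1, "/") * 1e6)

  qrd <- qr(design)
  coefs <- t(qr.coef(qrd, t(y)))
  fitted <- coefs %*% t(design)
  res <- y - fitted
  df_res <- ncol(counts) - ncol(design)
  if (df_res <= 0) stop_sigtrace("no residual degrees of freedom.")
  sigma <- sqrt(rowSums(res^2) / df_res)

  if (nrow(y) < 2) {
    rlang::warn("fewer than 2 genes: mean-variance trend is undefined; returning unit weights.")
    w <- matrix(1, nrow(y), ncol(y), dimnames = dimnames(y))
    return(structure(list(E = y, weights = w,
                          trend = tibble(x = numeric(), y = numeric()),
                          design = design, lib_size = lib),
                     class = "voom_fit"))
  }

  sx <- rowMeans(y) + mean(log2(lib + 1)) - log2(1e6)
  sy <- sqrt(sigma)
  l <- lowess(sx, sy, f = span)
  trend_fun <- approxfun(l, rule = 2, ties = mean)
  fitted_cpm <- 2^fitted
  fitted_count <- 1e-6 * sweep(fitted_cpm, 2, lib + 1, "*")
  fitted_log <- log2(fitted_count)
  pred_sd <- trend_fun(fitted_log)
  pred_sd <- pmax(pred_sd, 1e-6)
  w <- matrix(pred_sd^-4, nrow(y), ncol(y), dimnames = dimnames(y))
  structure(list(E = y, weights = w, trend = tibble(x = l$x, y = l$y),
                 design = design, lib_size = lib),
            class = "voom_fit")
}

# Newton solve of trigamma(x) = y (monotone decreasing); used by the
# moment-matching variance-prior estimator
trigamma_inverse <- function(y) {
  x <- 0.5 + 1 / y
  for (i in 1:60) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (max(abs(dif / x)) < 1e-10) break
  }
  x
}

# Moment matching of log residual variances against a scaled-F model:
# returns the prior degrees of freedom and prior variance that shrinkage
# pulls gene-wise variances toward.
fit_variance_prior <- function(s2, df) {
  ok <- s2 > 0 & !is.na(s2)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  n <- length(e)
  evar <- sum((e - emean)^2) / (n - 1) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: complete pooling onto the
    # geometric mean of the observed variances (exact fixed point when all
    # gene variances coincide)
    return(list(df_prior = Inf, s2_prior = exp(mean(z))))
  }
  df_prior <- 2 * trigamma_inverse(evar)
  s2_prior <- exp(emean + digamma(df_prior / 2) - log(df_prior / 2))
  list(df_prior = df_prior, s2_prior = s2_prior)
}

#' Weighted linear modelling with empirical-Bayes variance moderation
#'
#' Fits a weighted least-squares model per gene, shrinks residual variances
#' toward a pooled prior estimated by moment matching on the log variances,
#' and reports moderated t-statistics on `residual df + prior df` degrees
#' of freedom with Benjamini-Hochberg adjusted p-values.
#'
#' @param vfit a `voom_fit` from [voom_weights()], or a list with `E`,
#'   `weights`, `design`.
#' @param coef name (or index) of the design coefficient to test, or a
#'   numeric contrast vector of length `ncol(design)`.
#' @param stratum label recorded in the result (e.g. `"combined"`,
#'   `"colon_only"`).
#' @param df_prior_override optional forced prior df (0 recovers the
#'   ordinary t-test; `Inf` pools completely).
#' @return An object of class `de_fit` with the per-gene table (gene,
#'   log2fc, t, p_value, fdr), the shrinkage hyperparameters, and the
#'   stratum label. Use [tidy()] / [glance()] to extract tibbles.
#' @export
fit_and_moderate <- function(vfit, coef = 2L, stratum = "combined",
                             df_prior_override = NULL) {
  E <- vfit$E
  W <- vfit$weights
  design <- vfit$design
  n <- ncol(E)
  p <- ncol(design)
  df_res <- n - p
  if (df_res <= 0) stop_sigtrace("residual degrees of freedom <= 0.")
  contrast <- if (is.numeric(coef) && length(coef) == ncol(design)) {
    coef
  } else {
    cc <- rep(0, p)
    idx <- if (is.character(coef)) match(coef, colnames(design)) else coef
    if (is.na(idx) || idx < 1 || idx > p) {
      stop_sigtrace("`coef` does not name a design column.")
    }
    cc[idx] <- 1
    cc
  }

  g <- nrow(E)
  beta <- numeric(g)
  stdev_unscaled <- numeric(g)
  s2 <- numeric(g)
  for (i in seq_len(g)) {
    wi <- W[i, ]
    sw <- sqrt(wi)
    X <- design * sw
    yv <- E[i, ] * sw
    qrd <- qr(X)
    b <- qr.coef(qrd, yv)
    resid <- yv - X %*% b
    s2[i] <- sum(resid^2) / df_res
    xtxinv <- chol2inv(qr.R(qrd))
    beta[i] <- sum(contrast * b)
    stdev_unscaled[i] <- sqrt(drop(t(contrast) %*% xtxinv %*% contrast))
  }

  prior <- fit_variance_prior(s2, df_res)
  if (!is.null(df_prior_override)) prior$df_prior <- df_prior_override
  if (is.finite(prior$df_prior)) {
    s2_post <- (prior$df_prior * prior$s2_prior + df_res * s2) /
      (prior$df_prior + df_res)
    df_total <- df_res + prior$df_prior
  } else {
    s2_post <- rep(prior$s2_prior, g)
    df_total <- Inf
  }
  tstat <- beta / (stdev_unscaled * sqrt(s2_post))
  pval <- 2 * pt(-abs(tstat), df = df_total)
  table <- tibble(
    gene = rownames(E), log2fc = beta, t = tstat, p_value = pval,
    fdr = adjust_bh(pval)
  )
  structure(
    list(table = table, stratum = stratum, df_residual = df_res,
         df_prior = prior$df_prior, s2_prior = prior$s2_prior,
         s2 = setNames(s2, rownames(E)), s2_post = setNames(s2_post,
                                                            rownames(E)),
         contrast = contrast, design = design),
    class = "de_fit"
  )
}

#' @export
print.de_fit <- function(x, ...) {
  cat(sprintf("<de_fit> stratum '%s': %d genes, df_residual = %d, df_prior = %.2f\n",
              x$stratum, nrow(x$table), x$df_residual, x$df_prior))
  cat(sprintf("  genes at FDR < 0.05: %d\n", sum(x$table$fdr < 0.05)))
  invisible(x)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1). Input outside [0, 1]
#' is an error.
#'
#' @param p numeric vector of p-values.
#' @return Adjusted p-values of the same length.
#' @examples
#' adjust_bh(c(0.01, 0.02, 0.03, 0.04))
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop_sigtrace("p-values must lie in [0, 1].")
  }
  p.adjust(p, method = "BH")
}

#' Three-clause treatment-modulated gene call
#'
#' A gene is called treatment-modulated when (1) its absolute fold change
#' in the combined two-location analysis is at least `fc_cut` (i.e.
#' `|log2FC| >= log2(fc_cut)`), (2) its combined-analysis FDR is below
#' `fdr_cut`, and (3) it is nominally significant (unadjusted p below
#' `nominal_cut`) in both the colon-only and ileum-only analyses.
#'
#' @param combined,colon,ileum `de_fit` objects (or their tidied tables)
#'   over an identical gene universe.
#' @param fc_cut linear-scale fold-change threshold (inclusive).
#' @param fdr_cut combined-analysis FDR threshold (strict).
#' @param nominal_cut per-location nominal p threshold (strict).
#' @return Sorted character vector of called genes.
#' @export
call_treatment_modulated <- function(combined, colon, ileum, fc_cut = 1.5,
                                     fdr_cut = 0.05, nominal_cut = 0.05) {
  tab <- function(x) if (inherits(x, "de_fit")) x$table else as_tibble(x)
  tc <- tab(combined); tl <- tab(colon); ti <- tab(ileum)
  if (!setequal(tc$gene, tl$gene) || !setequal(tc$gene, ti$gene)) {
    stop_sigtrace("gene universes differ across the three analyses.")
  }
  tl <- tl[match(tc$gene, tl$gene), ]
  ti <- ti[match(tc$gene, ti$gene), ]
  called <- abs(tc$log2fc) >= log2(fc_cut) &
    tc$fdr < fdr_cut &
    tl$p_value < nominal_cut &
    ti$p_value < nominal_cut
  sort(tc$gene[called])
}

# model matrix for the treatment analysis: arm, prior anti-TNF, location,
# visit, and the arm x visit interaction (the treatment-specific change)
treatment_design <- function(meta, include_location = TRUE) {
  arm <- as.integer(meta$arm == "treatment")
  visit <- as.integer(meta$visit == "week14")
  tnf <- as.integer(meta$anti_tnf == "yes")
  X <- cbind(
    intercept = 1, arm = arm, anti_tnf = tnf,
    visit = visit, arm_visit = arm * visit
  )
  if (include_location) {
    X <- cbind(X[, 1:3, drop = FALSE],
               location = as.integer(meta$location == "ileum"),
               X[, 4:5, drop = FALSE])
  }
  X
}

#' Samples entering the paired treatment-effect analysis
#'
#' A patient contributes both visits when a screening and a week-14 sample
#' from the same bowel segment exist; optionally (default) the screening
#' biopsy must come from an endoscopically active segment.
#'
#' @param meta metadata tibble (see [bulk_study()]).
#' @param active_screening_only require an active screening segment.
#' @return Tibble with one row per retained pair: `patient_id, location,
#'   arm, anti_tnf, screening_id, week14_id`; an `exclusions` attribute
#'   logs dropped patients with reason codes.
#' @export
paired_samples <- function(meta, active_screening_only = TRUE) {
  scr <- meta[meta$visit == "screening", ]
  w14 <- meta[meta$visit == "week14", ]
  pairs <- inner_join(
    scr[, c("sample_id", "patient_id", "location", "arm", "anti_tnf",
            "activity")],
    w14[, c("sample_id", "patient_id", "location")],
    by = c("patient_id", "location"), suffix = c("_scr", "_w14")
  )
  if (anyDuplicated(pairs[, c("patient_id", "location")])) {
    stop_sigtrace("duplicate visit pairs for a patient + location.")
  }
  excl <- list()
  unpaired <- setdiff(meta$patient_id, pairs$patient_id)
  if (length(unpaired) > 0) {
    excl[[1]] <- tibble(patient_id = unpaired, reason = "unpaired_visits")
  }
  if (active_screening_only) {
    dropped <- pairs$patient_id[pairs$activity != "active"]
    if (length(dropped) > 0) {
      excl[[2]] <- tibble(patient_id = dropped,
                          reason = "inactive_screening_segment")
    }
    pairs <- pairs[pairs$activity == "active", ]
  }
  out <- tibble(
    patient_id = pairs$patient_id, location = pairs$location,
    arm = pairs$arm, anti_tnf = pairs$anti_tnf,
    screening_id = pairs$sample_id_scr, week14_id = pairs$sample_id_w14
  )
  attr(out, "exclusions") <- bind_rows(excl)
  out
}

#' Treatment-effect differential expression for one stratum
#'
#' Runs the full bulk chain for the paired treatment analysis: restricts to
#' patients with both visits (and, by default, an active screening
#' segment), applies the gene inclusion filter, computes precision weights
#' and fits the covariate-adjusted model (arm, prior anti-TNF, location
#' where applicable, visit, arm x visit), testing the arm x visit
#' interaction — the treatment-specific expression change.
#'
#' @param study a [bulk_study()].
#' @param stratum `"combined"`, `"colon_only"` or `"ileum_only"`.
#' @param min_reads,min_samples gene filter thresholds; `min_samples =
#'   NULL` scales the cohort default (half the retained samples) — pass the
#'   cohort-specific value to reproduce a fixed rule.
#' @param active_screening_only restrict to pairs with active screening
#'   segments.
#' @param genes optional fixed gene universe (row names) to use instead of
#'   re-filtering, so strata share one universe.
#' @return A `de_fit`.
#' @export
de_treatment_effect <- function(study,
                                stratum = c("combined", "colon_only",
                                            "ileum_only"),
                                min_reads = 10, min_samples = NULL,
                                active_screening_only = TRUE,
                                genes = NULL) {
  stratum <- match.arg(stratum)
  pairs <- paired_samples(study$meta, active_screening_only)
  if (stratum == "colon_only") pairs <- pairs[pairs$location == "colon", ]
  if (stratum == "ileum_only") pairs <- pairs[pairs$location == "ileum", ]
  ids <- c(pairs$screening_id, pairs$week14_id)
  if (length(ids) < 8) {
    stop_sigtrace(sprintf("too few paired samples in stratum '%s'.", stratum))
  }
  counts <- study$counts[, ids, drop = FALSE]
  meta <- study$meta[match(ids, study$meta$sample_id), ]
  if (is.null(genes)) {
    ms <- min_samples %||% floor(ncol(counts) / 2)
    genes <- rownames(counts)[filter_genes(counts, min_reads, ms)]
  }
  counts <- counts[genes, , drop = FALSE]
  design <- treatment_design(meta, include_location = stratum == "combined")
  vfit <- voom_weights(counts, design)
  fit_and_moderate(vfit, coef = "arm_visit", stratum = stratum)
}

#' Disease-activity differential expression at screening
#'
#' Compares endoscopically active against inactive segments using only
#' screening-visit biopsies, with prior anti-TNF status and anatomic
#' location as covariates. Week-14 samples never enter, whatever their
#' content.
#'
#' @param study a [bulk_study()].
#' @param min_reads,min_samples gene filter thresholds (default: strictly
#'   more than `min_reads` counts in strictly more than half the screening
#'   samples).
#' @param genes optional fixed gene universe.
#' @return A `de_fit` with stratum `"active_vs_inactive"`; positive
#'   `log2fc` means higher in active segments.
#' @export
de_active_vs_inactive <- function(study, min_reads = 10, min_samples = NULL,
                                  genes = NULL) {
  meta <- study$meta[study$meta$visit == "screening", ]
  if (sum(meta$activity == "active") < 2 ||
      sum(meta$activity == "inactive") < 2) {
    stop_sigtrace("need at least 2 active and 2 inactive screening samples.")
  }
  counts <- study$counts[, meta$sample_id, drop = FALSE]
  if (is.null(genes)) {
    ms <- min_samples %||% floor(ncol(counts) / 2)
    genes <- rownames(counts)[filter_genes(counts, min_reads, ms)]
  }
  counts <- counts[genes, , drop = FALSE]
  design <- cbind(
    intercept = 1,
    activity = as.integer(meta$activity == "active"),
    location = as.integer(meta$location == "ileum"),
    anti_tnf = as.integer(meta$anti_tnf == "yes")
  )
  vfit <- voom_weights(counts, design)
  fit_and_moderate(vfit, coef = "activity", stratum = "active_vs_inactive")
}
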