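#' Eigengene score of a gene signature across samples
#'
#' Standardizes each signature gene across samples (z-score), takes the
#' first right singular vector of the resulting genes x samples matrix, and
#' orients its sign so the score correlates nonnegatively with the
#' per-sample mean of the z-scored genes. The score is reported on the z
#' scale (unit-variance scaling), so when every signature gene shares one
#' expression profile the score equals that profile z-scored.
#'
#' @param expr log-expression genes x samples matrix (any monotone log
#'   scale; the score is invariant to per-gene affine transforms).
#' @param genes character vector of signature genes; at least 2 must be
#'   present in `expr` and at least 50% must be found, otherwise an error
#'   lists the missing genes. Zero-variance genes are dropped with a
#'   warning.
#' @return Named numeric vector of per-sample scores.
#' @examples
#' expr <- matrix(rnorm(50), 5, 10,
#'                dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
#' eigengene_score(expr, c("g1", "g2", "g3"))
#' @export
eigengene_score <- function(expr, genes) {
  if (ncol(expr) < 3) stop_sigtrace("need at least 3 samples to score.")
  genes <- unique(genes)
  present <- intersect(genes, rownames(expr))
  missing <- setdiff(genes, present)
  if (length(present) < 2 || length(present) < 0.5 * length(genes)) {
    stop_sigtrace(sprintf(
      "too few signature genes found (%d of %d); missing: %s.",
      length(present), length(genes),
      paste(head(missing, 10), collapse = ", ")),
      class = "sigtrace_missing_genes")
  }
  if (length(missing) > 0) {
    rlang::warn(sprintf("%d signature genes absent from the matrix: %s.",
                        length(missing),
                        paste(head(missing, 10), collapse = ", ")))
  }
  sub <- expr[present, , drop = FALSE]
  sdv <- apply(sub, 1, sd)
  if (any(sdv == 0)) {
    rlang::warn(sprintf("dropping %d zero-variance signature gene(s).",
                        sum(sdv == 0)))
    sub <- sub[sdv > 0, , drop = FALSE]
    if (nrow(sub) < 2) stop_sigtrace("fewer than 2 variable signature genes.")
  }
  z <- t(scale(t(sub)))
  sv <- svd(z, nu = 0, nv = 1)
  v1 <- sv$v[, 1]
  ref <- colMeans(z)
  orient <- sum(v1 * ref)
  if (orient < 0) v1 <- -v1
  score <- v1 * sqrt(ncol(z) - 1)
  setNames(score, colnames(expr))
}

#' Per-patient paired score changes
#'
#' Computes week-14 minus screening score for every complete same-segment
#' pair; unpaired samples are excluded and logged in the `exclusions`
#' attribute.
#'
#' @param scores tibble with columns `sample_id, signature, score` (or a
#'   named numeric vector for a single signature).
#' @param meta per-sample metadata (see [bulk_study()]).
#' @param active_screening_only restrict to pairs whose screening segment
#'   was endoscopically active.
#' @return Tibble `patient_id, location, arm, signature, delta` with an
#'   `exclusions` attribute.
#' @export
paired_change <- function(scores, meta, active_screening_only = TRUE) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    scores <- tibble(sample_id = names(scores), signature = "signature",
                     score = unname(scores))
  }
  pairs <- paired_samples(meta, active_screening_only)
  sc <- scores
  out <- pairs |>
    left_join(sc, by = c("screening_id" = "sample_id")) |>
    dplyr::rename(score_screening = "score") |>
    left_join(sc, by = c("week14_id" = "sample_id",
                         "signature" = "signature")) |>
    dplyr::rename(score_week14 = "score") |>
    mutate(delta = .data$score_week14 - .data$score_screening) |>
    select(all_of(c("patient_id", "location", "arm", "signature", "delta")))
  if (any(is.na(out$delta))) {
    stop_sigtrace("scores missing for some paired samples.")
  }
  attr(out, "exclusions") <- attr(pairs, "exclusions")
  out
}

#' Between-arm comparison of paired score changes
#'
#' Two-sample t-test (Welch by default) of per-patient deltas, treatment
#' minus placebo.
#'
#' @param deltas numeric vector of paired changes.
#' @param arm parallel character vector, `"treatment"` / `"placebo"`.
#' @param method `"welch"` (unequal variances) or `"student"`.
#' @return One-row tibble: `mean_treatment, mean_placebo, diff, t,
#'   p_value, n_treatment, n_placebo`.
#' @export
compare_arms <- function(deltas, arm, method = c("welch", "student")) {
  method <- match.arg(method)
  tr <- deltas[arm == "treatment"]
  pl <- deltas[arm == "placebo"]
  if (length(tr) < 2 || length(pl) < 2) {
    stop_sigtrace("need at least 2 paired changes per arm.")
  }
  if (stats::sd(tr) == 0 && stats::sd(pl) == 0) {
    rlang::warn("zero variance in both arms; p reported as 1.")
    return(tibble(mean_treatment = mean(tr), mean_placebo = mean(pl),
                  diff = mean(tr) - mean(pl), t = 0, p_value = 1,
                  n_treatment = length(tr), n_placebo = length(pl)))
  }
  tt <- t.test(tr, pl, var.equal = method == "student")
  tibble(mean_treatment = mean(tr), mean_placebo = mean(pl),
         diff = mean(tr) - mean(pl), t = unname(tt$statistic),
         p_value = tt$p.value, n_treatment = length(tr),
         n_placebo = length(pl))
}

#' Score every signature and compare arms
#'
#' Scores each signature on log2-CPM expression of the bulk study, forms
#' paired week-14 minus screening changes per patient, and tests the
#' treatment-vs-placebo difference per signature, with Benjamini-Hochberg
#' adjustment across signatures.
#'
#' @param study a [bulk_study()].
#' @param signatures signature tibble (`signature`, `gene`) or named list
#'   of gene vectors.
#' @param expr optional log-expression matrix to score instead of the
#'   study's log2-CPM (e.g. externally normalized arrays).
#' @param active_screening_only see [paired_samples()].
#' @param method t-test flavour, see [compare_arms()].
#' @return Object of class `signature_comparison`: `scores` (sample-level),
#'   `deltas` (patient-level) and `comparison` (one row per signature with
#'   `delta_treatment, delta_placebo, diff, t, p_value, fdr`).
#' @export
score_all_signatures <- function(study, signatures, expr = NULL,
                                 active_screening_only = TRUE,
                                 method = "welch") {
  sets <- signature_sets(signatures)
  if (length(sets) == 0) stop_sigtrace("no signatures supplied.")
  expr <- expr %||% log2cpm(study$counts)
  score_rows <- lapply(names(sets), function(nm) {
    s <- eigengene_score(expr, sets[[nm]])
    tibble(sample_id = names(s), signature = nm, score = unname(s))
  })
  scores <- bind_rows(score_rows)
  deltas <- paired_change(scores, study$meta, active_screening_only)
  comparison <- deltas |>
    group_by(.data$signature) |>
    dplyr::group_modify(function(d, key) {
      compare_arms(d$delta, d$arm, method = method)
    }) |>
    ungroup() |>
    dplyr::rename(delta_treatment = "mean_treatment",
                  delta_placebo = "mean_placebo") |>
    mutate(fdr = adjust_bh(.data$p_value))
  structure(list(scores = scores, deltas = deltas, comparison = comparison,
                 exclusions = attr(deltas, "exclusions")),
            class = "signature_comparison")
}

#' @export
print.signature_comparison <- function(x, ...) {
  cat(sprintf("<signature_comparison> %d signatures, %d scored samples\n",
              nrow(x$comparison), length(unique(x$scores$sample_id))))
  print(x$comparison)
  invisible(x)
}
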