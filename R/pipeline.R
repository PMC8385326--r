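#' Pipeline configuration
#'
#' Collects every stage threshold and seed of the end-to-end analysis into
#' one object that serializes losslessly to JSON. The JSON form is the
#' source of truth for a run and is embedded in the run report.
#'
#' @param min_umi,max_mito_fraction barcode QC thresholds.
#' @param k_neighbors,resolution,n_pcs clustering parameters.
#' @param min_markers,min_fold cluster-merge rule.
#' @param sig_fdr,sig_max_genes signature construction.
#' @param filter_min_reads gene inclusion count threshold.
#' @param filter_min_samples gene inclusion sample threshold (`NULL`:
#'   half the samples in each analysis).
#' @param fc_cut,fdr_cut,nominal_cut treatment-modulated call thresholds.
#' @param active_screening_only paired-analysis inclusion rule.
#' @param t_test `"welch"` or `"student"`.
#' @param concordance_genes `"modulated"` or `"all"`.
#' @param seed global seed; per-stage seeds are fanned out from it.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(min_umi = 2000, max_mito_fraction = 0.08,
                            k_neighbors = 15, resolution = 0.3, n_pcs = 20,
                            min_markers = 30, min_fold = 1.5,
                            sig_fdr = 0.01, sig_max_genes = 50,
                            filter_min_reads = 10,
                            filter_min_samples = NULL,
                            fc_cut = 1.5, fdr_cut = 0.05,
                            nominal_cut = 0.05,
                            active_screening_only = TRUE,
                            t_test = "welch",
                            concordance_genes = "all",
                            seed = 1L) {
  cfg <- list(
    min_umi = min_umi, max_mito_fraction = max_mito_fraction,
    k_neighbors = k_neighbors, resolution = resolution, n_pcs = n_pcs,
    min_markers = min_markers, min_fold = min_fold,
    sig_fdr = sig_fdr, sig_max_genes = sig_max_genes,
    filter_min_reads = filter_min_reads,
    filter_min_samples = filter_min_samples,
    fc_cut = fc_cut, fdr_cut = fdr_cut, nominal_cut = nominal_cut,
    active_screening_only = active_screening_only,
    t_test = t_test, concordance_genes = concordance_genes,
    seed = check_count(seed, "seed", min = 0L)
  )
  for (nm in c("min_umi", "k_neighbors", "min_markers", "min_fold",
               "sig_max_genes", "fc_cut")) {
    check_positive(cfg[[nm]], nm)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read / write a pipeline configuration as JSON
#'
#' @param config a `pipeline_config`.
#' @param path JSON file path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Validate and normalize sample metadata
#'
#' Checks the required columns, normalizes categorical levels to lower
#' case, and — when a `ses_cd` segment-score column is present — recomputes
#' the activity label from the location-specific rule (colon active at
#' score >= 7, ileum at >= 4). A provided activity label contradicting the
#' derived one is an error listing the offending rows.
#'
#' @param meta raw metadata data frame.
#' @return Normalized tibble with a `pairing` attribute (the
#'   [paired_samples()] table without the activity restriction).
#' @export
validate_metadata <- function(meta) {
  meta <- as_tibble(meta)
  required <- c("sample_id", "patient_id", "arm", "visit", "location",
                "activity", "anti_tnf")
  missing <- setdiff(required, colnames(meta))
  if (length(missing) > 0) {
    stop_sigtrace(sprintf("metadata is missing required column(s): %s.",
                          paste(missing, collapse = ", ")),
                  class = "sigtrace_metadata_error")
  }
  for (col in c("arm", "visit", "location", "activity", "anti_tnf")) {
    meta[[col]] <- tolower(as.character(meta[[col]]))
  }
  levels_ok <- list(
    arm = c("placebo", "treatment"), visit = c("screening", "week14"),
    location = c("colon", "ileum"), activity = c("active", "inactive"),
    anti_tnf = c("yes", "no")
  )
  for (col in names(levels_ok)) {
    bad <- setdiff(unique(meta[[col]]), levels_ok[[col]])
    if (length(bad) > 0) {
      stop_sigtrace(sprintf("invalid %s level(s): %s.", col,
                            paste(bad, collapse = ", ")),
                    class = "sigtrace_metadata_error")
    }
  }
  if (anyDuplicated(meta$sample_id)) {
    stop_sigtrace("duplicate sample_id in metadata.",
                  class = "sigtrace_metadata_error")
  }
  if ("ses_cd" %in% colnames(meta)) {
    derived <- activity_from_score(meta$ses_cd, meta$location)
    clash <- which(!is.na(meta$ses_cd) & derived != meta$activity)
    if (length(clash) > 0) {
      stop_sigtrace(sprintf(
        "provided activity contradicts segment scores in row(s): %s.",
        paste(clash, collapse = ", ")),
        class = "sigtrace_metadata_error")
    }
    meta$activity <- ifelse(is.na(meta$ses_cd), meta$activity, derived)
  }
  attr(meta, "pairing") <- paired_samples(meta,
                                          active_screening_only = FALSE)
  meta
}

#' Run the full analysis chain on simulated data
#'
#' Drives every stage end to end: simulate the single-cell atlas and the
#' trial, QC and cluster the cells, merge under-determined clusters, learn
#' markers and signatures, fit the treatment model in the combined and
#' per-location strata, call treatment-modulated genes, score signatures
#' longitudinally, and correlate treatment changes with disease-activity
#' changes. Artifacts (GMT, TSV tables, JSON report) are written when
#' `out_dir` is given. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param sim a [sim_config()] describing the synthetic study (its `seed`
#'   is overridden by the pipeline seed fan-out for determinism of the
#'   whole run).
#' @param out_dir optional output directory.
#' @return A list of class `sigtrace_run` with elements `signatures`,
#'   `markers`, `cluster_labels`, `de` (list of `de_fit` per stratum),
#'   `modulated_genes`, `scores` (a `signature_comparison`), `concordance`
#'   (per arm), `report`.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         sim = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"), inherits(sim, "sim_config"))
  # deterministic per-stage seed fan-out from the global seed
  base_seed <- config$seed
  stage_seed <- function(k) (base_seed * 1000L + k) %% .Machine$integer.max
  sim_sc <- sim
  sim_sc$seed <- stage_seed(1L)
  sim_bulk <- sim
  sim_bulk$seed <- stage_seed(1L)   # shared so profiles match across modalities

  sc <- simulate_single_cell(sim_sc)
  trial <- simulate_trial(sim_bulk)
  study <- trial$study

  qc <- qc_filter_barcodes(sc$matrix, config$min_umi,
                           config$max_mito_fraction)
  norm <- normalize_cells(qc$matrix)
  labels <- cluster_cells(norm, k_neighbors = config$k_neighbors,
                          resolution = config$resolution,
                          seed = stage_seed(2L),
                          donor = qc$matrix$donor, n_pcs = config$n_pcs)
  labels <- merge_small_clusters(norm, labels, config$min_markers,
                                 config$min_fold)
  markers <- rank_sum_markers(norm, labels)
  # name each cluster's signature after the dominant true type when truth
  # is available, else by cluster id
  sig_names <- cluster_signature_names(labels, sc$truth$cell_labels)
  signatures <- build_all_signatures(markers, names = sig_names,
                                     max_genes = config$sig_max_genes,
                                     fdr_cut = config$sig_fdr)

  genes <- NULL
  de <- list(
    combined = de_treatment_effect(
      study, "combined", config$filter_min_reads, config$filter_min_samples,
      config$active_screening_only)
  )
  genes <- de$combined$table$gene
  de$colon_only <- de_treatment_effect(
    study, "colon_only", config$filter_min_reads, config$filter_min_samples,
    config$active_screening_only, genes = genes)
  de$ileum_only <- de_treatment_effect(
    study, "ileum_only", config$filter_min_reads, config$filter_min_samples,
    config$active_screening_only, genes = genes)
  de$active_vs_inactive <- de_active_vs_inactive(
    study, config$filter_min_reads, config$filter_min_samples,
    genes = genes)

  modulated <- call_treatment_modulated(de$combined, de$colon_only,
                                        de$ileum_only, config$fc_cut,
                                        config$fdr_cut, config$nominal_cut)
  scores <- score_all_signatures(study, signatures,
                                 active_screening_only =
                                   config$active_screening_only,
                                 method = config$t_test)
  conc_subset <- config$concordance_genes
  if (conc_subset == "modulated" && length(modulated) < 3) {
    # too few called genes to correlate; fall back to the all-genes variant
    conc_subset <- "all"
  }
  concordance <- lapply(c(treatment = "treatment", placebo = "placebo"),
                        function(a) {
    concordance_analysis(study, arm = a,
                         activity_fit = de$active_vs_inactive,
                         gene_subset = conc_subset,
                         modulated_genes = modulated,
                         active_screening_only =
                           config$active_screening_only)
  })

  report <- list(
    package_version = as.character(utils::packageVersion("sigtrace")),
    config = unclass(config),
    sim_config = unclass(sim),
    qc = as.list(qc$report),
    n_clusters = length(unique(labels)),
    n_signatures = length(unique(signatures$signature)),
    n_genes_tested = length(genes),
    n_modulated_genes = length(modulated),
    concordance = lapply(concordance, function(x) as.list(x$summary)),
    exclusions = as.data.frame(scores$exclusions %||%
                                 tibble(patient_id = character(),
                                        reason = character()))
  )

  run <- structure(
    list(signatures = signatures, markers = markers,
         cluster_labels = labels, de = de, modulated_genes = modulated,
         scores = scores, concordance = concordance, report = report,
         truth = list(single_cell = sc$truth, trial = trial$truth)),
    class = "sigtrace_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

# majority-vote naming of clusters by planted type (ties and unknowns fall
# back to cluster ids)
cluster_signature_names <- function(labels, true_labels = NULL) {
  if (is.null(true_labels)) return(NULL)
  ids <- sort(unique(labels))
  nms <- vapply(ids, function(cid) {
    tl <- true_labels[names(labels)[labels == cid]]
    tl <- tl[!is.na(tl)]
    if (length(tl) == 0) return(paste0("cluster", cid))
    names(sort(table(tl), decreasing = TRUE))[1]
  }, character(1))
  # disambiguate clusters mapping to the same type
  dup <- duplicated(nms) | duplicated(nms, fromLast = TRUE)
  nms[dup] <- paste0(nms[dup], "_c", ids[dup])
  setNames(nms, as.character(ids))
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gmt(run$signatures, file.path(out_dir, "signatures.gmt"))
  utils::write.table(run$markers, file.path(out_dir, "markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(run$de)) {
    utils::write.table(run$de[[nm]]$table,
                       file.path(out_dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(run$scores$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(run$scores$comparison,
                     file.path(out_dir, "arm_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(run$modulated_genes, file.path(out_dir, "modulated_genes.txt"))
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.sigtrace_run <- function(x, ...) {
  cat("<sigtrace_run>\n")
  cat(sprintf("  clusters after merging : %d\n", x$report$n_clusters))
  cat(sprintf("  signatures             : %d\n", x$report$n_signatures))
  cat(sprintf("  genes tested (bulk)    : %d\n", x$report$n_genes_tested))
  cat(sprintf("  treatment-modulated    : %d\n", x$report$n_modulated_genes))
  for (a in names(x$concordance)) {
    s <- x$concordance[[a]]$summary
    cat(sprintf("  concordance r (%s): %.3f (n = %d)\n", a, s$r, s$n))
  }
  invisible(x)
}
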