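#' Simulation configuration
#'
#' Bundles every knob of the synthetic single-cell and trial generators into
#' a validated configuration object. Defaults describe the study design the
#' package targets: a droplet single-cell atlas of gut T-cell subtypes and a
#' paired two-visit, two-location trial randomized 1:4 (placebo:treatment)
#' in which treatment depletes one cell type (by default a CD8 IEL-like
#' population) and resolves an inflammation program tied to endoscopic
#' activity.
#'
#' @param n_cell_types number of planted cell types.
#' @param n_genes size of the shared gene universe (single-cell and bulk).
#' @param n_markers_per_type planted marker genes per type (disjoint sets).
#' @param marker_fold_change multiplicative elevation of a marker's mean in
#'   its own type relative to all other types.
#' @param nb_dispersion negative-binomial dispersion shared by all genes
#'   (variance = mu + dispersion * mu^2).
#' @param cells_per_type viable cells simulated per type.
#' @param frac_low_quality_barcodes fraction of all barcodes that are low
#'   quality (half low-UMI, half high-mitochondrial).
#' @param mito_gene_count number of mitochondrial genes (flagged in output).
#' @param n_patients patients enrolled in the simulated trial.
#' @param randomization_ratio integer pair `c(placebo, treatment)`.
#' @param effect_size multiplicative factor in (0, 1] applied at the
#'   post-treatment visit, in the treatment arm only, to the target cell
#'   type's mixture proportion and to the latent disease severity; 1 means
#'   no treatment effect.
#' @param target_cell_type name of the depleted type (must be one of the
#'   generated type names `type1..typeK`, or the default `"CD8_IEL"` which
#'   aliases the first type).
#' @param n_activity_genes genes in the planted inflammation program.
#' @param activity_fold_change elevation of activity genes in biopsies from
#'   endoscopically active segments.
#' @param library_size_log_mean,library_size_log_sd log-normal parameters of
#'   bulk library sizes.
#' @param seed integer seed; fixed seed implies byte-identical output.
#' @return An object of class `sim_config` (a named list).
#' @examples
#' cfg <- sim_config(n_genes = 300, cells_per_type = 50, n_patients = 12)
#' @export
sim_config <- function(n_cell_types = 5L,
                       n_genes = 2000L,
                       n_markers_per_type = 40L,
                       marker_fold_change = 8,
                       nb_dispersion = 0.1,
                       cells_per_type = 300L,
                       frac_low_quality_barcodes = 0.1,
                       mito_gene_count = 50L,
                       n_patients = 100L,
                       randomization_ratio = c(1L, 4L),
                       effect_size = 0.5,
                       target_cell_type = "CD8_IEL",
                       n_activity_genes = 100L,
                       activity_fold_change = 4,
                       library_size_log_mean = log(2e6),
                       library_size_log_sd = 0.25,
                       seed = 1L) {
  n_cell_types <- check_count(n_cell_types, "n_cell_types", min = 1L)
  n_genes <- check_count(n_genes, "n_genes")
  n_markers_per_type <- check_count(n_markers_per_type, "n_markers_per_type")
  cells_per_type <- check_count(cells_per_type, "cells_per_type")
  mito_gene_count <- check_count(mito_gene_count, "mito_gene_count", min = 1L)
  n_patients <- check_count(n_patients, "n_patients", min = 2L)
  n_activity_genes <- check_count(n_activity_genes, "n_activity_genes", min = 0L)
  check_positive(marker_fold_change, "marker_fold_change")
  check_positive(nb_dispersion, "nb_dispersion")
  check_positive(activity_fold_change, "activity_fold_change")
  check_fraction(frac_low_quality_barcodes, "frac_low_quality_barcodes")
  if (!is.numeric(effect_size) || length(effect_size) != 1L ||
      effect_size <= 0 || effect_size > 1) {
    stop_sigtrace("`effect_size` must lie in (0, 1].")
  }
  if (length(randomization_ratio) != 2L || any(randomization_ratio < 1) ||
      any(randomization_ratio != as.integer(randomization_ratio))) {
    stop_sigtrace("`randomization_ratio` must be two positive integers.")
  }
  if (n_markers_per_type * n_cell_types > n_genes) {
    stop_sigtrace(
      "n_markers_per_type * n_cell_types exceeds n_genes; no room for markers.",
      class = "sigtrace_config_error"
    )
  }
  if (n_markers_per_type * n_cell_types + n_activity_genes + mito_gene_count >
      n_genes) {
    stop_sigtrace(
      "markers + activity genes + mitochondrial genes exceed n_genes.",
      class = "sigtrace_config_error"
    )
  }
  seed <- check_count(seed, "seed", min = 0L)
  structure(
    list(
      n_cell_types = n_cell_types, n_genes = n_genes,
      n_markers_per_type = n_markers_per_type,
      marker_fold_change = marker_fold_change,
      nb_dispersion = nb_dispersion, cells_per_type = cells_per_type,
      frac_low_quality_barcodes = frac_low_quality_barcodes,
      mito_gene_count = mito_gene_count, n_patients = n_patients,
      randomization_ratio = as.integer(randomization_ratio),
      effect_size = effect_size, target_cell_type = target_cell_type,
      n_activity_genes = n_activity_genes,
      activity_fold_change = activity_fold_change,
      library_size_log_mean = library_size_log_mean,
      library_size_log_sd = library_size_log_sd,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-26s %s\n", nm, paste(format(x[[nm]]), collapse = ":")))
  }
  invisible(x)
}

# Cell-type name table: the first type is the treatment target (CD8 IEL-like
# by default), the remainder are generic gut T-cell compartments.
sim_type_names <- function(config) {
  base <- c(config$target_cell_type, "CD8_LP", "CD4_effector", "CD4_Treg",
            "ILC3")
  if (config$n_cell_types <= length(base)) {
    base[seq_len(config$n_cell_types)]
  } else {
    c(base, paste0("type", seq_len(config$n_cell_types - length(base)) +
                     length(base)))
  }
}

# Shared deterministic construction of the gene universe and per-type
# expression profiles. Both generators call this with the same config, so the
# signatures learned from the single-cell data describe exactly the programs
# mixed into the bulk samples.
sim_profiles <- function(config) {
  set.seed(config$seed)
  k <- config$n_cell_types
  g <- config$n_genes
  m <- config$n_markers_per_type
  mito_idx <- seq_len(config$mito_gene_count)
  gene_ids <- sprintf("GENE%04d", seq_len(g))
  gene_ids[mito_idx] <- sprintf("MT-%03d", seq_along(mito_idx))
  mito <- seq_len(g) %in% mito_idx

  # markers and activity genes drawn from the non-mitochondrial pool
  pool <- setdiff(seq_len(g), mito_idx)
  marker_idx <- matrix(pool[seq_len(k * m)], nrow = m, ncol = k)
  act_pool <- setdiff(pool, as.vector(marker_idx))
  activity_idx <- act_pool[seq_len(config$n_activity_genes)]

  # baseline relative abundance, log-normal across genes
  base <- exp(rnorm(g, mean = 0, sd = 1))
  profiles <- matrix(rep(base, k), nrow = g, ncol = k)
  for (t in seq_len(k)) {
    profiles[marker_idx[, t], t] <- profiles[marker_idx[, t], t] *
      config$marker_fold_change
  }
  # fix the mitochondrial share of each profile at 2% so viable cells sit
  # well below the 8% QC cutoff
  for (t in seq_len(k)) {
    p <- profiles[, t]
    p[mito_idx] <- p[mito_idx] / sum(p[mito_idx]) * 0.02
    p[-mito_idx] <- p[-mito_idx] / sum(p[-mito_idx]) * 0.98
    profiles[, t] <- p
  }
  types <- sim_type_names(config)
  dimnames(profiles) <- list(gene_ids, types)
  list(
    gene_ids = gene_ids, mito = mito, profiles = profiles,
    true_markers = setNames(
      lapply(seq_len(k), function(t) gene_ids[marker_idx[, t]]), types),
    activity_genes = gene_ids[activity_idx],
    types = types
  )
}

# NB sampler around a genes x cells matrix of expected counts
sim_nb <- function(mu, dispersion) {
  counts <- matrix(
    rnbinom(length(mu), mu = as.vector(mu), size = 1 / dispersion),
    nrow = nrow(mu), dimnames = dimnames(mu)
  )
  counts
}

#' Simulate a droplet single-cell UMI count matrix with ground truth
#'
#' Generates negative-binomial UMI counts for `n_cell_types` planted cell
#' types with disjoint marker-gene sets, plus a configured fraction of
#' low-quality barcodes. Low-quality barcodes come in two flavours so each
#' quality-control clause is exercised independently: half have small
#' libraries (expected total well under 2000 UMIs), half have a
#' mitochondrial load around 20% of UMIs. Viable cells have libraries around
#' 8000 UMIs and ~2% mitochondrial content. Cells are spread across four
#' donors with a mild per-donor log-normal gene offset.
#'
#' @param config a [sim_config()].
#' @return A list with elements `matrix` (a `cell_matrix`) and `truth`
#'   (a list with `cell_labels`, `true_markers`, `low_quality` flags).
#' @examples
#' sim <- simulate_single_cell(sim_config(n_genes = 300, cells_per_type = 40))
#' dim(sim$matrix$counts)
#' @export
simulate_single_cell <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prof <- sim_profiles(config)
  set.seed(config$seed)
  k <- config$n_cell_types
  n_good <- k * config$cells_per_type
  frac <- config$frac_low_quality_barcodes
  n_low <- if (frac > 0) round(frac / (1 - frac) * n_good) else 0L
  n_cells <- n_good + n_low

  type_of <- c(rep(seq_len(k), each = config$cells_per_type),
               sample(seq_len(k), n_low, replace = TRUE))
  quality <- c(rep("viable", n_good),
               rep(c("low_umi", "high_mito"), length.out = n_low))
  ord <- sample(n_cells)                      # shuffle barcode order
  type_of <- type_of[ord]
  quality <- quality[ord]

  lib <- exp(rnorm(n_cells, log(8000), 0.25))
  lib[quality == "low_umi"] <- exp(rnorm(sum(quality == "low_umi"),
                                         log(700), 0.35))
  donor <- paste0("donor", sample(1:4, n_cells, replace = TRUE))
  donor_offset <- matrix(exp(rnorm(config$n_genes * 4, 0, 0.05)),
                         ncol = 4, dimnames = list(prof$gene_ids,
                                                   paste0("donor", 1:4)))

  mu <- prof$profiles[, type_of, drop = FALSE] * donor_offset[, donor]
  # inflate mitochondrial share to ~20% for the high-mito subpopulation
  hm <- quality == "high_mito"
  if (any(hm)) {
    mu[prof$mito, hm] <- mu[prof$mito, hm] * (0.20 / 0.02)
  }
  mu <- sweep(mu, 2, colSums(mu), "/")
  mu <- sweep(mu, 2, lib, "*")
  counts <- sim_nb(mu, config$nb_dispersion)
  barcodes <- sprintf("BC%05d", seq_len(n_cells))
  colnames(counts) <- barcodes

  cm <- cell_matrix(
    counts = counts,
    gene_ids = prof$gene_ids, barcode_ids = barcodes,
    mito = prof$mito, donor = setNames(donor, barcodes)
  )
  truth <- list(
    cell_labels = setNames(prof$types[type_of], barcodes),
    true_markers = prof$true_markers,
    low_quality = setNames(quality != "viable", barcodes),
    quality_class = setNames(quality, barcodes),
    donor_offsets = donor_offset
  )
  list(matrix = cm, truth = truth)
}

# exact arm split honoring the randomization ratio
arm_assignment <- function(n_patients, ratio) {
  n_placebo <- round(n_patients * ratio[1] / sum(ratio))
  if (n_placebo < 2 || n_patients - n_placebo < 2) {
    stop_sigtrace("fewer than 2 patients per arm under this ratio.",
                  class = "sigtrace_config_error")
  }
  rep(c("placebo", "treatment"), c(n_placebo, n_patients - n_placebo))
}

# SES-CD-style segment score from a latent severity in [0, 1]; colonic
# segments are scored on 0-12 (active at >= 7), ileal on 0-8 (active at >= 4)
severity_to_score <- function(u, location) {
  ifelse(location == "colon", round(3 + 9 * u), round(1 + 7 * u))
}

#' Classify endoscopic activity from segment scores
#'
#' Applies the location-specific activity rule: a colonic biopsy is active
#' when its colonic segment score is >= 7, an ileal biopsy when its ileal
#' segment score is >= 4.
#'
#' @param score numeric segment score(s).
#' @param location `"colon"` or `"ileum"`, recycled against `score`.
#' @return Character vector, `"active"` or `"inactive"`.
#' @examples
#' activity_from_score(c(7, 6), c("colon", "colon"))
#' activity_from_score(c(4, 3), c("ileum", "ileum"))
#' @export
activity_from_score <- function(score, location) {
  if (!all(location %in% c("colon", "ileum"))) {
    stop_sigtrace("location must be 'colon' or 'ileum'.")
  }
  ifelse(location == "colon", score >= 7, score >= 4) |>
    ifelse("active", "inactive")
}

#' Simulate a paired two-visit randomized trial of bulk RNA-seq biopsies
#'
#' Each patient contributes one screening and one week-14 biopsy from the
#' same bowel segment (colon or ileum). Arms are assigned exactly at the
#' configured placebo:treatment ratio. Expected bulk counts are
#' library-size-scaled mixtures of the same per-type expression programs the
#' single-cell generator plants, weighted by patient-level Dirichlet
#' proportions; at week 14 in the treatment arm only, the target cell type's
#' proportion is multiplied by `effect_size` (then renormalized). A latent
#' per-patient disease severity is thresholded through the segment-score
#' rule (colon >= 7, ileum >= 4) to produce activity labels; activity genes
#' are elevated `activity_fold_change`-fold in active biopsies. Treatment
#' also scales the latent severity by `effect_size` at week 14, so the
#' inflammation program resolves specifically under treatment; with
#' `effect_size = 1` the trial is exactly null.
#'
#' @param config a [sim_config()].
#' @return A list with `study` (a [bulk_study()]) and `truth` (sample
#'   proportions, activity genes, true markers, per-patient true proportion
#'   shift of the target type).
#' @examples
#' trial <- simulate_trial(sim_config(n_genes = 300, n_patients = 12))
#' table(trial$study$meta$arm, trial$study$meta$visit)
#' @export
simulate_trial <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  prof <- sim_profiles(config)
  set.seed(config$seed)
  k <- config$n_cell_types
  n <- config$n_patients
  arm <- sample(arm_assignment(n, config$randomization_ratio))
  patient <- sprintf("PT%03d", seq_len(n))
  location <- sample(c("colon", "ileum"), n, replace = TRUE)
  anti_tnf <- sample(c("yes", "no"), n, replace = TRUE)

  # patient-level mixture over cell types; same base proportions reused at
  # week 14 so the only systematic longitudinal change is the planted effect.
  # concentration 10 gives between-patient proportion CV ~ 0.3
  alpha <- rep(10, k)
  props0 <- t(sapply(seq_len(n), function(i) {
    x <- rgamma(k, shape = alpha)
    x / sum(x)
  }))
  colnames(props0) <- prof$types
  target <- config$target_cell_type
  if (!target %in% prof$types) {
    stop_sigtrace("target_cell_type is not one of the simulated types.",
                  class = "sigtrace_config_error")
  }
  props14 <- props0
  treat <- arm == "treatment"
  if (config$effect_size < 1) {
    props14[treat, target] <- props14[treat, target] * config$effect_size
    props14 <- props14 / rowSums(props14)
  }

  # latent severity: screening value per patient; treatment scales it at wk14
  u0 <- runif(n, 0.1, 1)
  u14 <- ifelse(treat, u0 * config$effect_size, u0)

  loc2 <- rep(location, 2)
  meta <- tibble(
    sample_id = c(paste0(patient, "_scr"), paste0(patient, "_w14")),
    patient_id = rep(patient, 2),
    arm = rep(arm, 2),
    visit = rep(c("screening", "week14"), each = n),
    location = loc2,
    ses_cd = severity_to_score(c(u0, u14), loc2),
    anti_tnf = rep(anti_tnf, 2)
  )
  meta$activity <- activity_from_score(meta$ses_cd, meta$location)
  meta <- meta[, c("sample_id", "patient_id", "arm", "visit", "location",
                   "activity", "anti_tnf", "ses_cd")]

  props_all <- rbind(props0, props14)
  rownames(props_all) <- meta$sample_id
  mix <- prof$profiles %*% t(props_all)           # genes x samples
  act <- meta$activity == "active"
  if (length(prof$activity_genes) > 0 && any(act)) {
    mix[prof$activity_genes, act] <- mix[prof$activity_genes, act] *
      config$activity_fold_change
  }
  mix <- sweep(mix, 2, colSums(mix), "/")
  lib <- exp(rnorm(2 * n, config$library_size_log_mean,
                   config$library_size_log_sd))
  mu <- sweep(mix, 2, lib, "*")
  counts <- sim_nb(mu, config$nb_dispersion)
  colnames(counts) <- meta$sample_id

  study <- bulk_study(counts = counts, meta = meta)
  truth <- list(
    sample_proportions = props_all,
    true_markers = prof$true_markers,
    activity_genes = prof$activity_genes,
    target_cell_type = target,
    treated_delta = setNames(props14[, target] - props0[, target], patient),
    severity = list(screening = setNames(u0, patient),
                    week14 = setNames(u14, patient))
  )
  list(study = study, truth = truth)
}
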