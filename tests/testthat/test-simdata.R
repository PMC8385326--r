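test_that("generators are deterministic for a fixed seed", {
  cfg <- tiny_sim(seed = 42)
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(a$matrix$counts, b$matrix$counts)
  expect_identical(a$truth$cell_labels, b$truth$cell_labels)
  ta <- simulate_trial(cfg)
  tb <- simulate_trial(cfg)
  expect_identical(ta$study$counts, tb$study$counts)
  expect_identical(ta$study$meta, tb$study$meta)
  # a different seed changes the data
  c <- simulate_single_cell(tiny_sim(seed = 43))
  expect_false(identical(a$matrix$counts, c$matrix$counts))
})

test_that("configuration errors are raised for impossible settings", {
  expect_error(sim_config(n_cell_types = 10, n_genes = 100,
                          n_markers_per_type = 20),
               class = "sigtrace_config_error")
  expect_error(sim_config(effect_size = 0))
  expect_error(sim_config(effect_size = 1.2))
  expect_error(simulate_trial(tiny_sim(n_patients = 4)),
               class = "sigtrace_config_error")
})

test_that("QC removes approximately the planted low-quality fraction", {
  # 10% low-quality at 5000 barcodes: the filter should remove ~500
  cfg <- sim_config(n_genes = 600, cells_per_type = 900,
                    frac_low_quality_barcodes = 0.10,
                    mito_gene_count = 20, n_activity_genes = 50, seed = 7)
  sim <- simulate_single_cell(cfg)
  n_total <- ncol(sim$matrix$counts)
  expect_equal(n_total, 5000)
  n_planted <- sum(sim$truth$low_quality)
  qc <- qc_filter_barcodes(sim$matrix)
  removed <- qc$report$removed_total
  # planted count is exact by construction; sampling noise can move a few
  # barcodes across the thresholds (binomial-scale error)
  expect_lt(abs(removed - n_planted), 3 * sqrt(n_total * 0.1 * 0.9))
  # the removed barcodes are overwhelmingly the planted ones
  kept <- qc$matrix$barcode_ids
  expect_gt(mean(!sim$truth$low_quality[kept]), 0.99)
})

test_that("null marker fold collapses clusters under the merge rule", {
  cfg <- tiny_sim(marker_fold_change = 1.0, seed = 11)
  sim <- simulate_single_cell(cfg)
  qc <- qc_filter_barcodes(sim$matrix)
  norm <- normalize_cells(qc$matrix)
  labels <- cluster_cells(norm, seed = 11, donor = qc$matrix$donor)
  merged <- merge_small_clusters(norm, labels)
  # with no expression difference between planted types, no cluster can
  # present >= 30 genes at >= 1.5-fold and everything merges
  expect_equal(length(unique(merged)), 1L)
})

test_that("trial honors the randomization ratio and pairing structure", {
  cfg <- sim_config(n_genes = 600, n_patients = 100, mito_gene_count = 20,
                    n_activity_genes = 50, seed = 3)
  trial <- simulate_trial(cfg)
  meta <- trial$study$meta
  arms <- table(meta$arm[meta$visit == "screening"])
  expect_equal(unname(arms[["placebo"]]), 20)
  expect_equal(unname(arms[["treatment"]]), 80)
  # every patient has exactly one sample per visit, same location
  by_pt <- split(meta, meta$patient_id)
  expect_true(all(vapply(by_pt, function(d) {
    nrow(d) == 2 && length(unique(d$location)) == 1 &&
      setequal(d$visit, c("screening", "week14"))
  }, logical(1))))
  # ground-truth proportions lie on the simplex
  expect_true(all(abs(rowSums(trial$truth$sample_proportions) - 1) < 1e-9))
})

test_that("effect_size = 1 leaves ground-truth proportions unchanged", {
  trial <- simulate_trial(tiny_sim(effect_size = 1.0, seed = 5))
  pr <- trial$truth$sample_proportions
  scr <- pr[grepl("_scr$", rownames(pr)), ]
  w14 <- pr[grepl("_w14$", rownames(pr)), ]
  expect_equal(unname(scr), unname(w14))
  expect_true(all(trial$truth$treated_delta == 0))
})

test_that("activity labels follow the segment-score rule", {
  expect_equal(activity_from_score(7, "colon"), "active")
  expect_equal(activity_from_score(6, "colon"), "inactive")
  expect_equal(activity_from_score(4, "ileum"), "active")
  expect_equal(activity_from_score(3, "ileum"), "inactive")
  trial <- simulate_trial(tiny_sim(seed = 9))
  m <- trial$study$meta
  expect_identical(m$activity, activity_from_score(m$ses_cd, m$location))
})

test_that("mixture consistency: marker means track true proportions", {
  cfg <- tiny_sim(seed = 13)
  trial <- simulate_trial(cfg)
  lc <- log2cpm(trial$study$counts)
  pr <- trial$truth$sample_proportions[colnames(lc), ]
  for (ty in colnames(pr)) {
    mk <- intersect(trial$truth$true_markers[[ty]], rownames(lc))
    r <- cor(colMeans(lc[mk, ]), pr[, ty])
    expect_gt(r, 0.5)
  }
})

test_that("single-cell fixtures round-trip losslessly", {
  sim <- simulate_single_cell(tiny_sim(cells_per_type = 30, seed = 2))
  dir <- withr::local_tempdir()
  write_fixture(sim$matrix, dir)
  back <- read_sc_fixture(dir)
  expect_equal(as.matrix(back$counts), as.matrix(sim$matrix$counts))
  expect_identical(back$gene_ids, sim$matrix$gene_ids)
  expect_identical(back$mito, sim$matrix$mito)
  expect_identical(unname(back$donor), unname(sim$matrix$donor))
})

test_that("an empty matrix writes a valid MTX with zero entries", {
  m <- Matrix::Matrix(0, 3, 2, sparse = TRUE)
  dimnames(m) <- list(paste0("g", 1:3), paste0("b", 1:2))
  cm <- cell_matrix(m)
  dir <- withr::local_tempdir()
  write_fixture(cm, dir)
  back <- read_sc_fixture(dir)
  expect_equal(sum(back$counts), 0)
  expect_equal(dim(back$counts), c(3L, 2L))
})

test_that("bulk fixtures round-trip and carry the exact metadata schema", {
  trial <- simulate_trial(tiny_sim(seed = 4))
  dir <- withr::local_tempdir()
  write_fixture(trial$study, dir)
  header <- strsplit(readLines(file.path(dir, "metadata.tsv"), n = 1),
                     "\t")[[1]]
  expect_identical(header, c("sample_id", "patient_id", "arm", "visit",
                             "location", "activity", "anti_tnf"))
  back <- read_bulk_fixture(dir)
  expect_equal(back$counts, trial$study$counts)
  expect_identical(back$meta$sample_id, trial$study$meta$sample_id)
  expect_identical(back$meta$activity, trial$study$meta$activity)
})

test_that("per-gene simulated means agree with configured expectations", {
  # one homogeneous population: empirical mean within 3 SE of mu
  cfg <- sim_config(n_cell_types = 1, n_genes = 300, cells_per_type = 1200,
                    n_markers_per_type = 1, frac_low_quality_barcodes = 0,
                    mito_gene_count = 10, n_activity_genes = 0, seed = 21)
  sim <- simulate_single_cell(cfg)
  counts <- as.matrix(sim$matrix$counts)
  # expected counts vary per cell through library size; compare to the
  # empirical per-gene mean of the generator's own expectation
  # compare per-cell expression proportions against the generator's exact
  # expectation (profile x donor offset, renormalized); proportions remove
  # shared library-size noise from the comparison
  props <- sweep(counts, 2, colSums(counts), "/")
  p_hat <- rowMeans(props)
  se <- apply(props, 1, sd) / sqrt(ncol(props))
  prof <- sigtrace:::sim_profiles(cfg)$profiles[, 1]
  off <- sim$truth$donor_offsets[, sim$matrix$donor, drop = FALSE]
  p_cell <- sweep(prof * off, 2, colSums(prof * off), "/")
  p_theory <- rowMeans(p_cell)
  frac_within <- mean(abs(p_hat - p_theory) <= 3 * pmax(se, 1e-8))
  expect_gt(frac_within, 0.95)
})
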