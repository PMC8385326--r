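test_that("a rank-1 signature block scores as the shared profile, z-scored", {
  set.seed(21)
  profile <- rnorm(12)
  expr <- t(sapply(1:6, function(i) 2 * profile + i))  # affine copies
  dimnames(expr) <- list(paste0("g", 1:6), paste0("s", 1:12))
  s <- eigengene_score(expr, paste0("g", 1:6))
  z <- as.numeric(scale(profile))
  expect_equal(unname(s), z, tolerance = 1e-10)
})

test_that("scores are invariant to per-gene affine maps and gene order", {
  set.seed(22)
  expr <- matrix(rnorm(20 * 15), 20, 15,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:15)))
  genes <- paste0("g", 1:8)
  s0 <- eigengene_score(expr, genes)
  shifted <- expr
  shifted[genes, ] <- expr[genes, ] * 3.7 + 11
  expect_equal(eigengene_score(shifted, genes), s0, tolerance = 1e-10)
  expect_equal(eigengene_score(expr, rev(genes)), s0, tolerance = 1e-10)
})

test_that("missing and degenerate signature genes are handled as stated", {
  set.seed(23)
  expr <- matrix(rnorm(50), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  expect_error(eigengene_score(expr, c("g1", "nope1", "nope2", "nope3")),
               regexp = "nope", class = "sigtrace_missing_genes")
  expect_warning(s <- eigengene_score(expr, c("g1", "g2", "g3", "nope1")),
                 regexp = "absent")
  expect_length(s, 10)
  expr["g1", ] <- 5
  expect_warning(eigengene_score(expr, c("g1", "g2", "g3")),
                 regexp = "zero-variance")
  expect_error(eigengene_score(expr[, 1:2], c("g1", "g2")))
})

test_that("score tracks the true mixing proportion of the target type", {
  trial <- simulate_trial(sim_config(seed = 25))
  lc <- log2cpm(trial$study$counts)
  mks <- trial$truth$true_markers[["CD8_IEL"]]
  s <- eigengene_score(lc, mks)
  pr <- trial$truth$sample_proportions[names(s), "CD8_IEL"]
  expect_gte(cor(s, pr), 0.9)
})

test_that("paired changes follow the week14 - screening definition", {
  meta <- make_meta(3, arm = "treatment")
  scores <- tibble::tibble(
    sample_id = meta$sample_id,
    signature = "sig",
    score = c(1, 2, 5, 2, 2, 4)   # screening then week14, patients P01-P03
  )
  pc <- paired_change(scores, meta)
  expect_equal(pc$delta[pc$patient_id == "P01"], 1)
  expect_equal(pc$delta[pc$patient_id == "P02"], 0)
  expect_equal(pc$delta[pc$patient_id == "P03"], -1)
})

test_that("incomplete pairs are excluded and logged; duplicates error", {
  meta <- make_meta(3, arm = "treatment")
  meta <- meta[meta$sample_id != "P02_w14", ]   # P02 missing week 14
  scores <- tibble::tibble(sample_id = meta$sample_id, signature = "sig",
                           score = seq_len(nrow(meta)))
  pc <- paired_change(scores, meta)
  expect_false("P02" %in% pc$patient_id)
  excl <- attr(pc, "exclusions")
  expect_true("P02" %in% excl$patient_id)
  expect_true("unpaired_visits" %in%
                excl$reason[excl$patient_id == "P02"])
  dup <- make_meta(2, arm = "treatment")
  dup <- rbind(dup, dup[4, ])
  dup$sample_id[5] <- "P02_w14b"
  expect_error(paired_samples(dup), regexp = "duplicate")
})

test_that("inactive screening segments are excluded under the default rule", {
  meta <- make_meta(4, arm = "treatment",
                    activity_scr = c("active", "inactive", "active",
                                     "inactive"))
  pairs <- paired_samples(meta, active_screening_only = TRUE)
  expect_setequal(pairs$patient_id, c("P01", "P03"))
  all_pairs <- paired_samples(meta, active_screening_only = FALSE)
  expect_equal(nrow(all_pairs), 4)
})

test_that("arm comparison reproduces the Welch oracle", {
  tr <- c(-1.1, -0.9, -1.0, -1.2)
  pl <- c(0.1, -0.1, 0.0, 0.05)
  res <- compare_arms(c(tr, pl), rep(c("treatment", "placebo"), each = 4))
  ref <- stats::t.test(tr, pl)
  expect_equal(res$diff, mean(tr) - mean(pl))
  expect_equal(res$diff, -1.0625)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  expect_lt(res$p_value, 0.01)
  # student variant matches the pooled-variance test
  ref2 <- stats::t.test(tr, pl, var.equal = TRUE)
  res2 <- compare_arms(c(tr, pl), rep(c("treatment", "placebo"), each = 4),
                       method = "student")
  expect_equal(res2$p_value, ref2$p.value, tolerance = 1e-12)
})

test_that("degenerate and undersized arm comparisons are handled", {
  expect_error(compare_arms(c(1, 2, 3), c("treatment", "treatment",
                                          "placebo")))
  expect_warning(res <- compare_arms(rep(0.5, 6),
                                     rep(c("treatment", "placebo"), 3)),
                 regexp = "zero variance")
  expect_equal(res$diff, 0)
  expect_equal(res$p_value, 1)
})

test_that("the depleted type has the most negative treatment-arm delta", {
  trial <- simulate_trial(sim_config(seed = 27))
  sa <- score_all_signatures(trial$study, trial$truth$true_markers)
  cmp <- tidy(sa)
  target <- cmp[cmp$signature == "CD8_IEL", ]
  expect_equal(which.min(cmp$delta_treatment),
               which(cmp$signature == "CD8_IEL"))
  expect_lt(target$delta_treatment, 0)
  expect_lt(target$p_value, 0.05)
  # single-signature input: FDR equals p
  one <- score_all_signatures(trial$study,
                              trial$truth$true_markers["CD8_IEL"])
  expect_equal(one$comparison$fdr, one$comparison$p_value)
})

test_that("treatment-arm score deltas are monotone in effect size", {
  deltas <- vapply(c(1.0, 0.75, 0.5, 0.25), function(e) {
    trial <- simulate_trial(sim_config(seed = 29, effect_size = e))
    sa <- score_all_signatures(trial$study,
                               trial$truth$true_markers["CD8_IEL"])
    sa$comparison$delta_treatment
  }, numeric(1))
  expect_true(all(diff(deltas) < 0))
})
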