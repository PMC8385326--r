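test_that("CPM and log2-CPM follow their definitions", {
  counts <- matrix(c(10, 0, 90, 100), 2, 2,
                   dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_equal(cpm(matrix(10), libsizes = 1e6)[1, 1], 10)
  expect_equal(cpm(counts)[2, 1], 0)
  # doubling counts and libraries leaves CPM unchanged
  expect_equal(cpm(counts), cpm(2 * counts, libsizes = 2 * colSums(counts)))
  expect_equal(log2cpm(counts, libsizes = c(100, 190))[1, 1],
               log2((10 + 0.5) / 101 * 1e6))
  expect_error(cpm(counts, libsizes = c(0, 1)))
})

test_that("gene filter applies both strict thresholds", {
  mk_counts <- function(value, n_samples, total = 100) {
    m <- matrix(0, 1, total)
    m[1, seq_len(n_samples)] <- value
    m
  }
  expect_length(filter_genes(mk_counts(11, 32), 10, 31), 1)
  expect_length(filter_genes(mk_counts(10, 100), 10, 31), 0)
  expect_length(filter_genes(mk_counts(11, 31), 10, 31), 0)
})

test_that("flat mean-variance trend yields near-unit relative weights", {
  set.seed(1)
  counts <- matrix(rpois(500 * 60, 1000), 500, 60,
                   dimnames = list(paste0("g", 1:500), paste0("s", 1:60)))
  design <- cbind(1, rep(0:1, each = 30))
  vw <- voom_weights(counts, design)
  expect_lt(max(vw$weights) / min(vw$weights), 1.3)
  expect_true(all(vw$weights > 0))
})

test_that("weights increase along a decreasing mean-variance trend", {
  set.seed(2)
  g <- 400; n <- 40
  mu <- exp(seq(log(5), log(5000), length.out = g))
  counts <- matrix(rnbinom(g * n, mu = rep(mu, n), size = 10), g, n,
                   dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  design <- cbind(1, rep(0:1, each = n / 2))
  vw <- voom_weights(counts, design)
  w <- rowMeans(vw$weights)
  expect_gt(cor(mu, w, method = "spearman"), 0.9)
})

test_that("voom weights agree with the limma reference implementation", {
  skip_if_not_installed("limma")
  set.seed(3)
  g <- 300; n <- 24
  counts <- matrix(rnbinom(g * n, mu = rep(exp(runif(g, 2, 7)), n),
                           size = 8), g, n,
                   dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  design <- cbind(1, rep(0:1, each = n / 2), rep(0:1, n / 2))
  vw <- voom_weights(counts, design)
  ref <- limma::voom(counts, design)
  expect_equal(vw$E, ref$E, ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(vw$weights, ref$weights, ignore_attr = TRUE,
               tolerance = 1e-6)
})

test_that("degenerate and rank-deficient inputs are rejected informatively", {
  counts <- matrix(rpois(20, 50), 1, 20,
                   dimnames = list("g1", paste0("s", 1:20)))
  design <- cbind(1, rep(0:1, 10))
  expect_warning(vw <- voom_weights(counts, design), regexp = "unit weights")
  expect_true(all(vw$weights == 1))
  counts2 <- matrix(rpois(40, 50), 2, 20,
                    dimnames = list(c("g1", "g2"), paste0("s", 1:20)))
  bad_design <- cbind(intercept = 1, a = rep(0:1, 10), b = rep(0:1, 10))
  expect_error(voom_weights(counts2, bad_design), regexp = "b",
               class = "sigtrace_design_error")
})

test_that("unit-weight fits equal ordinary least squares", {
  set.seed(4)
  n <- 16
  design <- cbind(intercept = 1, x = rnorm(n))
  y <- matrix(rnorm(5 * n), 5, n, dimnames = list(paste0("g", 1:5), NULL))
  vfit <- list(E = y, weights = matrix(1, 5, n), design = design)
  fit <- fit_and_moderate(vfit, coef = "x", df_prior_override = 0)
  for (g in 1:5) {
    ls <- summary(stats::lm(y[g, ] ~ design[, "x"]))
    expect_equal(fit$table$log2fc[g], unname(ls$coefficients[2, 1]),
                 tolerance = 1e-10)
    expect_equal(fit$table$t[g], unname(ls$coefficients[2, 3]),
                 tolerance = 1e-10)
    expect_equal(fit$table$p_value[g], unname(ls$coefficients[2, 4]),
                 tolerance = 1e-10)
  }
})

test_that("identical gene variances are a fixed point of shrinkage", {
  # residual variances all equal -> the prior collapses onto that value and
  # moderation changes nothing
  set.seed(5)
  n <- 12
  design <- cbind(1, rep(0:1, each = 6))
  base <- rnorm(n)
  y <- matrix(rep(base, each = 20), 20, n,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  vfit <- list(E = y, weights = matrix(1, 20, n), design = design)
  fit <- fit_and_moderate(vfit, coef = 2)
  expect_equal(unname(fit$s2_post), unname(fit$s2), tolerance = 1e-9)
})

test_that("moderated statistics agree with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(6)
  g <- 400; n <- 30
  counts <- matrix(rnbinom(g * n, mu = rep(exp(runif(g, 2.5, 7)), n),
                           size = 6), g, n,
                   dimnames = list(paste0("g", 1:g), paste0("s", 1:n)))
  design <- cbind(intercept = 1, grp = rep(0:1, each = n / 2))
  vw <- voom_weights(counts, design)
  fit <- fit_and_moderate(vw, coef = "grp")
  ref <- limma::eBayes(limma::lmFit(limma::voom(counts, design), design))
  tt <- limma::topTable(ref, coef = "grp", number = Inf, sort.by = "none")
  expect_equal(fit$table$log2fc, tt$logFC, tolerance = 1e-8)
  expect_equal(fit$table$t, tt$t, tolerance = 1e-4)
  expect_equal(fit$table$p_value, tt$P.Value, tolerance = 1e-4)
  expect_equal(fit$df_prior, ref$df.prior, tolerance = 1e-4)
  expect_equal(fit$s2_prior, ref$s2.prior, tolerance = 1e-4)
})

test_that("moderated t reduces to the ordinary t as the prior vanishes", {
  set.seed(7)
  n <- 10
  design <- cbind(1, rep(0:1, each = 5))
  y <- matrix(rnorm(30 * n), 30, n,
              dimnames = list(paste0("g", 1:30), NULL))
  vfit <- list(E = y, weights = matrix(1, 30, n), design = design)
  plain <- fit_and_moderate(vfit, coef = 2, df_prior_override = 0)
  for (g in c(1, 15, 30)) {
    ref <- stats::t.test(y[g, design[, 2] == 1], y[g, design[, 2] == 0],
                         var.equal = TRUE)
    expect_equal(plain$table$t[g], unname(ref$statistic), tolerance = 1e-10)
    expect_equal(plain$table$p_value[g], ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the direct step-up formula", {
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.3), 0.3)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  expect_error(adjust_bh(c(0.5, 1.2)))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:200, 1))
    expect_equal(adjust_bh(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("treatment-modulated call enforces all three clauses", {
  genes <- paste0("g", 1:4)
  mk_fit <- function(log2fc, p, fdr) {
    tibble::tibble(gene = genes, log2fc = log2fc, t = 0, p_value = p,
                   fdr = fdr)
  }
  # g1 passes everything; g2 fails the fold clause; g3 fails ileum nominal;
  # g4 fails combined FDR
  combined <- mk_fit(log2fc = c(log2(1.6), log2(1.4), log2(2), log2(2)),
                     p = 0.001, fdr = c(0.03, 0.03, 0.03, 0.2))
  colon <- mk_fit(log2fc = 1, p = c(0.01, 0.01, 0.01, 0.01), fdr = 1)
  ileum <- mk_fit(log2fc = 1, p = c(0.04, 0.04, 0.06, 0.01), fdr = 1)
  expect_identical(call_treatment_modulated(combined, colon, ileum), "g1")
  # |FC| boundary is inclusive
  combined2 <- mk_fit(log2fc = rep(log2(1.5), 4), p = 0.001, fdr = 0.01)
  expect_identical(call_treatment_modulated(combined2, colon,
                                            mk_fit(1, 0.01, 1)),
                   genes)
  # negative fold changes count through the absolute value
  combined3 <- mk_fit(log2fc = rep(-log2(1.6), 4), p = 0.001, fdr = 0.01)
  expect_length(call_treatment_modulated(combined3, colon,
                                         mk_fit(1, 0.01, 1)), 4)
  expect_error(call_treatment_modulated(combined[1:3, ], colon, ileum))
})

test_that("activity model uses screening samples only and finds the program", {
  trial <- simulate_trial(tiny_sim(seed = 17, activity_fold_change = 2))
  fit <- de_active_vs_inactive(trial$study)
  act <- intersect(trial$truth$activity_genes, fit$table$gene)
  hits <- fit$table[fit$table$gene %in% act, ]
  expect_gt(mean(hits$fdr < 0.05), 0.8)
  expect_true(all(hits$log2fc[hits$fdr < 0.05] > 0))
  # corrupting week-14 rows cannot change the result
  corrupted <- trial$study
  w14 <- corrupted$meta$visit == "week14"
  corrupted$counts[, w14] <- 0L
  fit2 <- de_active_vs_inactive(corrupted)
  expect_equal(fit$table, fit2$table)
})

test_that("activity confounded with location is an explicit error", {
  set.seed(18)
  meta <- make_meta(12, arm = c("placebo", "treatment"),
                    location = rep(c("colon", "ileum"), each = 6),
                    activity_scr = rep(c("active", "inactive"), each = 6))
  counts <- matrix(rnbinom(100 * 24, mu = 50, size = 10), 100, 24,
                   dimnames = list(paste0("g", 1:100), meta$sample_id))
  study <- bulk_study(counts, meta)
  expect_error(de_active_vs_inactive(study),
               class = "sigtrace_design_error")
})
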