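# Shared fixtures and independent oracles used across the suite.

# small-but-complete simulation settings for fast end-to-end runs
tiny_sim <- function(seed = 1L, ...) {
  args <- list(n_genes = 600, cells_per_type = 100, n_patients = 30,
               mito_gene_count = 20, n_activity_genes = 50, seed = seed)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# direct step-up BH formula: p_(i) * m / i with a cumulative minimum from
# the largest p down, capped at 1 (independent of stats::p.adjust)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# independent exact two-sided rank-sum oracle: recursive generation of all
# subsets (no combn), mid-ranks, 2 * min(tail) capped at 1
rank_sum_oracle <- function(x, y) {
  r <- rank(c(x, y))
  n <- length(r)
  n1 <- length(x)
  sums <- numeric(choose(n, n1))
  pos <- 0L
  recurse <- function(start, left, acc) {
    if (left == 0) {
      pos <<- pos + 1L
      sums[pos] <<- acc
      return(invisible())
    }
    for (i in start:(n - left + 1)) {
      recurse(i + 1, left - 1, acc + r[i])
    }
  }
  recurse(1, n1, 0)
  w <- sum(r[seq_len(n1)])
  tol <- 1e-9
  min(1, 2 * min(mean(sums <= w + tol), mean(sums >= w - tol)))
}

# minimal metadata builder for hand-constructed bulk studies
make_meta <- function(n_patients, arm, location = "colon",
                      activity_scr = "active", anti_tnf = "no") {
  pt <- sprintf("P%02d", seq_len(n_patients))
  arm <- rep_len(arm, n_patients)
  location <- rep_len(location, n_patients)
  activity_scr <- rep_len(activity_scr, n_patients)
  tibble::tibble(
    sample_id = c(paste0(pt, "_scr"), paste0(pt, "_w14")),
    patient_id = rep(pt, 2),
    arm = rep(arm, 2),
    visit = rep(c("screening", "week14"), each = n_patients),
    location = rep(location, 2),
    activity = c(activity_scr, activity_scr),
    anti_tnf = rep(rep_len(anti_tnf, n_patients), 2)
  )
}

# small normalized matrix with two groups of cells and configurable planted
# difference, for marker/merge unit tests
make_two_group_norm <- function(n_genes = 50, n_cells = 40, n_diff = 10,
                                fold = 4, seed = 1) {
  set.seed(seed)
  base <- matrix(rpois(n_genes * n_cells, 20), n_genes, n_cells)
  grp <- rep(0:1, each = n_cells / 2)
  base[seq_len(n_diff), grp == 1] <- base[seq_len(n_diff), grp == 1] * fold
  dimnames(base) <- list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("c%03d", seq_len(n_cells)))
  cm <- cell_matrix(base)
  list(norm = normalize_cells(cm),
       labels = stats::setNames(grp, colnames(base)))
}
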