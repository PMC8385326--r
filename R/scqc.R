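#' Viable-barcode quality-control filter
#'
#' Retains exactly the barcodes considered to contain viable cells: total
#' UMI count at least `min_umi` (inclusive) and mitochondrial UMI fraction
#' strictly below `max_mito_fraction`. A barcode with 1999 UMIs is removed;
#' a barcode at exactly 8% mitochondrial content is removed.
#'
#' @param matrix a [cell_matrix()].
#' @param min_umi minimum total UMI per barcode (kept when total >= min_umi).
#' @param max_mito_fraction barcodes are kept when their mitochondrial UMI
#'   fraction is strictly less than this value.
#' @return A list with `matrix` (filtered `cell_matrix`) and `report`, a
#'   one-row tibble counting barcodes removed under each criterion
#'   (criteria can overlap).
#' @examples
#' sim <- simulate_single_cell(sim_config(n_genes = 300, cells_per_type = 40))
#' qc <- qc_filter_barcodes(sim$matrix)
#' qc$report
#' @export
qc_filter_barcodes <- function(matrix, min_umi = 2000,
                               max_mito_fraction = 0.08) {
  stopifnot(inherits(matrix, "cell_matrix"))
  totals <- Matrix::colSums(matrix$counts)
  mito_totals <- Matrix::colSums(matrix$counts[matrix$mito, , drop = FALSE])
  mito_frac <- ifelse(totals > 0, mito_totals / totals, 1)
  low_umi <- totals < min_umi
  high_mito <- mito_frac >= max_mito_fraction
  keep <- !low_umi & !high_mito
  report <- tibble(
    n_input = length(keep),
    n_kept = sum(keep),
    removed_low_umi = sum(low_umi),
    removed_high_mito = sum(high_mito),
    removed_total = sum(!keep),
    min_umi = min_umi,
    max_mito_fraction = max_mito_fraction
  )
  if (!any(keep)) {
    rlang::warn("QC removed every barcode; returning an empty cell_matrix.",
                class = "sigtrace_empty_qc")
  }
  filtered <- cell_matrix(
    matrix$counts[, keep, drop = FALSE],
    gene_ids = matrix$gene_ids,
    barcode_ids = matrix$barcode_ids[keep],
    mito = matrix$mito,
    donor = matrix$donor[keep]
  )
  list(matrix = filtered, report = report)
}

#' Log-normalize a QC-filtered count matrix
#'
#' Scales each cell to a fixed total of `scale_factor` counts, then applies
#' `log1p`. The transform is scale invariant within a cell and monotone in
#' counts.
#'
#' @param matrix a `cell_matrix` (already QC-filtered).
#' @param scale_factor per-cell total after scaling (default 10,000).
#' @return A sparse genes x cells matrix of `log1p(count * S / total)`.
#' @export
normalize_cells <- function(matrix, scale_factor = 1e4) {
  stopifnot(inherits(matrix, "cell_matrix"))
  totals <- Matrix::colSums(matrix$counts)
  if (any(totals == 0)) {
    stop_sigtrace("zero-total barcode encountered; run QC filtering first.")
  }
  norm <- matrix$counts %*% Matrix::Diagonal(x = scale_factor / totals)
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(matrix$counts)
  norm
}

# per-donor gene standardization (each gene centered/scaled within donor),
# the package's stand-in for cross-donor alignment; synthetic donors differ
# only by mild multiplicative offsets, which this removes exactly
standardize_by_donor <- function(norm, donor) {
  x <- as.matrix(norm)
  for (d in unique(donor)) {
    idx <- which(donor == d)
    sub <- x[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sdv <- apply(sub, 1, sd)
    sdv[sdv == 0] <- 1
    x[, idx] <- (sub - mu) / sdv
  }
  x
}

#' Graph-based clustering of cells
#'
#' Standardizes genes within donor, reduces to principal components, builds
#' a k-nearest-neighbour graph (Euclidean distance in PC space) and applies
#' Louvain community detection at the given resolution. Deterministic for a
#' fixed seed.
#'
#' @param norm normalized genes x cells matrix from [normalize_cells()].
#' @param k_neighbors neighbours per cell in the kNN graph.
#' @param resolution Louvain resolution; lower values give the broad,
#'   low-resolution clusters appropriate for cell types.
#' @param seed integer seed for the community search.
#' @param donor optional per-cell donor labels for within-donor
#'   standardization (single donor assumed when `NULL`).
#' @param n_pcs number of principal components retained.
#' @return Integer cluster labels (contiguous from 0), named by barcode.
#' @export
cluster_cells <- function(norm, k_neighbors = 15, resolution = 0.3,
                          seed = 1L, donor = NULL, n_pcs = 20) {
  n_cells <- ncol(norm)
  if (n_cells < 2 * k_neighbors) {
    stop_sigtrace("need at least 2 * k_neighbors cells to cluster.")
  }
  donor <- donor %||% rep("donor1", n_cells)
  x <- standardize_by_donor(norm, donor)
  keep <- apply(x, 1, function(r) any(r != 0))
  x <- x[keep, , drop = FALSE]
  n_pcs <- min(n_pcs, n_cells - 1L, nrow(x) - 1L)
  pcs <- prcomp(t(x), center = FALSE, scale. = FALSE, rank. = n_pcs)$x
  d <- as.matrix(stats::dist(pcs))
  edges <- lapply(seq_len(n_cells), function(i) {
    nn <- order(d[i, ])[2:(k_neighbors + 1)]
    cbind(i, nn)
  })
  g <- igraph::graph_from_edgelist(do.call(rbind, edges), directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- igraph::membership(comm)
  labels <- as.integer(factor(labels, levels = sort(unique(labels)))) - 1L
  setNames(labels, colnames(norm))
}

# genes qualifying as markers of a cluster under the linear-scale fold rule
n_qualifying_genes <- function(lin, in_cluster, min_fold) {
  mean_in <- rowMeans(lin[, in_cluster, drop = FALSE])
  mean_out <- rowMeans(lin[, !in_cluster, drop = FALSE])
  sum(mean_in >= min_fold * (mean_out + .SIGTRACE_EPS))
}

#' Merge clusters lacking distinguishing genes
#'
#' Iteratively applies the marker-count merge rule: a cluster is retained
#' only if at least `min_markers` genes have linear-scale mean expression
#' in-cluster at least `min_fold` times the mean over all other cells.
#' A failing cluster (the one with fewest qualifying genes, ties broken by
#' label) is merged into the cluster whose centroid (in normalized log
#' space) has the highest Pearson correlation with its own. This repeats
#' until every cluster passes or a single cluster remains; final labels are
#' re-indexed contiguously from 0.
#'
#' @param norm normalized genes x cells matrix.
#' @param labels integer cluster labels named by barcode.
#' @param min_markers minimum number of qualifying genes (a cluster with
#'   exactly `min_markers` qualifying genes is retained).
#' @param min_fold linear-scale fold-change threshold for a qualifying gene.
#' @return Re-indexed integer labels named by barcode.
#' @export
merge_small_clusters <- function(norm, labels, min_markers = 30,
                                 min_fold = 1.5) {
  if (ncol(norm) != length(labels)) {
    stop_sigtrace("labels length must match number of cells.")
  }
  logm <- as.matrix(norm)
  lin <- expm1(logm)
  lab <- as.integer(labels)
  repeat {
    ids <- sort(unique(lab))
    if (length(ids) <= 1) break
    counts <- vapply(ids, function(cid) {
      n_qualifying_genes(lin, lab == cid, min_fold)
    }, numeric(1))
    failing <- ids[counts < min_markers]
    if (length(failing) == 0) break
    worst <- failing[which.min(counts[match(failing, ids)])]
    centroids <- vapply(ids, function(cid) {
      rowMeans(logm[, lab == cid, drop = FALSE])
    }, numeric(nrow(norm)))
    others <- ids[ids != worst]
    sims <- vapply(others, function(cid) {
      suppressWarnings(
        cor(centroids[, match(worst, ids)], centroids[, match(cid, ids)]))
    }, numeric(1))
    sims[is.na(sims)] <- -Inf
    target <- others[which.max(sims)]
    lab[lab == worst] <- target
  }
  relab <- as.integer(factor(lab, levels = sort(unique(lab)))) - 1L
  setNames(relab, names(labels))
}
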