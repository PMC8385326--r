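# Exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) group
# assignments of the pooled mid-ranks. Used when both groups have <= 10
# observations; handles ties exactly.
exact_rank_sum_p <- function(x, y) {
  r <- rank(c(x, y))
  n1 <- length(x)
  w_obs <- sum(r[seq_len(n1)])
  ws <- colSums(matrix(r[combn(length(r), n1)], nrow = n1))
  tol <- 1e-9
  p_le <- mean(ws <= w_obs + tol)
  p_ge <- mean(ws >= w_obs - tol)
  min(1, 2 * min(p_le, p_ge))
}

# Normal approximation with mid-ranks and tie-corrected variance (no
# continuity correction).
approx_rank_sum_p <- function(w, n1, n2, ties) {
  n <- n1 + n2
  mu <- n1 * (n + 1) / 2
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  v <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs(w - mu) / sqrt(v))
}

rank_sum_p <- function(w, r_in, r_all, n1, n2, exact_max = 10L) {
  if (n1 <= exact_max && n2 <= exact_max) {
    # re-enumerate from the rank vector directly
    ws <- colSums(matrix(r_all[combn(n1 + n2, n1)], nrow = n1))
    tol <- 1e-9
    min(1, 2 * min(mean(ws <= w + tol), mean(ws >= w - tol)))
  } else {
    ties <- table(r_all)
    approx_rank_sum_p(w, n1, n2, as.numeric(ties))
  }
}

#' One-vs-rest Wilcoxon rank-sum marker statistics
#'
#' For each gene, compares its normalized expression in a cluster against
#' all remaining cells with a two-sided Wilcoxon rank-sum test (exact
#' enumeration when both groups have at most 10 cells, normal approximation
#' with mid-ranks and tie-corrected variance otherwise). Fold changes are
#' computed on linear-scale means of the normalized expression with a
#' pseudocount of 1e-9 in numerator and denominator. P-values are adjusted
#' by Benjamini-Hochberg within each cluster's gene family.
#'
#' @param norm normalized genes x cells matrix from [normalize_cells()].
#' @param labels cluster labels named by barcode (as from
#'   [cluster_cells()]).
#' @param cluster a single cluster id, or `NULL` to compute markers for all
#'   clusters.
#' @return A tibble with columns `cluster, gene, log2fc, statistic
#'   (rank sum), p_value, fdr, pct_in, pct_out`.
#' @examples
#' m <- matrix(rpois(600, 5), nrow = 20,
#'             dimnames = list(paste0("g", 1:20), paste0("c", 1:30)))
#' cm <- cell_matrix(m)
#' norm <- normalize_cells(cm)
#' labels <- setNames(rep(0:1, 15), colnames(m))
#' rank_sum_markers(norm, labels, cluster = 0)
#' @export
rank_sum_markers <- function(norm, labels, cluster = NULL) {
  x <- as.matrix(norm)
  lab <- as.integer(labels)
  # per-gene mid-ranks and tie terms are shared across all one-vs-rest tests
  ranks <- t(apply(x, 1, rank))
  tie_term <- apply(ranks, 1, function(r) {
    t <- rle(sort(r))$lengths
    sum(t^3 - t)
  })
  lin <- expm1(x)
  clusters <- if (is.null(cluster)) sort(unique(lab)) else cluster
  out <- lapply(clusters, function(cid) {
    rank_sum_one(x, lin, ranks, tie_term, lab, cid)
  })
  bind_rows(out)
}

rank_sum_one <- function(x, lin, ranks, tie_term, lab, cluster) {
  in_idx <- which(lab == cluster)
  if (length(in_idx) == 0) stop_sigtrace("cluster has no cells.")
  if (length(in_idx) == ncol(x)) {
    stop_sigtrace("cluster contains all cells; no complement to test against.")
  }
  n1 <- length(in_idx)
  n2 <- ncol(x) - n1
  n <- n1 + n2
  mean_in <- rowMeans(lin[, in_idx, drop = FALSE])
  mean_out <- rowMeans(lin[, -in_idx, drop = FALSE])
  log2fc <- log2((mean_in + .SIGTRACE_EPS) / (mean_out + .SIGTRACE_EPS))
  w <- rowSums(ranks[, in_idx, drop = FALSE])

  if (n1 <= 10 && n2 <= 10) {
    pvals <- vapply(seq_len(nrow(x)), function(g) {
      rank_sum_p(w[g], ranks[g, in_idx], ranks[g, ], n1, n2)
    }, numeric(1))
  } else {
    mu <- n1 * (n + 1) / 2
    v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
    z <- ifelse(v > 0, (w - mu) / sqrt(v), 0)
    pvals <- ifelse(v > 0, 2 * stats::pnorm(-abs(z)), 1)
  }

  tibble(
    cluster = cluster,
    gene = rownames(x),
    log2fc = unname(log2fc),
    statistic = unname(w),
    p_value = unname(pvals),
    fdr = adjust_bh(pvals),
    pct_in = rowMeans(x[, in_idx, drop = FALSE] > 0),
    pct_out = rowMeans(x[, -in_idx, drop = FALSE] > 0)
  )
}

#' Build a bounded-size signature from a marker table
#'
#' Selects, for one cluster, the most differential genes: those with FDR
#' below `fdr_cut` and positive log2 fold change, ordered by descending
#' log2 fold change (ties broken deterministically by gene id) and
#' truncated to `max_genes`.
#'
#' @param markers marker tibble from [rank_sum_markers()].
#' @param cluster cluster id to build the signature for.
#' @param name signature name (defaults to `cluster<id>`).
#' @param max_genes cap on signature size.
#' @param fdr_cut FDR threshold for membership.
#' @return A tibble with columns `signature, gene, log2fc`, ordered by
#'   decreasing effect size; zero rows (with a warning) when no gene
#'   qualifies.
#' @export
build_signature <- function(markers, cluster, name = NULL, max_genes = 50,
                            fdr_cut = 0.01) {
  cl <- cluster
  name <- name %||% paste0("cluster", cl)
  hits <- markers |>
    filter(.data$cluster == cl, .data$fdr < fdr_cut, .data$log2fc > 0) |>
    arrange(desc(.data$log2fc), .data$gene) |>
    head(max_genes)
  if (nrow(hits) == 0) {
    rlang::warn(sprintf("no gene qualifies for signature '%s'.", name),
                class = "sigtrace_empty_signature")
  }
  tibble(signature = rep(name, nrow(hits)), gene = hits$gene,
         log2fc = hits$log2fc)
}

#' Build signatures for every cluster
#'
#' @param markers marker tibble covering all clusters.
#' @param names optional named character vector mapping cluster id (as
#'   character) to signature name.
#' @inheritParams build_signature
#' @return A signature tibble (`signature, gene, log2fc`).
#' @export
build_all_signatures <- function(markers, names = NULL, max_genes = 50,
                                 fdr_cut = 0.01) {
  ids <- sort(unique(markers$cluster))
  bind_rows(lapply(ids, function(cid) {
    nm <- if (!is.null(names) && as.character(cid) %in% base::names(names)) {
      names[[as.character(cid)]]
    } else NULL
    build_signature(markers, cid, name = nm, max_genes = max_genes,
                    fdr_cut = fdr_cut)
  }))
}

#' Read and write GMT gene-set files
#'
#' GMT is one line per set: name, description, then member genes, all
#' tab-separated. `write_gmt()` accepts a signature tibble (columns
#' `signature`, `gene`) or a named list of character vectors; empty
#' signatures are written as a name with no genes. `read_gmt()` returns a
#' signature tibble preserving gene order; duplicate genes within a line
#' are removed with a warning; a line with fewer than two fields is a parse
#' error reported with its line number.
#'
#' @param path file path.
#' @param signatures signature tibble or named list of gene vectors.
#' @param descriptions optional named character vector of descriptions.
#' @return `read_gmt()`: a tibble `signature, description, gene` (zero gene
#'   rows for empty sets are dropped, but the set is retained in the
#'   `sets` attribute); `write_gmt()`: the path, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  rows <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2) {
      stop_sigtrace(sprintf("malformed GMT line %d: fewer than 2 fields.", i),
                    class = "sigtrace_parse_error")
    }
    nm <- fields[[1]]
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      rlang::warn(sprintf("duplicate genes in GMT set '%s'; deduplicated.", nm))
      genes <- unique(genes)
    }
    sets[[nm]] <- genes
    descs[[nm]] <- fields[[2]]
    if (length(genes) > 0) {
      rows[[i]] <- tibble(signature = nm, description = fields[[2]],
                          gene = genes)
    }
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(signature = character(), description = character(),
                  gene = character())
  }
  attr(out, "sets") <- sets
  attr(out, "descriptions") <- descs
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(signatures, path, descriptions = NULL) {
  sets <- signature_sets(signatures)
  lines <- vapply(names(sets), function(nm) {
    desc <- descriptions[[nm]] %||% "sigtrace"
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Coerce signatures to a named list of gene vectors
#'
#' @param signatures a signature tibble (`signature`, `gene`) or already a
#'   named list of character vectors.
#' @return Named list of character gene vectors, order preserved.
#' @export
signature_sets <- function(signatures) {
  if (is.list(signatures) && !is.data.frame(signatures)) {
    stopifnot(!is.null(names(signatures)))
    return(lapply(signatures, as.character))
  }
  stopifnot(all(c("signature", "gene") %in% colnames(signatures)))
  nms <- unique(signatures$signature)
  setNames(lapply(nms, function(nm) {
    signatures$gene[signatures$signature == nm]
  }), nms)
}
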