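#' Single-cell UMI count container
#'
#' A light container for a sparse genes x barcodes UMI matrix together with
#' the per-gene mitochondrial flag and per-barcode donor label the QC and
#' clustering steps need.
#'
#' @param counts genes x barcodes matrix of nonnegative integer counts
#'   (dense or sparse; stored as `dgCMatrix`).
#' @param gene_ids,barcode_ids row / column identifiers.
#' @param mito logical per-gene mitochondrial flag.
#' @param donor per-barcode donor label (defaults to a single donor).
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, gene_ids = rownames(counts),
                        barcode_ids = colnames(counts),
                        mito = rep(FALSE, nrow(counts)),
                        donor = rep("donor1", ncol(counts))) {
  counts <- Matrix::Matrix(counts, sparse = TRUE)
  # pattern/logical sparse inputs (e.g. an all-zero MTX read back) become
  # numeric general sparse
  counts <- methods::as(methods::as(methods::as(
    counts, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(gene_ids) || is.null(barcode_ids)) {
    stop_sigtrace("gene and barcode identifiers are required.")
  }
  if (length(gene_ids) != nrow(counts) || length(barcode_ids) != ncol(counts)) {
    stop_sigtrace("identifier lengths do not match matrix dimensions.")
  }
  if (length(mito) != nrow(counts)) {
    stop_sigtrace("`mito` must have one flag per gene.")
  }
  if (any(counts@x < 0) || any(counts@x != round(counts@x))) {
    stop_sigtrace("counts must be nonnegative integers.")
  }
  dimnames(counts) <- list(gene_ids, barcode_ids)
  structure(
    list(counts = counts, gene_ids = gene_ids, barcode_ids = barcode_ids,
         mito = as.logical(mito),
         donor = setNames(as.character(donor), barcode_ids)),
    class = "cell_matrix"
  )
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat(sprintf(
    "<cell_matrix> %d genes x %d barcodes (%d mitochondrial genes, %d donors)\n",
    nrow(x$counts), ncol(x$counts), sum(x$mito), length(unique(x$donor))))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Bulk RNA-seq trial container
#'
#' Couples a genes x samples count matrix with per-sample trial metadata.
#' Metadata must carry `sample_id`, `patient_id`, `arm`
#' (placebo/treatment), `visit` (screening/week14), `location`
#' (colon/ileum), `activity` (active/inactive) and `anti_tnf` (yes/no);
#' an optional `ses_cd` segment score column is retained when present.
#'
#' @param counts genes x samples nonnegative integer matrix with dimnames.
#' @param meta data frame of per-sample metadata; coerced to tibble and
#'   validated by [validate_metadata()].
#' @return An object of class `bulk_study`.
#' @export
bulk_study <- function(counts, meta) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_sigtrace("counts must have gene rownames and sample colnames.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_sigtrace("counts must be nonnegative integers.")
  }
  meta <- validate_metadata(meta)
  if (!setequal(colnames(counts), meta$sample_id)) {
    stop_sigtrace("metadata sample_id set does not match count columns.")
  }
  meta <- meta[match(colnames(counts), meta$sample_id), ]
  structure(list(counts = counts, meta = meta), class = "bulk_study")
}

#' @export
print.bulk_study <- function(x, ...) {
  cat(sprintf("<bulk_study> %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  print(table(arm = x$meta$arm, visit = x$meta$visit))
  invisible(x)
}

#' @export
dim.bulk_study <- function(x) dim(x$counts)
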