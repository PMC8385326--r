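#' Write a dataset to plain-text fixture files
#'
#' Serializes simulated (or real) datasets into the standard plain-text
#' exchange formats: single-cell matrices as MatrixMarket MTX plus
#' `barcodes.tsv` / `features.tsv` (the feature table carries the
#' mitochondrial flag), bulk studies as a counts TSV plus a metadata TSV
#' with columns `sample_id, patient_id, arm, visit, location, activity,
#' anti_tnf`. Round trips through [read_sc_fixture()] /
#' [read_bulk_fixture()] are lossless.
#'
#' @param dataset a `cell_matrix` or `bulk_study`.
#' @param directory output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(dataset, directory) {
  UseMethod("write_fixture")
}

#' @export
write_fixture.cell_matrix <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop_sigtrace(sprintf("cannot create directory '%s'.", directory),
                  class = "sigtrace_io_error")
  }
  mtx <- file.path(directory, "matrix.mtx")
  Matrix::writeMM(dataset$counts, mtx)
  bc <- tibble(barcode = dataset$barcode_ids,
               donor = unname(dataset$donor))
  ft <- tibble(gene_id = dataset$gene_ids,
               mito = as.integer(dataset$mito))
  utils::write.table(bc, file.path(directory, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ft, file.path(directory, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(directory, c("matrix.mtx", "barcodes.tsv",
                                   "features.tsv")))
}

#' @export
write_fixture.bulk_study <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop_sigtrace(sprintf("cannot create directory '%s'.", directory),
                  class = "sigtrace_io_error")
  }
  counts <- data.frame(gene = rownames(dataset$counts), dataset$counts,
                       check.names = FALSE)
  utils::write.table(counts, file.path(directory, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta_cols <- c("sample_id", "patient_id", "arm", "visit", "location",
                 "activity", "anti_tnf")
  utils::write.table(dataset$meta[, meta_cols],
                     file.path(directory, "metadata.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(file.path(directory, c("counts.tsv", "metadata.tsv")))
}

#' Read a single-cell fixture directory
#'
#' @param directory directory holding `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` as written by [write_fixture()].
#' @return A `cell_matrix`.
#' @export
read_sc_fixture <- function(directory) {
  counts <- Matrix::readMM(file.path(directory, "matrix.mtx"))
  bc <- utils::read.delim(file.path(directory, "barcodes.tsv"),
                          stringsAsFactors = FALSE)
  ft <- utils::read.delim(file.path(directory, "features.tsv"),
                          stringsAsFactors = FALSE)
  cell_matrix(counts, gene_ids = ft$gene_id, barcode_ids = bc$barcode,
              mito = ft$mito == 1, donor = bc$donor)
}

#' Read a bulk-study fixture directory
#'
#' @param directory directory holding `counts.tsv` and `metadata.tsv`.
#' @return A `bulk_study`.
#' @export
read_bulk_fixture <- function(directory) {
  ct <- utils::read.delim(file.path(directory, "counts.tsv"),
                          check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(ct[, -1, drop = FALSE])
  rownames(counts) <- ct$gene
  meta <- utils::read.delim(file.path(directory, "metadata.tsv"),
                            stringsAsFactors = FALSE)
  bulk_study(counts, meta)
}

#' Write ground truth to JSON
#'
#' @param truth ground-truth list from a generator.
#' @param path output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  out <- truth
  if (!is.null(out$sample_proportions)) {
    out$sample_proportions <- as.data.frame(out$sample_proportions) |>
      tibble::rownames_to_column("sample_id")
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
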