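# Readers and writers for count matrices and pipeline tables.

#' Write a count matrix as TSV
#'
#' Features x samples, header row of sample IDs, first column
#' `feature_id`.
#'
#' @param counts matrix with row and column names (defaults supplied).
#' @param path output path.
#' @export
write_counts_tsv <- function(counts, path) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  df <- data.frame(feature_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix from TSV
#'
#' @param path TSV written by [write_counts_tsv()].
#' @return numeric matrix with feature IDs as row names.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}

#' Write a count matrix in MatrixMarket form
#'
#' Writes `<stem>.mtx` plus sidecar `<stem>_features.tsv` and
#' `<stem>_samples.tsv`.
#'
#' @param counts matrix.
#' @param stem output path stem (no extension).
#' @return the `.mtx` path, invisibly.
#' @export
write_counts_mtx <- function(counts, stem) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MatrixMarket output")
  }
  counts <- as.matrix(counts)
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(Matrix::Matrix(counts, sparse = TRUE), mtx)
  writeLines(rownames(counts) %||% paste0("f", seq_len(nrow(counts))),
             paste0(stem, "_features.tsv"))
  writeLines(colnames(counts) %||% paste0("s", seq_len(ncol(counts))),
             paste0(stem, "_samples.tsv"))
  invisible(mtx)
}

#' Read a MatrixMarket count matrix with sidecars
#'
#' @param stem path stem used by [write_counts_mtx()].
#' @return dense numeric matrix with dimnames from the sidecars.
#' @export
read_counts_mtx <- function(stem) {
  if (!requireNamespace("Matrix", quietly = TRUE)) {
    stop("the Matrix package is required for MatrixMarket input")
  }
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, "_features.tsv"))
  colnames(m) <- readLines(paste0(stem, "_samples.tsv"))
  m
}

#' Write ground truth and condition labels as TSV
#'
#' @param sim a `paired_count_data`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "paired_count_data"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_counts_tsv(sim$Y, file.path(dir, "absolute_counts.tsv"))
  write_counts_tsv(sim$Z, file.path(dir, "observed_counts.tsv"))
  utils::write.table(
    data.frame(sample_id = colnames(sim$Z), condition = sim$condition),
    file.path(dir, "condition.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(
    data.frame(feature_id = rownames(sim$Z), truth = sim$truth),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(dir)
}
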