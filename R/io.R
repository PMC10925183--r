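#' Read an expression dataset from disk
#'
#' Reads either a MatrixMarket sparse coordinate file plus one-per-line
#' gene and sample annotation TSVs, or a dense TSV whose first column is
#' the gene symbol and whose header row names the samples.
#'
#' @param matrix_path Path to the matrix: `.mtx` (MatrixMarket, genes in
#'   rows) or dense TSV.
#' @param genes_path Path to a TSV with one gene per line (first field =
#'   symbol). Ignored (may be `NULL`) for dense TSV input.
#' @param samples_path Path to a TSV with header and columns
#'   `sample_id`, and optionally `cell_type`, `age`, `species`. May be
#'   `NULL`, in which case minimal metadata is built from the matrix
#'   columns.
#' @param dataset_id Identifier for the new dataset.
#' @param age_unit Unit label for the `age` column.
#' @return An [expression_dataset].
#' @export
read_expression <- function(matrix_path, genes_path = NULL,
                            samples_path = NULL, dataset_id,
                            age_unit = "unspecified") {
  if (!file.exists(matrix_path)) stop("no such file: ", matrix_path)
  first <- readLines(matrix_path, n = 1L)
  is_mtx <- grepl("^%%MatrixMarket", first) || grepl("\\.mtx$", matrix_path)
  if (is_mtx) {
    m <- methods::as(Matrix::readMM(matrix_path), "CsparseMatrix")
    if (is.null(genes_path)) {
      stop("MatrixMarket input needs a gene annotation file")
    }
    genes <- utils::read.delim(genes_path, header = FALSE,
                               stringsAsFactors = FALSE)[[1]]
    if (length(genes) != nrow(m)) {
      stop(sprintf(
        "dimension mismatch: genes file has %d rows but matrix declares %d rows",
        length(genes), nrow(m)
      ))
    }
  } else {
    tab <- utils::read.delim(matrix_path, header = TRUE, check.names = FALSE,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    storage.mode(m) <- "double"
  }
  if (!is.null(samples_path)) {
    meta <- utils::read.delim(samples_path, header = TRUE,
                              stringsAsFactors = FALSE)
    if (!"sample_id" %in% names(meta)) {
      names(meta)[1] <- "sample_id"
    }
    if (nrow(meta) != ncol(m)) {
      stop(sprintf(
        "dimension mismatch: samples file has %d rows but matrix declares %d columns",
        nrow(meta), ncol(m)
      ))
    }
  } else if (!is_mtx && !is.null(colnames(m))) {
    meta <- data.frame(sample_id = colnames(m), stringsAsFactors = FALSE)
  } else {
    meta <- NULL
  }
  expression_dataset(m, genes, meta, dataset_id, age_unit = age_unit)
}

#' Write an expression dataset to a directory
#'
#' Writes `matrix.mtx` (MatrixMarket coordinate), `genes.tsv` (one symbol
#' per line) and `samples.tsv` (metadata with header), the same layout
#' [read_expression] consumes.
#'
#' @param d An `expression_dataset`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_expression <- function(d, dir) {
  stopifnot(inherits(d, "expression_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    matrix = file.path(dir, "matrix.mtx"),
    genes = file.path(dir, "genes.tsv"),
    samples = file.path(dir, "samples.tsv")
  )
  m <- d$matrix
  if (!methods::is(m, "sparseMatrix")) {
    m <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
  }
  Matrix::writeMM(m, paths[["matrix"]])
  writeLines(d$genes, paths[["genes"]])
  utils::write.table(d$sample_meta, paths[["samples"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a dataset directory written by [write_expression]
#' @param dir Directory containing `matrix.mtx`, `genes.tsv`, `samples.tsv`.
#' @param dataset_id Identifier (defaults to the directory name).
#' @param age_unit Unit label for the age column.
#' @return An [expression_dataset].
#' @export
read_expression_dir <- function(dir, dataset_id = basename(dir),
                                age_unit = "unspecified") {
  read_expression(file.path(dir, "matrix.mtx"), file.path(dir, "genes.tsv"),
                  file.path(dir, "samples.tsv"), dataset_id,
                  age_unit = age_unit)
}

#' Write a gene-loading matrix as TSV
#'
#' First column `gene`, remaining columns one per pattern.
#' @param W Loading matrix with row names (genes) and column names
#'   (patterns).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_loadings <- function(W, path) {
  stopifnot(!is.null(rownames(W)), !is.null(colnames(W)))
  df <- data.frame(gene = rownames(W), as.data.frame(as.matrix(W)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-loading matrix written by [write_loadings]
#' @param path TSV with a `gene` column followed by one column per pattern.
#' @return Numeric matrix, genes in rows (row names = symbols).
#' @export
read_loadings <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- toupper(df[[1]])
  storage.mode(W) <- "double"
  W
}
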