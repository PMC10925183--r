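#' Construct an expression dataset
#'
#' Bundles a nonnegative gene-by-sample matrix with its gene symbols and
#' per-sample metadata. This is the unit of input for the joint
#' factorization, projection and annotation steps: rows are genes
#' (uppercased symbols), columns are cells or bulk samples.
#'
#' @param matrix Nonnegative numeric matrix (base or [Matrix::Matrix]),
#'   genes in rows, samples in columns.
#' @param genes Character vector of gene symbols, one per matrix row.
#'   Symbols are uppercased; duplicates are an error.
#' @param sample_meta Data frame with one row per sample. Must contain a
#'   `sample_id` column (or row names are used); optional columns
#'   `cell_type`, `age` (numeric), `species`. Missing columns are filled
#'   with `NA`.
#' @param dataset_id Short identifier for the dataset.
#' @param age_unit Free-text label for the unit of the `age` column
#'   (e.g. `"days"`, `"gestational_week"`, `"bin"`).
#'
#' @return An object of class `expression_dataset`: a list with elements
#'   `dataset_id`, `genes`, `matrix`, `sample_meta`, `age_unit`.
#' @export
expression_dataset <- function(matrix, genes, sample_meta, dataset_id,
                               age_unit = "unspecified") {
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (!(is.matrix(matrix) || methods::is(matrix, "Matrix"))) {
    stop("`matrix` must be a base matrix or a Matrix object")
  }
  genes <- toupper(as.character(genes))
  if (length(genes) != nrow(matrix)) {
    stop(sprintf(
      "dimension mismatch: %d gene symbols but matrix has %d rows",
      length(genes), nrow(matrix)
    ))
  }
  dup <- unique(genes[duplicated(genes)])
  if (length(dup)) {
    stop("duplicate gene symbols: ", paste(dup, collapse = ", "))
  }
  sample_meta <- normalize_sample_meta(sample_meta, ncol(matrix))
  if (nrow(sample_meta) != ncol(matrix)) {
    stop(sprintf(
      "dimension mismatch: %d metadata rows but matrix has %d columns",
      nrow(sample_meta), ncol(matrix)
    ))
  }
  dup_s <- unique(sample_meta$sample_id[duplicated(sample_meta$sample_id)])
  if (length(dup_s)) {
    stop("duplicate sample ids: ", paste(dup_s, collapse = ", "))
  }
  vals <- if (methods::is(matrix, "sparseMatrix")) matrix@x else as.numeric(matrix)
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals)))) {
    stop("matrix entries must be finite")
  }
  if (length(vals) && any(vals < 0)) {
    stop("matrix entries must be nonnegative")
  }
  dimnames(matrix) <- list(genes, sample_meta$sample_id)
  structure(
    list(
      dataset_id = as.character(dataset_id)[1],
      genes = genes,
      matrix = matrix,
      sample_meta = sample_meta,
      age_unit = age_unit
    ),
    class = "expression_dataset"
  )
}

normalize_sample_meta <- function(sample_meta, n_samples) {
  if (is.null(sample_meta)) {
    sample_meta <- data.frame(sample_id = sprintf("S%04d", seq_len(n_samples)))
  }
  sample_meta <- as.data.frame(sample_meta)
  if (!"sample_id" %in% names(sample_meta)) {
    if (!is.null(rownames(sample_meta)) &&
        !identical(rownames(sample_meta), as.character(seq_len(nrow(sample_meta))))) {
      sample_meta$sample_id <- rownames(sample_meta)
    } else {
      stop("sample_meta needs a `sample_id` column or informative row names")
    }
  }
  sample_meta$sample_id <- as.character(sample_meta$sample_id)
  for (col in c("cell_type", "species")) {
    if (!col %in% names(sample_meta)) sample_meta[[col]] <- NA_character_
    sample_meta[[col]] <- as.character(sample_meta[[col]])
  }
  if (!"age" %in% names(sample_meta)) sample_meta$age <- NA_real_
  sample_meta$age <- as.numeric(sample_meta$age)
  rownames(sample_meta) <- NULL
  ord <- c("sample_id", "cell_type", "age", "species")
  sample_meta[, c(ord, setdiff(names(sample_meta), ord)), drop = FALSE]
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> '%s': %d genes x %d samples\n",
    x$dataset_id, nrow(x$matrix), ncol(x$matrix)
  ))
  sp <- unique(stats::na.omit(x$sample_meta$species))
  if (length(sp)) cat("  species:", paste(sp, collapse = ", "), "\n")
  n_age <- sum(!is.na(x$sample_meta$age))
  cat(sprintf("  samples with age: %d (unit: %s)\n", n_age, x$age_unit))
  invisible(x)
}

#' @export
dim.expression_dataset <- function(x) dim(x$matrix)

#' Species tag of a dataset
#'
#' The single species recorded in the sample metadata (the most frequent
#' value if several are present, `NA` when none is recorded).
#' @param d An `expression_dataset`.
#' @return Character scalar.
#' @export
dataset_species <- function(d) {
  sp <- stats::na.omit(d$sample_meta$species)
  if (!length(sp)) return(NA_character_)
  names(sort(table(sp), decreasing = TRUE))[1]
}

#' Library-size normalization of an expression dataset
#'
#' `cp10k_log` rescales every sample (column) to a total of 10,000 counts
#' and applies `log(1 + x)` — the standard counts-per-10k/log1p transform
#' for single-cell data. All-zero columns are left all-zero with a
#' warning. `none` returns the dataset unchanged.
#'
#' @param d An `expression_dataset` of nonnegative counts.
#' @param mode `"cp10k_log"` (default) or `"none"`.
#' @return An `expression_dataset` with the transformed matrix.
#' @export
normalize_expression <- function(d, mode = c("cp10k_log", "none")) {
  mode <- match.arg(mode)
  stopifnot(inherits(d, "expression_dataset"))
  if (mode == "none") return(d)
  m <- d$matrix
  cs <- Matrix::colSums(m)
  zero <- cs == 0
  if (any(zero)) {
    warning(sprintf("%d all-zero column(s) left unchanged", sum(zero)))
  }
  scale <- ifelse(zero, 0, 1e4 / cs)
  if (methods::is(m, "sparseMatrix")) {
    m <- m %*% Matrix::Diagonal(x = scale)
    m@x <- log1p(m@x)
  } else {
    m <- sweep(as.matrix(m), 2, scale, `*`)
    m <- log1p(m)
  }
  out <- d
  out$matrix <- m
  dimnames(out$matrix) <- list(d$genes, d$sample_meta$sample_id)
  out
}
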