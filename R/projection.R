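#' Project a dataset into a fixed set of gene loadings
#'
#' Transfer learning step: each sample's expression vector is regressed
#' onto the loading matrix `W` restricted to the genes the dataset and
#' `W` share, under a nonnegativity constraint (per-sample non-negative
#' least squares). The raw embeddings live on a scale that depends on
#' the dataset's units and depth, so a per-pattern min--max rescaling
#' bounded by the projected dataset itself is attached for display:
#' scaled values are comparable within, never across, datasets.
#'
#' Genes of `W` absent from the dataset are dropped from `W` (not
#' zero-filled in the data, which would bias embeddings downward). If
#' the shared fraction of `W`'s genes falls below `min_overlap` the
#' projection aborts, guarding against silently meaningless
#' cross-platform projections.
#'
#' @param dataset An [expression_dataset] (normalize first for real
#'   data; the solver itself is agnostic).
#' @param W Loading matrix, gene symbols as row names, patterns as
#'   column names. An unweighted gene list can be projected by building
#'   a one-column indicator matrix (membership weight 1).
#' @param min_overlap Minimum fraction of `W`'s genes that must be
#'   present in the dataset (default 0.5).
#' @param method `"nnls"` (default) or `"pinv"`, an unconstrained
#'   least-squares alternative kept for comparison (its raw embeddings
#'   can be negative).
#' @return An object of class `projection_result` with elements
#'   `dataset_id`, `pattern_names`, `raw` (patterns x samples),
#'   `scaled` (per-pattern min--max of raw, in `[0,1]`), `genes_used`,
#'   `genes_missing`, `method`.
#' @export
project <- function(dataset, W, min_overlap = 0.5,
                    method = c("nnls", "pinv")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"))
  W <- as.matrix(W)
  if (is.null(rownames(W))) stop("`W` must have gene symbols as row names")
  if (is.null(colnames(W))) {
    colnames(W) <- sprintf("p%dof%d", seq_len(ncol(W)), ncol(W))
  }
  rownames(W) <- toupper(rownames(W))
  shared <- intersect(rownames(W), dataset$genes)
  overlap <- length(shared) / nrow(W)
  if (overlap < min_overlap) {
    stop(sprintf(
      "gene overlap %.3f below min_overlap %.3f (%d of %d loading genes present)",
      overlap, min_overlap, length(shared), nrow(W)
    ))
  }
  Ws <- W[shared, , drop = FALSE]
  zero_col <- colSums(Ws^2) == 0
  if (any(zero_col)) {
    warning(sprintf(
      "%d loading column(s) are zero on the shared genes; their embeddings are set to 0",
      sum(zero_col)
    ))
  }
  X <- as.matrix(dataset$matrix[shared, , drop = FALSE])
  k <- ncol(W)
  n <- ncol(X)
  raw <- matrix(0, k, n, dimnames = list(colnames(W), colnames(X)))
  active <- which(!zero_col)
  if (length(active)) {
    Wa <- Ws[, active, drop = FALSE]
    if (method == "nnls") {
      AtA <- crossprod(Wa)
      AtB <- crossprod(Wa, X)
      for (i in seq_len(n)) {
        raw[active, i] <- nnls_normal(AtA, AtB[, i])
      }
    } else {
      raw[active, ] <- qr.solve(Wa, X)
    }
  }
  structure(
    list(
      dataset_id = dataset$dataset_id,
      pattern_names = colnames(W),
      raw = raw,
      scaled = minmax_scale(raw),
      genes_used = length(shared),
      genes_missing = nrow(W) - length(shared),
      method = method
    ),
    class = "projection_result"
  )
}

#' @export
print.projection_result <- function(x, ...) {
  cat(sprintf(
    "<projection_result> '%s': %d pattern(s) x %d sample(s) [%s; %d genes used, %d missing]\n",
    x$dataset_id, nrow(x$raw), ncol(x$raw), x$method, x$genes_used,
    x$genes_missing
  ))
  invisible(x)
}

#' Per-row min--max scaling to [0, 1]
#'
#' Every row is mapped by `(v - min) / (max - min)`; constant rows map
#' to all zeros. This is the display convention for projections:
#' minimum-to-maximum bounded by each individual dataset projected.
#'
#' @param raw Numeric matrix (patterns x samples), finite entries.
#' @return Matrix of the same shape with entries in `[0, 1]`.
#' @export
minmax_scale <- function(raw) {
  raw <- as.matrix(raw)
  stopifnot(all(is.finite(raw)))
  lo <- apply(raw, 1, min)
  hi <- apply(raw, 1, max)
  rng <- hi - lo
  out <- (raw - lo) / ifelse(rng == 0, 1, rng)
  out[rng == 0, ] <- 0
  dimnames(out) <- dimnames(raw)
  out
}

#' Summarize projected embeddings by sample groups
#'
#' One row per observed combination of the grouping columns and pattern,
#' with mean, median, 10th/90th percentiles and group size. Groups
#' smaller than `min_n` are flagged (`small_group = TRUE`) rather than
#' dropped.
#'
#' @param p A `projection_result`.
#' @param meta Data frame of sample metadata with a `sample_id` column
#'   matching the projected samples.
#' @param group_cols Character vector of metadata columns to group by,
#'   e.g. `c("cell_type", "age")`.
#' @param value Summarize `"scaled"` (default) or `"raw"` embeddings.
#' @param min_n Flag floor for group size (default 10).
#' @return Data frame of group x pattern summaries.
#' @export
summarize_by_group <- function(p, meta, group_cols,
                               value = c("scaled", "raw"), min_n = 10L) {
  value <- match.arg(value)
  stopifnot(inherits(p, "projection_result"))
  meta <- as.data.frame(meta)
  if (!"sample_id" %in% names(meta)) stop("meta needs a `sample_id` column")
  missing_cols <- setdiff(group_cols, names(meta))
  if (length(missing_cols)) {
    stop("unknown group column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- p[[value]]
  idx <- match(colnames(m), meta$sample_id)
  if (anyNA(idx)) stop("metadata is missing some projected samples")
  g <- meta[idx, group_cols, drop = FALSE]
  key <- interaction(g, drop = TRUE, lex.order = TRUE)
  rows <- lapply(levels(key), function(lv) {
    cells <- which(key == lv)
    grp <- g[cells[1], , drop = FALSE]
    vals <- m[, cells, drop = FALSE]
    data.frame(
      grp,
      pattern = rownames(m),
      n = length(cells),
      mean = rowMeans(vals),
      median = apply(vals, 1, stats::median),
      q10 = apply(vals, 1, stats::quantile, probs = 0.10),
      q90 = apply(vals, 1, stats::quantile, probs = 0.90),
      small_group = length(cells) < min_n,
      row.names = NULL,
      check.names = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
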