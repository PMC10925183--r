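#' Composite gene-set scores per cell
#'
#' Scores every cell against every gene set by combining the expression
#' of the member genes: `sum` (summed expression, the convention for
#' S/G2M cell-cycle phase scores), `mean`, or `mean_z` (each gene is
#' first standardized across cells, then member z-scores are averaged;
#' robust to set size and the default for consensus cell typing with
#' cross-study marker sets). Zero-variance genes contribute 0 under
#' `mean_z`. Sets with no member present in the dataset are skipped with
#' a warning.
#'
#' @param dataset A normalized [expression_dataset].
#' @param sets A [gene_set_collection].
#' @param method `"mean_z"` (default), `"sum"`, or `"mean"`.
#' @return An object of class `cell_scores`: list with `scores`
#'   (sets x cells matrix), `method`, `sets_skipped`.
#' @export
composite_score <- function(dataset, sets, method = c("mean_z", "sum", "mean")) {
  method <- match.arg(method)
  stopifnot(inherits(dataset, "expression_dataset"),
            inherits(sets, "gene_set_collection"))
  if (!length(sets$sets)) stop("empty gene-set collection")
  X <- as.matrix(dataset$matrix)
  if (method == "mean_z") {
    mu <- rowMeans(X)
    sd <- sqrt(rowSums((X - mu)^2) / max(ncol(X) - 1, 1))
    Z <- (X - mu) / ifelse(sd == 0, 1, sd)
    Z[sd == 0, ] <- 0
    X <- Z
  }
  present <- lapply(sets$sets, function(g) intersect(g, dataset$genes))
  skipped <- names(present)[lengths(present) == 0]
  if (length(skipped)) {
    warning("set(s) with no member gene present skipped: ",
            paste(skipped, collapse = ", "))
  }
  keep <- names(present)[lengths(present) > 0]
  if (!length(keep)) stop("no gene set has members in the dataset")
  scores <- t(vapply(keep, function(nm) {
    rows <- X[present[[nm]], , drop = FALSE]
    if (method == "sum") colSums(rows) else colMeans(rows)
  }, numeric(ncol(X))))
  dimnames(scores) <- list(keep, colnames(dataset$matrix))
  structure(
    list(scores = scores, method = method, sets_skipped = skipped),
    class = "cell_scores"
  )
}

#' @export
print.cell_scores <- function(x, ...) {
  cat(sprintf("<cell_scores> %d set(s) x %d cell(s), method=%s\n",
              nrow(x$scores), ncol(x$scores), x$method))
  invisible(x)
}

#' Assign consensus labels from composite scores
#'
#' Each cell is labeled with the highest-scoring set; exact ties go to
#' the alphabetically first set name so labeling is deterministic. The
#' margin is the difference between the best and second-best score
#' (with a single set, the score itself); cells whose margin falls below
#' `min_margin` abstain as `"unassigned"`. Raising `min_margin` can only
#' turn assigned labels into abstentions, never change them.
#'
#' @param scores A `cell_scores` object (or a sets x cells matrix).
#' @param min_margin Abstention threshold (default 0).
#' @return Data frame of class `cell_labeling` with columns `sample_id`,
#'   `label`, `margin`.
#' @export
assign_labels <- function(scores, min_margin = 0) {
  m <- if (inherits(scores, "cell_scores")) scores$scores else as.matrix(scores)
  set_names <- rownames(m)
  stopifnot(!is.null(set_names))
  ord_sets <- order(set_names)
  n <- ncol(m)
  label <- character(n)
  margin <- numeric(n)
  for (i in seq_len(n)) {
    v <- m[, i]
    o <- order(-v, set_names)
    label[i] <- set_names[o[1]]
    margin[i] <- if (length(v) > 1) v[o[1]] - v[o[2]] else v[o[1]]
  }
  margin <- pmax(margin, 0)
  label[margin < min_margin] <- "unassigned"
  out <- data.frame(
    sample_id = colnames(m) %||% sprintf("S%04d", seq_len(n)),
    label = label,
    margin = margin,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_labeling", "data.frame")
  attr(out, "min_margin") <- min_margin
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
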