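#' Rank-sum enrichment of gene sets in pattern loadings
#'
#' For each gene set, tests whether member genes carry larger loadings
#' than non-members with a one-sided Wilcoxon rank-sum test (midranks
#' for ties; exact null when feasible, otherwise normal approximation
#' with continuity correction — the behavior of [stats::wilcox.test]).
#' Benjamini--Hochberg q-values are computed across every pattern x set
#' pair tested in the one call.
#'
#' @param loadings Named numeric vector (one pattern) or a genes x
#'   patterns matrix with gene row names and pattern column names.
#' @param sets A [gene_set_collection].
#' @param universe Gene symbols defining the tested universe (default:
#'   the loading genes).
#' @return Data frame with columns `pattern`, `set`, `test`,
#'   `n_set_in_universe`, `statistic` (rank-sum W), `p_value`,
#'   `q_value`. Sets empty after intersection with the universe, or
#'   equal to it, are skipped with a warning.
#' @export
loading_ranksum_enrichment <- function(loadings, sets, universe = NULL) {
  run_enrichment(loadings, sets, universe, test = "ranksum")
}

#' Hypergeometric enrichment in the top loading fraction
#'
#' Cuts the top `ceiling(top_fraction * |universe|)` genes by loading
#' (ties at the cutoff broken by symbol, as in [top_loading_genes]) and
#' tests each set's overlap with that top list against the upper
#' hypergeometric tail. This mirrors top-quantile statements such as a
#' gene ranking in the top 1% of genome-wide loadings.
#'
#' @inheritParams loading_ranksum_enrichment
#' @param top_fraction Fraction of the universe forming the top list,
#'   in `(0, 1)` (default 0.01).
#' @return Data frame as in [loading_ranksum_enrichment], with
#'   `statistic` = overlap count and extra column `k_top`.
#' @export
loading_topfraction_hypergeom <- function(loadings, sets, universe = NULL,
                                          top_fraction = 0.01) {
  if (!is.numeric(top_fraction) || top_fraction <= 0 || top_fraction >= 1) {
    stop("`top_fraction` must be in (0, 1)")
  }
  run_enrichment(loadings, sets, universe, test = "hypergeom",
                 top_fraction = top_fraction)
}

run_enrichment <- function(loadings, sets, universe, test,
                           top_fraction = NULL) {
  stopifnot(inherits(sets, "gene_set_collection"))
  if (is.null(dim(loadings))) {
    loadings <- matrix(loadings, ncol = 1,
                       dimnames = list(names(loadings), "p1"))
  }
  W <- as.matrix(loadings)
  if (is.null(rownames(W))) stop("loadings must carry gene names")
  rownames(W) <- toupper(rownames(W))
  if (is.null(universe)) universe <- rownames(W)
  universe <- unique(toupper(universe))
  universe <- universe[universe %in% rownames(W)]
  n_univ <- length(universe)
  if (n_univ < 2) stop("universe must contain at least 2 loading genes")
  rows <- list()
  for (p in colnames(W)) {
    v <- W[universe, p]
    if (test == "hypergeom") {
      k_top <- ceiling(top_fraction * n_univ)
      top_genes <- universe[order(-v, universe)][seq_len(k_top)]
    }
    for (s in names(sets$sets)) {
      members <- intersect(sets$sets[[s]], universe)
      m <- length(members)
      if (m == 0 || m == n_univ) {
        warning(sprintf(
          "set '%s' skipped for pattern '%s': %s the universe",
          s, p, if (m == 0) "empty after intersection with" else "equal to"))
        next
      }
      if (test == "ranksum") {
        wt <- suppressWarnings(stats::wilcox.test(
          v[universe %in% members], v[!universe %in% members],
          alternative = "greater"
        ))
        stat <- unname(wt$statistic)
        pv <- wt$p.value
        extra <- NULL
      } else {
        x <- sum(members %in% top_genes)
        pv <- stats::phyper(x - 1, m, n_univ - m, k_top, lower.tail = FALSE)
        stat <- x
        extra <- k_top
      }
      row <- data.frame(
        pattern = p, set = s, test = test, n_set_in_universe = m,
        statistic = stat, p_value = pv, stringsAsFactors = FALSE
      )
      if (!is.null(extra)) row$k_top <- extra
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (!length(rows)) {
    stop("no testable pattern x set pair")
  }
  out <- do.call(rbind, rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Rank correlation between loadings and gene-level GWAS scores
#'
#' Associates a pattern's gene loadings with any per-gene real summary
#' of a genome-wide association study (e.g. MAGMA-style gene scores or
#' -log10 p) by Spearman correlation on the shared genes, with the
#' t-approximation p-value of [stats::cor.test]. Genes present on only
#' one side are dropped and counted.
#'
#' @param loadings Named numeric vector of one pattern's gene loadings.
#' @param gene_scores Named numeric vector of per-gene GWAS summaries.
#' @param method Only `"spearman"` is provided.
#' @return List with `estimate`, `p_value`, `n_shared`,
#'   `n_dropped_loadings`, `n_dropped_scores`, `method`.
#' @export
gwas_loading_association <- function(loadings, gene_scores,
                                     method = "spearman") {
  method <- match.arg(method, "spearman")
  stopifnot(!is.null(names(loadings)), !is.null(names(gene_scores)))
  names(loadings) <- toupper(names(loadings))
  names(gene_scores) <- toupper(names(gene_scores))
  shared <- intersect(names(loadings), names(gene_scores))
  if (length(shared) < 10) {
    stop(sprintf("only %d genes shared between loadings and scores (need >= 10)",
                 length(shared)))
  }
  ct <- suppressWarnings(stats::cor.test(
    loadings[shared], gene_scores[shared],
    method = "spearman", exact = FALSE
  ))
  list(
    estimate = unname(ct$estimate),
    p_value = ct$p.value,
    n_shared = length(shared),
    n_dropped_loadings = length(loadings) - length(shared),
    n_dropped_scores = length(gene_scores) - length(shared),
    method = method
  )
}

#' Select cells with the highest embedding of a pattern
#'
#' Deterministic top-slice selection: the target count is
#' `max(ceiling(n * (1 - quantile)), min_cells)` and cells are ranked by
#' embedding descending with ties (including fully constant embeddings)
#' broken by sample id ascending. Every selected cell has a value at
#' least as large as every excluded cell. This is how "cells defined by
#' levels of" a program (e.g. putative oRG cells by their oRG-pattern
#' embedding) are picked.
#'
#' @param embeddings Named numeric vector of one pattern's per-cell
#'   embeddings.
#' @param quantile Quantile cut (default 0.99 keeps the top 1%).
#' @param min_cells Minimum number of cells to keep (default 50); an
#'   error if the dataset has fewer cells than this.
#' @return Character vector of selected cell ids (or integer indices if
#'   the vector is unnamed), in rank order.
#' @export
select_top_cells <- function(embeddings, quantile = 0.99, min_cells = 50L) {
  n <- length(embeddings)
  if (n < min_cells) {
    stop(sprintf("only %d cells present but min_cells=%d", n, min_cells))
  }
  ids <- names(embeddings) %||% as.character(seq_len(n))
  m <- max(ceiling(n * (1 - quantile)), min_cells)
  ord <- order(-embeddings, ids)
  sel <- ord[seq_len(m)]
  if (!is.null(names(embeddings))) ids[sel] else sel
}

#' Loading-versus-expression profile in selected cells
#'
#' For one pattern, plots (numerically) each gene's loading against its
#' mean expression in a chosen cell subset — typically the cells highest
#' in that pattern — with the Pearson correlation of the two measures
#' and a loess trend (degree-1 locally weighted regression, tricube
#' weights, no robustness iterations, evaluated on a 100-point grid
#' spanning the observed loadings). Across species, the strength of this
#' correlation indexes how coherently a program's member genes are
#' actually expressed in the cells that carry the program.
#'
#' @param dataset A normalized [expression_dataset].
#' @param loadings Named numeric vector of one pattern's gene loadings.
#' @param cells Cell ids (or indices) over which to average expression,
#'   e.g. from [select_top_cells].
#' @param loess_span Loess span fraction (default 0.5).
#' @param grid_n Grid size for the fitted curve (default 100).
#' @return Object of class `loading_expression_profile`: list with
#'   `dataset_id`, `genes`, `loading`, `mean_expr`, `correlation`
#'   (list: method, estimate, p_value), `loess` (data frame `x`,
#'   `fitted`, `x` strictly increasing), `n_cells`.
#' @export
loading_expression_profile <- function(dataset, loadings, cells,
                                       loess_span = 0.5, grid_n = 100L) {
  stopifnot(inherits(dataset, "expression_dataset"))
  stopifnot(!is.null(names(loadings)))
  names(loadings) <- toupper(names(loadings))
  genes <- intersect(dataset$genes, names(loadings))
  if (length(genes) < 10) stop("fewer than 10 genes shared with the loadings")
  X <- dataset$matrix[genes, cells, drop = FALSE]
  mean_expr <- as.numeric(Matrix::rowMeans(X))
  x <- unname(loadings[genes])
  correlation <- list(method = "pearson", estimate = NA_real_,
                      p_value = NA_real_)
  if (stats::sd(x) == 0 || stats::sd(mean_expr) == 0) {
    warning("zero variance on one axis; correlation undefined")
  } else {
    ct <- stats::cor.test(x, mean_expr, method = "pearson")
    correlation$estimate <- unname(ct$estimate)
    correlation$p_value <- ct$p.value
  }
  # Sparse loadings pile most genes near zero; loess emits zero-width
  # neighborhood warnings there even though the fit is well defined, so
  # fitting is quiet and only non-finite output escalates (refit at full
  # span, which always has a nonempty window).
  grid <- seq(min(x), max(x), length.out = grid_n)
  fit_curve <- function(span) {
    fit <- suppressWarnings(stats::loess(
      mean_expr ~ x, span = span, degree = 1, family = "gaussian",
      control = stats::loess.control(surface = "direct")
    ))
    suppressWarnings(stats::predict(fit, newdata = grid))
  }
  fitted <- fit_curve(loess_span)
  if (any(!is.finite(fitted))) {
    fitted <- fit_curve(1)
  }
  curve <- data.frame(x = grid, fitted = fitted)
  structure(
    list(
      dataset_id = dataset$dataset_id,
      genes = genes,
      loading = x,
      mean_expr = mean_expr,
      correlation = correlation,
      loess = curve,
      loess_span = loess_span,
      n_cells = if (is.matrix(X) || methods::is(X, "Matrix")) ncol(X) else 1L
    ),
    class = "loading_expression_profile"
  )
}

#' @export
print.loading_expression_profile <- function(x, ...) {
  cat(sprintf(
    "<loading_expression_profile> '%s': %d genes over %d cells, r=%.3f\n",
    x$dataset_id, length(x$genes), x$n_cells, x$correlation$estimate
  ))
  invisible(x)
}
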