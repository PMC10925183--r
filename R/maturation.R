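#' Build a maturation-space map
#'
#' Places every cell in a 2-D maturation space: x = raw embedding on the
#' maturation pattern, y = raw embedding on the nascent-neuron pattern,
#' colored by the min--max-scaled embedding of a chosen (typically
#' layer-specific) signature. Cells without a recorded age are excluded
#' with a message stating how many were dropped.
#'
#' @param p A `projection_result` containing all three patterns.
#' @param x_pattern Name of the pattern mapped to the x axis (neuron
#'   maturation).
#' @param y_pattern Name of the pattern mapped to the y axis (nascent
#'   neurons).
#' @param color_pattern Name of the signature providing the color scale.
#' @param meta Sample metadata data frame with `sample_id` and `age`
#'   (and optionally `cell_type`, `donor`).
#' @return Data frame of class `maturation_map` with columns
#'   `sample_id`, `x`, `y`, `color`, `age`, plus `cell_type`/`donor`
#'   when present in `meta`.
#' @export
build_maturation_map <- function(p, x_pattern, y_pattern, color_pattern,
                                 meta) {
  stopifnot(inherits(p, "projection_result"))
  for (pat in c(x_pattern, y_pattern, color_pattern)) {
    if (!pat %in% p$pattern_names) stop("missing pattern name: ", pat)
  }
  meta <- as.data.frame(meta)
  if (!all(c("sample_id", "age") %in% names(meta))) {
    stop("meta needs `sample_id` and `age` columns")
  }
  ids <- colnames(p$raw)
  idx <- match(ids, meta$sample_id)
  if (anyNA(idx)) stop("metadata is missing some projected samples")
  out <- data.frame(
    sample_id = ids,
    x = p$raw[x_pattern, ],
    y = p$raw[y_pattern, ],
    color = p$scaled[color_pattern, ],
    age = meta$age[idx],
    stringsAsFactors = FALSE
  )
  for (col in c("cell_type", "donor")) {
    if (col %in% names(meta)) out[[col]] <- meta[[col]][idx]
  }
  dropped <- sum(is.na(out$age))
  if (dropped > 0) {
    message(sprintf("%d cell(s) without age excluded from maturation map",
                    dropped))
    out <- out[!is.na(out$age), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "patterns") <- c(x = x_pattern, y = y_pattern,
                             color = color_pattern)
  class(out) <- c("maturation_map", "data.frame")
  out
}

#' Emergence age of a signature
#'
#' Ages are treated as ordered categorical bins (donors/timepoints). For
#' every age bin with at least `min_cells` cells, the signature is
#' summarized by its `summary_quantile` (default: the 90th percentile,
#' which captures emergence in a subpopulation of cells while resisting
#' single-cell outliers). The emergence age is the earliest eligible age
#' whose summary reaches `threshold` (default 65%) of the maximum
#' summary across eligible ages; if the maximum is 0 the signature never
#' emerges. The detection is invariant to positive rescaling of the
#' values and monotone in the threshold.
#'
#' @param values Per-cell signature values (e.g. scaled embeddings of
#'   one layer signature).
#' @param ages Per-cell ages (same length; `NA` ages are dropped).
#' @param threshold Fraction of the maximal level to surpass (default
#'   0.65).
#' @param summary_quantile Per-age summary quantile (default 0.90).
#' @param min_cells Minimum cells for an age bin to be eligible
#'   (default 20).
#' @param signature Name recorded in the result.
#' @return Object of class `emergence_result`: list with `signature`,
#'   `ages` (ordered eligible ages), `summaries`, `global_max`,
#'   `emergence_age` (`NA` when the signature never emerges), `params`.
#' @export
emergence_age <- function(values, ages, threshold = 0.65,
                          summary_quantile = 0.90, min_cells = 20L,
                          signature = "signature") {
  stopifnot(length(values) == length(ages))
  keep <- !is.na(ages) & is.finite(values)
  values <- values[keep]
  ages <- ages[keep]
  tab <- table(ages)
  eligible <- as.numeric(names(tab))[tab >= min_cells]
  if (!length(eligible)) {
    stop(sprintf("no age bin with at least %d cells", min_cells))
  }
  eligible <- sort(eligible)
  summaries <- vapply(eligible, function(a) {
    stats::quantile(values[ages == a], probs = summary_quantile, names = FALSE)
  }, numeric(1))
  gmax <- max(summaries)
  emergence <- NA_real_
  if (gmax > 0) {
    hit <- which(summaries >= threshold * gmax)
    emergence <- eligible[hit[1]]
  }
  structure(
    list(
      signature = signature,
      ages = eligible,
      summaries = summaries,
      global_max = gmax,
      emergence_age = emergence,
      params = list(threshold = threshold,
                    summary_quantile = summary_quantile,
                    min_cells = min_cells)
    ),
    class = "emergence_result"
  )
}

#' @export
print.emergence_result <- function(x, ...) {
  cat(sprintf(
    "<emergence_result> '%s': emergence at %s (max %.4g over %d age bins)\n",
    x$signature,
    if (is.na(x$emergence_age)) "none" else format(x$emergence_age),
    x$global_max, length(x$ages)
  ))
  invisible(x)
}

#' Emergence ages for several signatures, in developmental order
#'
#' Runs [emergence_age] on every row of a signatures x cells value
#' matrix and returns one row per signature, sorted by emergence age
#' (signatures that never emerge last), ties broken by signature name.
#' On lifespan data this ordering recovers the inside-out (deep-to-upper
#' layer) sequence of laminar identity emergence.
#'
#' @param values Signatures x cells numeric matrix with signature row
#'   names (e.g. the `scaled` matrix of a projection restricted to
#'   layer signatures).
#' @param ages Per-cell ages (length = `ncol(values)`).
#' @inheritParams emergence_age
#' @return Data frame with columns `signature`, `emergence_age`,
#'   `global_max`, `n_ages`, sorted as described; attribute `"results"`
#'   holds the per-signature `emergence_result` objects.
#' @export
ordered_emergence <- function(values, ages, threshold = 0.65,
                              summary_quantile = 0.90, min_cells = 20L) {
  values <- as.matrix(values)
  stopifnot(!is.null(rownames(values)), ncol(values) == length(ages))
  results <- lapply(rownames(values), function(sig) {
    emergence_age(values[sig, ], ages, threshold = threshold,
                  summary_quantile = summary_quantile,
                  min_cells = min_cells, signature = sig)
  })
  names(results) <- rownames(values)
  out <- data.frame(
    signature = rownames(values),
    emergence_age = vapply(results, `[[`, numeric(1), "emergence_age"),
    global_max = vapply(results, `[[`, numeric(1), "global_max"),
    n_ages = vapply(results, function(r) length(r$ages), integer(1)),
    stringsAsFactors = FALSE
  )
  ord <- order(is.na(out$emergence_age), out$emergence_age, out$signature)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
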