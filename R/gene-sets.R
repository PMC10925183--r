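#' Construct a gene-set collection
#'
#' A named list of uppercase gene symbols, optionally with per-gene
#' weights (e.g. loadings exported as a weighted signature).
#'
#' @param sets Named list of character vectors (member symbols).
#' @param weights Optional named list, parallel to `sets`, each element a
#'   numeric vector named by gene symbol.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, weights = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)), all(nzchar(names(sets))))
  dup <- unique(names(sets)[duplicated(names(sets))])
  if (length(dup)) stop("duplicate set names: ", paste(dup, collapse = ", "))
  sets <- lapply(sets, function(g) unique(toupper(as.character(g))))
  if (any(lengths(sets) == 0)) {
    stop("empty member lists: ",
         paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  if (!is.null(weights)) {
    stopifnot(identical(names(weights), names(sets)))
    weights <- Map(function(w, g) {
      names(w) <- toupper(names(w))
      w[g]
    }, weights, sets)
  }
  structure(list(sets = sets, weights = weights),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d set(s)%s\n", length(x$sets),
              if (is.null(x$weights)) "" else " (weighted)"))
  show <- utils::head(names(x$sets), 5)
  for (nm in show) cat(sprintf("  %s: %d genes\n", nm, length(x$sets[[nm]])))
  if (length(x$sets) > 5) cat("  ...\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets from a GMT file
#'
#' Standard GMT dialect: tab-separated lines of
#' `name<TAB>description<TAB>member1<TAB>member2...`. Lines with fewer
#' than three fields, duplicate set names, or no members are rejected.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop(sprintf("GMT parse error: line %d has fewer than 3 fields",
                 short[1]))
  }
  nm <- vapply(parts, `[[`, character(1), 1L)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) stop("duplicate set names: ", paste(dup, collapse = ", "))
  sets <- lapply(parts, function(p) {
    members <- p[-(1:2)]
    members[nzchar(members)]
  })
  names(sets) <- nm
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty)) {
    stop("empty member lists: ", paste(empty, collapse = ", "))
  }
  gene_set_collection(sets)
}

#' Write a gene-set collection to a GMT file
#' @param collection A [gene_set_collection].
#' @param path Output file.
#' @param descriptions Optional character vector of per-set descriptions
#'   (defaults to `"na"`).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (is.null(descriptions)) {
    descriptions <- rep("na", length(collection$sets))
  }
  lines <- mapply(function(nm, desc, genes) {
    paste(c(nm, desc, genes), collapse = "\t")
  }, names(collection$sets), descriptions, collection$sets)
  writeLines(unname(lines), path)
  invisible(path)
}

#' Read an ortholog map TSV
#'
#' Expected columns: `species`, `source_symbol`, `reference_symbol`
#' (header required). Symbols are uppercased. Within each species,
#' entries that are not one-to-one (a source symbol mapping to several
#' reference symbols, or a reference symbol claimed by several source
#' symbols) are dropped, so that shared loadings never double-count a
#' gene.
#'
#' @param path TSV path.
#' @return A data frame of class `ortholog_map` with the three columns,
#'   already filtered to one-to-one pairs per species.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("species", "source_symbol", "reference_symbol")
  if (!all(need %in% names(df))) {
    stop("ortholog map must have columns: ", paste(need, collapse = ", "))
  }
  ortholog_map(df)
}

#' Build an ortholog map from a data frame
#' @param pairs Data frame with columns `species`, `source_symbol`,
#'   `reference_symbol`.
#' @return Filtered one-to-one `ortholog_map` data frame.
#' @export
ortholog_map <- function(pairs) {
  pairs <- as.data.frame(pairs)[, c("species", "source_symbol",
                                    "reference_symbol")]
  pairs$source_symbol <- toupper(pairs$source_symbol)
  pairs$reference_symbol <- toupper(pairs$reference_symbol)
  pairs <- unique(pairs)
  keep <- unlist(lapply(split(seq_len(nrow(pairs)), pairs$species),
                        function(idx) {
    sub <- pairs[idx, ]
    ok_src <- !(sub$source_symbol %in%
                  sub$source_symbol[duplicated(sub$source_symbol)])
    ok_ref <- !(sub$reference_symbol %in%
                  sub$reference_symbol[duplicated(sub$reference_symbol)])
    idx[ok_src & ok_ref]
  }))
  out <- pairs[sort(unname(keep)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ortholog_map", "data.frame")
  out
}

#' Harmonize several datasets onto one common gene space
#'
#' Maps each dataset's gene symbols to a shared reference symbol space
#' (via a one-to-one ortholog map when species differ), intersects the
#' mapped gene lists, and reorders every matrix onto the identical
#' ordered gene list (order of appearance in the first dataset). This is
#' the required preprocessing before a joint factorization, which assumes
#' a single row space shared by all input matrices.
#'
#' @param datasets List of [expression_dataset] objects.
#' @param map Optional `ortholog_map`. Datasets whose species has entries
#'   in the map get their symbols translated to reference symbols
#'   (unmapped genes are dropped); other datasets are taken to be in the
#'   reference space already.
#' @return List of datasets, all with the identical ordered gene list.
#' @export
harmonize_genes <- function(datasets, map = NULL) {
  stopifnot(length(datasets) >= 1)
  lapply(datasets, function(d) stopifnot(inherits(d, "expression_dataset")))
  mapped <- lapply(datasets, function(d) {
    g <- d$genes
    if (!is.null(map)) {
      sp <- dataset_species(d)
      if (!is.na(sp) && sp %in% map$species) {
        sub <- map[map$species == sp, ]
        ref <- sub$reference_symbol[match(g, sub$source_symbol)]
        return(ref)  # NA where unmapped
      }
    }
    g
  })
  common <- mapped[[1]][!is.na(mapped[[1]])]
  for (i in seq_along(mapped)[-1]) {
    common <- common[common %in% mapped[[i]]]
  }
  if (!length(common)) {
    sizes <- vapply(mapped, function(g) {
      sum(!is.na(g) & g %in% mapped[[1]])
    }, integer(1))
    stop("empty gene intersection across datasets (overlap with first: ",
         paste(sprintf("%s=%d",
                       vapply(datasets, `[[`, character(1), "dataset_id"),
                       sizes), collapse = ", "), ")")
  }
  Map(function(d, g) {
    idx <- match(common, g)
    out <- d
    out$genes <- common
    out$matrix <- d$matrix[idx, , drop = FALSE]
    dimnames(out$matrix) <- list(common, d$sample_meta$sample_id)
    out
  }, datasets, mapped)
}
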