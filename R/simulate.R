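#' Simulate a multi-dataset expression collection with known truth
#'
#' Generates `n_datasets` nonnegative count matrices from one shared
#' sparse gene-loading matrix `W_true` (per-column ~`w_sparsity` support,
#' exponential magnitudes, unit-normalized columns) and per-dataset
#' embedding matrices `H_true` whose rows follow smooth type- and
#' age-dependent activity curves: progenitor-like patterns decline with
#' age, neuronal-like patterns rise logistically after their onset age,
#' and each pattern is boosted in its preferred cell type. Counts are
#' drawn from the chosen noise model with mean
#' `s_c * (W_true %*% H_true)` for per-cell size factors `s_c`
#' (lognormal, scaled so the average cell has `mean_depth` counts).
#'
#' Two optional layers of structure back specific analyses: a
#' species-masked pattern (active in only `masked_active_frac` of cells
#' in the masked datasets versus `unmasked_active_frac` elsewhere,
#' emulating a primate-expanded program such as the oRG signature that is
#' nearly absent from mouse radial glia), and per-type marker genes whose
#' mean expression is multiplied by `marker_fold` in cells of their own
#' type (the planted-marker benchmark for consensus labeling;
#' `marker_fold = 1`, the default, leaves the factor model exact).
#'
#' All draws are reproducible from `seed`.
#'
#' @param n_datasets Number of datasets ("species") to generate.
#' @param n_genes Genes in the shared space.
#' @param n_cells Cells per dataset (recycled to `n_datasets`).
#' @param k Number of shared patterns.
#' @param n_cell_types Number of cell types.
#' @param age_bins Number of ordered age bins (ages are 1..age_bins).
#' @param noise `"nb"` (negative binomial, default), `"poisson"`, or
#'   `"none"` (the matrix is exactly the scaled mean).
#' @param nb_dispersion NB dispersion (variance = mu + dispersion*mu^2;
#'   default 0.5).
#' @param w_sparsity Fraction of genes in each pattern's support
#'   (default 0.10).
#' @param activity_scale Overall magnitude of pattern activities.
#' @param type_boost Multiplicative boost of a pattern in its preferred
#'   cell type (default 3).
#' @param logistic_slope Slope of the age activity curves (default 1).
#' @param masked_pattern Index of the species-masked pattern (`NULL`,
#'   the default, plants none).
#' @param masked_datasets Indices of datasets in which the masked
#'   pattern is nearly silent (default 1).
#' @param masked_active_frac Fraction of active cells for the masked
#'   pattern in masked datasets (default 0.02).
#' @param unmasked_active_frac Same, in the remaining datasets
#'   (default 0.20).
#' @param marker_genes_per_type Marker genes reserved per cell type
#'   (default 20).
#' @param marker_fold Fold-change bump applied to marker genes in cells
#'   of their own type (default 1 = off).
#' @param mean_depth Average total counts per cell (default 2500).
#' @param size_factor_sd Log-scale SD of the per-cell size factors
#'   (default 0.2, moderate depth variability).
#' @param onset_ages Optional numeric vector of onset ages for the
#'   neuronal patterns (recycled); by default spread over the age range.
#' @param gene_dropout_frac Fraction of genes randomly absent from each
#'   dataset after the first (default 0), to exercise gene-space
#'   harmonization.
#' @param species_prefix If `TRUE`, datasets after the first use
#'   species-prefixed gene symbols and the truth carries an ortholog map
#'   back to the shared space.
#' @param seed Integer RNG seed.
#' @return List with `datasets` (list of [expression_dataset]) and
#'   `truth` (class `synthetic_truth`): `W_true` (unit-norm columns),
#'   `H_true`, `labels`, `ages`, `marker_sets`, `planted_sets` (top-50
#'   loading genes per pattern), `onset_ages`, `pattern_roles`,
#'   `active_frac` (patterns x datasets), `size_factors`, `species`,
#'   `noise`, `seed`, and `ortholog_map` when `species_prefix = TRUE`.
#' @export
simulate_collection <- function(n_datasets = 3L, n_genes = 2000L,
                                n_cells = 500L, k = 7L, n_cell_types = 4L,
                                age_bins = 8L,
                                noise = c("nb", "poisson", "none"),
                                nb_dispersion = 0.5, w_sparsity = 0.10,
                                activity_scale = 3, type_boost = 3,
                                logistic_slope = 1,
                                masked_pattern = NULL,
                                masked_datasets = 1L,
                                masked_active_frac = 0.02,
                                unmasked_active_frac = 0.20,
                                marker_genes_per_type = 20L,
                                marker_fold = 1,
                                mean_depth = 2500,
                                size_factor_sd = 0.2,
                                onset_ages = NULL,
                                gene_dropout_frac = 0,
                                species_prefix = FALSE,
                                seed = 1L) {
  noise <- match.arg(noise)
  if (k > n_genes) stop("k must not exceed n_genes")
  n_cells <- rep_len(as.integer(n_cells), n_datasets)
  if (any(n_cells < n_cell_types)) {
    stop("each dataset needs at least as many cells as cell types")
  }
  if (n_cell_types * marker_genes_per_type > n_genes) {
    stop("not enough genes to reserve the requested marker sets")
  }
  set.seed(as.integer(seed))
  genes <- sprintf("G%06d", seq_len(n_genes))
  species <- sprintf("species%d", seq_len(n_datasets))
  dataset_ids <- sprintf("ds%d", seq_len(n_datasets))
  pattern_names <- default_pattern_names(k)

  ## shared sparse loadings, unit-norm columns
  support_size <- max(2L, ceiling(w_sparsity * n_genes))
  W <- matrix(0, n_genes, k, dimnames = list(genes, pattern_names))
  for (p in seq_len(k)) {
    sup <- sample.int(n_genes, support_size)
    W[sup, p] <- stats::rexp(support_size)
    W[, p] <- W[, p] / sqrt(sum(W[, p]^2))
  }

  ## pattern roles, onsets, preferred types
  roles <- rep(c("progenitor", "neuronal"), length.out = k)
  if (!is.null(masked_pattern)) {
    stopifnot(masked_pattern >= 1, masked_pattern <= k)
    roles[masked_pattern] <- "masked"
  }
  ## onsets/midpoints stay in the middle half of the age window so every
  ## planted program has substantial activity (and hence energy) within
  ## the sampled ages -- a boundary placement leaves a program near-silent
  ## and makes it unrecoverable by construction
  neuronal <- which(roles == "neuronal")
  onsets <- rep(NA_real_, k)
  if (length(neuronal)) {
    if (is.null(onset_ages)) {
      onset_ages <- seq(0.25 * age_bins, 0.75 * age_bins,
                        length.out = length(neuronal))
    }
    onsets[neuronal] <- rep_len(onset_ages, length(neuronal))
  }
  midpoints <- rep(NA_real_, k)
  progenitor <- which(roles == "progenitor")
  if (length(progenitor)) {
    midpoints[progenitor] <- rep_len(
      seq(0.375 * age_bins, 0.875 * age_bins,
          length.out = length(progenitor)),
      length(progenitor))
  }
  ## preferred types cycle within each role group, so two programs with
  ## the same age dynamics never share a cell type unless types run out --
  ## otherwise their planted activities are nearly collinear
  pref_type <- integer(k)
  pref_type[progenitor] <- rep_len(seq_len(n_cell_types), length(progenitor))
  pref_type[neuronal] <- rep_len(seq_len(n_cell_types), length(neuronal))
  if (any(roles == "masked")) {
    pref_type[roles == "masked"] <- 1L
  }

  ## disjoint marker sets, drawn from well-expressed genes (top third by
  ## aggregate loading): robust cell-type markers are by definition genes
  ## with solid baseline expression, and a fold bump on a near-silent
  ## gene would carry no signal
  need <- n_cell_types * marker_genes_per_type
  ranked <- order(-rowSums(W))
  pool <- ranked[seq_len(max(ceiling(n_genes / 3), need))]
  marker_idx <- sample(pool, need)
  marker_sets <- split(genes[marker_idx],
                       rep(seq_len(n_cell_types), each = marker_genes_per_type))
  names(marker_sets) <- sprintf("type%d", seq_len(n_cell_types))

  active_frac <- matrix(1, k, n_datasets,
                        dimnames = list(pattern_names, dataset_ids))
  datasets <- vector("list", n_datasets)
  H_list <- vector("list", n_datasets)
  labels <- vector("list", n_datasets)
  ages_list <- vector("list", n_datasets)
  sf_list <- vector("list", n_datasets)
  map_rows <- list()

  for (d in seq_len(n_datasets)) {
    n <- n_cells[d]
    type <- sample.int(n_cell_types, n, replace = TRUE)
    age <- sample.int(age_bins, n, replace = TRUE)
    H <- matrix(0, k, n)
    for (p in seq_len(k)) {
      if (roles[p] == "masked") {
        frac <- if (d %in% masked_datasets) masked_active_frac else unmasked_active_frac
        active_frac[p, d] <- frac
        ## the masked program defines the identity of its active cells
        ## (an oRG-like state), so it dominates their activity budget
        on <- stats::runif(n) < frac
        H[p, ] <- ifelse(on, stats::runif(n, 8, 12), 0.02)
      } else {
        base <- if (roles[p] == "progenitor") {
          stats::plogis(logistic_slope * (midpoints[p] - age))
        } else {
          stats::plogis(logistic_slope * (age - onsets[p]))
        }
        mult <- 1 + type_boost * (type == pref_type[p])
        cell_noise <- stats::rgamma(n, shape = 2, rate = 2)
        H[p, ] <- activity_scale * (0.05 + base) * mult * cell_noise
      }
    }
    mu <- W %*% H
    if (marker_fold != 1) {
      for (t in seq_len(n_cell_types)) {
        rows <- match(marker_sets[[t]], genes)
        cols <- which(type == t)
        if (length(cols)) {
          mu[rows, cols] <- mu[rows, cols] * marker_fold
        }
      }
    }
    s <- stats::rlnorm(n, meanlog = 0, sdlog = size_factor_sd)
    s <- s * mean_depth / mean(colSums(mu) * s)
    mu <- sweep(mu, 2, s, `*`)
    counts <- switch(noise,
      nb = matrix(stats::rnbinom(length(mu), mu = as.numeric(mu),
                                 size = 1 / nb_dispersion), nrow(mu)),
      poisson = matrix(stats::rpois(length(mu), as.numeric(mu)), nrow(mu)),
      none = mu
    )
    ds_genes <- genes
    keep_genes <- seq_len(n_genes)
    if (d > 1 && gene_dropout_frac > 0) {
      drop <- sample.int(n_genes, floor(gene_dropout_frac * n_genes))
      keep_genes <- setdiff(seq_len(n_genes), drop)
    }
    if (d > 1 && species_prefix) {
      ds_genes <- paste0(toupper(species[d]), "_", genes)
      map_rows[[length(map_rows) + 1L]] <- data.frame(
        species = species[d],
        source_symbol = ds_genes[keep_genes],
        reference_symbol = genes[keep_genes],
        stringsAsFactors = FALSE
      )
    }
    meta <- data.frame(
      sample_id = sprintf("%s_C%04d", dataset_ids[d], seq_len(n)),
      cell_type = sprintf("type%d", type),
      age = as.numeric(age),
      species = species[d],
      stringsAsFactors = FALSE
    )
    counts_d <- counts[keep_genes, , drop = FALSE]
    datasets[[d]] <- expression_dataset(
      Matrix::Matrix(counts_d, sparse = TRUE),
      ds_genes[keep_genes], meta, dataset_ids[d], age_unit = "bin"
    )
    colnames(H) <- meta$sample_id
    rownames(H) <- pattern_names
    H_list[[d]] <- H
    labels[[d]] <- stats::setNames(meta$cell_type, meta$sample_id)
    ages_list[[d]] <- stats::setNames(meta$age, meta$sample_id)
    sf_list[[d]] <- stats::setNames(s, meta$sample_id)
  }
  names(datasets) <- dataset_ids
  names(H_list) <- dataset_ids
  names(labels) <- dataset_ids
  names(ages_list) <- dataset_ids
  names(sf_list) <- dataset_ids

  planted_sets <- lapply(seq_len(k), function(p) {
    genes[order(-W[, p], genes)][1:50]
  })
  names(planted_sets) <- pattern_names

  truth <- structure(
    list(
      W_true = W,
      H_true = H_list,
      labels = labels,
      ages = ages_list,
      marker_sets = gene_set_collection(marker_sets),
      planted_sets = gene_set_collection(planted_sets),
      onset_ages = stats::setNames(onsets, pattern_names),
      pattern_roles = stats::setNames(roles, pattern_names),
      active_frac = active_frac,
      size_factors = sf_list,
      species = stats::setNames(species, dataset_ids),
      noise = list(model = noise,
                   dispersion = if (noise == "nb") nb_dispersion else NA_real_),
      seed = as.integer(seed),
      ortholog_map = if (length(map_rows)) {
        ortholog_map(do.call(rbind, map_rows))
      } else NULL
    ),
    class = "synthetic_truth"
  )
  list(datasets = datasets, truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(
    "<synthetic_truth> %d genes x %d patterns, %d dataset(s), noise=%s\n",
    nrow(x$W_true), ncol(x$W_true), length(x$H_true), x$noise$model
  ))
  invisible(x)
}

#' Species-masked ("oRG-style") collection
#'
#' [simulate_collection] preset in which the last pattern is active in
#' only a small fraction of cells of the first dataset (the mouse-like
#' species) but in a substantial fraction elsewhere, mirroring the
#' primate-expanded outer-radial-glia program.
#'
#' @inheritParams simulate_collection
#' @param ... Further arguments passed to [simulate_collection].
#' @return As [simulate_collection].
#' @export
simulate_org_collection <- function(n_datasets = 3L, k = 7L, seed = 1L, ...) {
  simulate_collection(n_datasets = n_datasets, k = k,
                      masked_pattern = k, masked_datasets = 1L,
                      seed = seed, ...)
}

#' Planted-marker benchmark collection
#'
#' [simulate_collection] preset for the consensus-labeling benchmark:
#' each cell type overexpresses its own 20 marker genes 4-fold under
#' negative-binomial noise.
#'
#' @inheritParams simulate_collection
#' @param ... Further arguments passed to [simulate_collection].
#' @return As [simulate_collection].
#' @export
simulate_marker_benchmark <- function(n_datasets = 1L, n_cells = 1000L,
                                      marker_fold = 4, seed = 1L, ...) {
  simulate_collection(n_datasets = n_datasets, n_cells = n_cells,
                      marker_fold = marker_fold, seed = seed, ...)
}

#' Simulate a lifespan cohort with planted signature onset ages
#'
#' Cells are spread over ordered age bins; each of `n_signatures`
#' laminar-style signatures activates logistically at its planted onset
#' age. Per-cell signature values are negative-binomial counts around
#' `amplitude * plogis(slope * (age - onset))`, min--max scaled per
#' signature (`noise = "none"` returns the scaled logistic means
#' exactly). Signatures are named in onset order (`sig01...`), with one
#' precocious upper-layer signature planted out of laminar order, the
#' way a layer-3/4 identity emerges before its neighbors.
#'
#' The planted truth `emergence_true` is computed from the generating
#' curve alone, on the same min--max scale the analysis sees: the
#' earliest age bin whose scaled mean reaches `threshold` of the maximal
#' scaled mean over the sampled bins.
#'
#' @param n_signatures Number of signatures (default 9).
#' @param age_bins Number of ordered age bins (default 8).
#' @param cells_per_age Cells per age bin (default 100).
#' @param onsets Planted onset ages (defaults to a deep-to-upper
#'   sequence with `sig03` precocious).
#' @param slope Logistic slope (default 4).
#' @param amplitude Mean count at full activation (default 20).
#' @param noise `"nb"` (default) or `"none"`.
#' @param nb_dispersion NB dispersion (default 0.5).
#' @param threshold Fraction of maximum used for the planted truth
#'   (default 0.65).
#' @param seed Integer RNG seed.
#' @return List with `values` (signatures x cells, min--max scaled),
#'   `ages` (per cell), `onsets`, `emergence_true`, `layers`.
#' @export
simulate_emergence_cohort <- function(n_signatures = 9L, age_bins = 8L,
                                      cells_per_age = 100L, onsets = NULL,
                                      slope = 4, amplitude = 20,
                                      noise = c("nb", "none"),
                                      nb_dispersion = 0.5, threshold = 0.65,
                                      seed = 1L) {
  noise <- match.arg(noise)
  layers <- c("SP_L6B", "L6", "L34_PRECOCIOUS", "L6A", "L5", "L45", "L4",
              "L23", "L2")
  if (is.null(onsets)) {
    onsets <- c(0.5, 1.5, 1.8, 2.5, 3.5, 4.5, 5.5, 6.5, 7.5)
  }
  onsets <- rep_len(onsets, n_signatures)
  layers <- rep_len(layers, n_signatures)
  ord <- order(onsets)
  onsets <- onsets[ord]
  layers <- layers[ord]
  sig_names <- sprintf("sig%02d_%s", seq_len(n_signatures), layers)
  set.seed(as.integer(seed))
  ages <- rep(seq_len(age_bins), each = cells_per_age)
  n <- length(ages)
  values <- matrix(0, n_signatures, n,
                   dimnames = list(sig_names, sprintf("C%05d", seq_len(n))))
  emergence_true <- numeric(n_signatures)
  for (s in seq_len(n_signatures)) {
    mu_age <- stats::plogis(slope * (seq_len(age_bins) - onsets[s]))
    scaled_mu <- (mu_age - min(mu_age)) / (max(mu_age) - min(mu_age))
    emergence_true[s] <- seq_len(age_bins)[
      which(scaled_mu >= threshold * max(scaled_mu))[1]]
    mu <- amplitude * mu_age[ages]
    values[s, ] <- if (noise == "nb") {
      stats::rnbinom(n, mu = mu, size = 1 / nb_dispersion)
    } else {
      mu
    }
  }
  values <- minmax_scale(values)
  list(
    values = values,
    ages = ages,
    onsets = stats::setNames(onsets, sig_names),
    emergence_true = stats::setNames(emergence_true, sig_names),
    layers = stats::setNames(layers, sig_names)
  )
}

#' Match estimated patterns to true patterns
#'
#' NMF patterns come back in arbitrary order; this finds the one-to-one
#' assignment between estimated and true loading columns that maximizes
#' total cosine similarity (Hungarian algorithm) and reports the matched
#' cosines in true-pattern order.
#'
#' @param W_est Estimated loading matrix (genes x k).
#' @param W_true True loading matrix (same genes, same k).
#' @return List with `permutation` (for each true pattern, the matched
#'   estimated column index), `cosines` (named by true pattern), and
#'   `mean_cosine`.
#' @export
match_factors <- function(W_est, W_true) {
  W_est <- as.matrix(W_est)
  W_true <- as.matrix(W_true)
  if (ncol(W_est) != ncol(W_true)) {
    stop(sprintf("pattern count mismatch: %d vs %d",
                 ncol(W_est), ncol(W_true)))
  }
  if (nrow(W_est) != nrow(W_true)) {
    stop("gene spaces differ between the loading matrices")
  }
  unit <- function(M) {
    nrm <- sqrt(colSums(M^2))
    sweep(M, 2, ifelse(nrm == 0, 1, nrm), `/`)
  }
  C <- crossprod(unit(W_est), unit(W_true))  # est x true
  assignment <- hungarian_assign(t(-C))      # rows = true, cols = est
  cosines <- C[cbind(assignment, seq_len(ncol(W_true)))]
  names(cosines) <- colnames(W_true) %||%
    sprintf("p%d", seq_len(ncol(W_true)))
  list(permutation = assignment, cosines = cosines,
       mean_cosine = mean(cosines))
}
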