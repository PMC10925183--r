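test_that("MatrixMarket round trip preserves the matrix and metadata exactly", {
  d <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_expression(d, dir)
  d2 <- read_expression_dir(dir, dataset_id = "tiny")
  expect_equal(as.matrix(d2$matrix), as.matrix(d$matrix))
  expect_identical(d2$genes, d$genes)
  expect_equal(d2$sample_meta, d$sample_meta)
  # exactly the three hand-placed nonzeros survive
  expect_equal(sum(d2$matrix != 0), 3)

  # seeded random sparse matrix round-trips entrywise
  r <- random_dataset(42)
  dir2 <- withr::local_tempdir()
  write_expression(r, dir2)
  r2 <- read_expression_dir(dir2, dataset_id = "rand")
  expect_equal(as.matrix(r2$matrix), as.matrix(r$matrix))
  expect_equal(r2$sample_meta, r$sample_meta)
})

test_that("malformed expression inputs are rejected with informative errors", {
  d <- tiny_dataset()
  dir <- withr::local_tempdir()
  write_expression(d, dir)
  # genes file shorter than the declared matrix rows
  writeLines(c("GA", "GB"), file.path(dir, "genes.tsv"))
  expect_error(read_expression_dir(dir), "dimension mismatch.*2.*3")
  writeLines(c("GA", "GB", "GA"), file.path(dir, "genes.tsv"))
  expect_error(read_expression_dir(dir), "duplicate gene symbols: GA")

  expect_error(
    expression_dataset(matrix(-1, 1, 1), "G1",
                       data.frame(sample_id = "s1"), "x"),
    "nonnegative"
  )
  expect_error(
    expression_dataset(matrix(NA_real_, 1, 1), "G1",
                       data.frame(sample_id = "s1"), "x"),
    "finite"
  )
  expect_error(
    expression_dataset(matrix(1, 2, 2), c("G1", "G2"),
                       data.frame(sample_id = "s1"), "x"),
    "dimension mismatch"
  )
})

test_that("GMT parsing enforces the dialect and round-trips", {
  path <- withr::local_tempfile()
  writeLines("S_PHASE\tdesc\tMCM2\tPCNA", path)
  gs <- read_gmt(path)
  expect_identical(gs$sets, list(S_PHASE = c("MCM2", "PCNA")))

  writeLines(c("A\td\tG1", "A\td\tG2"), path)
  expect_error(read_gmt(path), "duplicate set names: A")

  writeLines(c("A\td\tG1", "B\tonly-two-fields"), path)
  expect_error(read_gmt(path), "line 2 has fewer than 3 fields")

  # 50-set collection written by the package reparses identically
  set.seed(9)
  sets <- lapply(1:50, function(i) {
    sprintf("G%04d", sample(5000, sample(3:30, 1)))
  })
  names(sets) <- sprintf("SET%02d", 1:50)
  gs <- gene_set_collection(sets)
  write_gmt(gs, path)
  gs2 <- read_gmt(path)
  expect_identical(gs2$sets, gs$sets)
})

test_that("cp10k_log normalization matches hand arithmetic and handles degeneracies", {
  m <- matrix(c(1, 3, 0, 0), nrow = 2)
  d <- expression_dataset(m, c("G1", "G2"),
                          data.frame(sample_id = c("a", "b")), "x")
  expect_warning(nd <- normalize_expression(d), "all-zero")
  expect_equal(as.numeric(nd$matrix[, 1]),
               log1p(c(2500, 7500)), tolerance = 1e-12)
  expect_equal(as.numeric(nd$matrix[, 1]), c(7.8244, 8.9227),
               tolerance = 1e-4)
  expect_equal(as.numeric(nd$matrix[, 2]), c(0, 0))

  # mode none is the identity
  expect_identical(normalize_expression(d, "none")$matrix, d$matrix)

  # a single-nonzero column always maps to log1p(1e4), whatever the count
  for (v in c(1, 7, 3000)) {
    d1 <- expression_dataset(matrix(c(v, 0), 2), c("G1", "G2"),
                             data.frame(sample_id = "a"), "x")
    expect_equal(sum(normalize_expression(d1)$matrix), log1p(1e4))
  }

  # sparse and dense paths agree
  ds <- expression_dataset(Matrix::Matrix(m[, 1, drop = FALSE], sparse = TRUE),
                           c("G1", "G2"), data.frame(sample_id = "a"), "x")
  expect_equal(as.matrix(normalize_expression(ds)$matrix),
               suppressWarnings(
                 as.matrix(normalize_expression(d)$matrix[, 1, drop = FALSE])))
})

test_that("harmonize_genes intersects, maps orthologs one-to-one, and is idempotent", {
  mk <- function(genes, id, species = "human") {
    expression_dataset(
      matrix(seq_along(genes), ncol = 1), genes,
      data.frame(sample_id = paste0(id, "_s1"), species = species), id
    )
  }
  d1 <- mk(c("A", "B", "C"), "d1")
  d2 <- mk(c("B", "C", "D"), "d2")
  h <- harmonize_genes(list(d1, d2))
  expect_identical(h[[1]]$genes, c("B", "C"))
  expect_identical(h[[2]]$genes, c("B", "C"))
  expect_equal(as.numeric(h[[1]]$matrix), c(2, 3))
  expect_equal(as.numeric(h[[2]]$matrix), c(1, 2))

  # idempotence
  h2 <- harmonize_genes(h)
  expect_identical(h2[[1]]$genes, h[[1]]$genes)
  expect_equal(as.matrix(h2[[2]]$matrix), as.matrix(h[[2]]$matrix))

  # mouse symbol mapped through the ortholog table survives intersection
  dm <- mk(c("HOPX_MOUSE", "XX1"), "dm", species = "mouse")
  dh <- mk(c("HOPX", "OTHER"), "dh")
  map <- ortholog_map(data.frame(
    species = "mouse",
    source_symbol = c("HOPX_MOUSE", "XX1"),
    reference_symbol = c("HOPX", "ZZZ")
  ))
  hm <- harmonize_genes(list(dh, dm), map)
  expect_identical(hm[[1]]$genes, "HOPX")
  expect_identical(hm[[2]]$genes, "HOPX")

  # ambiguous X->Y and X->Z entries are dropped entirely
  amb <- ortholog_map(data.frame(
    species = "mouse",
    source_symbol = c("X", "X", "W"),
    reference_symbol = c("Y", "Z", "HOPX")
  ))
  expect_false("X" %in% amb$source_symbol)
  expect_true("W" %in% amb$source_symbol)

  expect_error(harmonize_genes(list(mk("A", "a"), mk("B", "b"))),
               "empty gene intersection")
})

test_that("species-prefixed synthetic symbols harmonize back to the shared space", {
  sim <- simulate_collection(n_datasets = 2, n_genes = 120, n_cells = 40,
                             k = 3, species_prefix = TRUE,
                             gene_dropout_frac = 0.1, seed = 3)
  expect_false(identical(sim$datasets[[1]]$genes, sim$datasets[[2]]$genes))
  h <- harmonize_genes(sim$datasets, sim$truth$ortholog_map)
  expect_identical(h[[1]]$genes, h[[2]]$genes)
  expect_true(all(h[[1]]$genes %in% rownames(sim$truth$W_true)))
  expect_gt(length(h[[1]]$genes), 100)
})
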