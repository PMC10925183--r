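test_that("rank-sum enrichment equals closed forms and enumeration oracles", {
  # members occupying the top 3 ranks of a 10-gene universe: p = 1/C(10,3)
  loadings <- stats::setNames(c(10:1), sprintf("G%02d", 1:10))
  sets <- gene_set_collection(list(TOP = c("G01", "G02", "G03")))
  r <- loading_ranksum_enrichment(loadings, sets)
  expect_equal(r$p_value, 1 / choose(10, 3), tolerance = 1e-12)

  # exhaustive-placement oracle on random small instances
  set.seed(41)
  for (i in 1:10) {
    n <- sample(8:12, 1)
    m <- sample(2:4, 1)
    l <- stats::setNames(rexp(n), sprintf("G%02d", seq_len(n)))
    memb <- sample(names(l), m)
    p_pkg <- loading_ranksum_enrichment(
      l, gene_set_collection(list(S = memb)))$p_value
    expect_equal(p_pkg, enum_ranksum_p(l, memb), tolerance = 1e-3)
  }

  # degenerate sets are skipped with a warning
  expect_warning(
    expect_error(
      loading_ranksum_enrichment(loadings,
                                 gene_set_collection(list(ALL = names(loadings)))),
      "no testable"
    ),
    "equal to"
  )
})

test_that("top-fraction hypergeometric test matches combinatoric arithmetic", {
  loadings <- stats::setNames(10:1, sprintf("G%02d", 1:10))
  top5 <- sprintf("G%02d", 1:5)
  r <- loading_topfraction_hypergeom(
    loadings, gene_set_collection(list(S = top5)), top_fraction = 0.5)
  expect_equal(r$p_value, 1 / choose(10, 5), tolerance = 1e-15)
  expect_equal(r$statistic, 5)

  # zero overlap means p = 1
  r0 <- loading_topfraction_hypergeom(
    loadings, gene_set_collection(list(S = sprintf("G%02d", 6:10))),
    top_fraction = 0.5)
  expect_equal(r0$p_value, 1)

  # random 200-gene instances against the explicit binomial-sum tail
  set.seed(43)
  univ <- sprintf("G%03d", 1:200)
  for (i in 1:10) {
    l <- stats::setNames(rnorm(200), univ)
    memb <- sample(univ, 30)
    r <- loading_topfraction_hypergeom(
      l, gene_set_collection(list(S = memb)), top_fraction = 0.1)
    k_top <- 20
    top <- univ[order(-l, univ)][1:k_top]
    x <- sum(memb %in% top)
    expect_equal(r$p_value, enum_hyper_tail(x, 30, 200, k_top),
                 tolerance = 1e-12)
  }

  expect_error(loading_topfraction_hypergeom(loadings,
      gene_set_collection(list(S = top5)), top_fraction = 1.5), "top_fraction")
})

test_that("BH q-values are monotone in p and never smaller than p", {
  set.seed(47)
  l <- stats::setNames(rnorm(500), sprintf("G%03d", 1:500))
  sets <- lapply(1:12, function(i) sample(names(l), 25))
  names(sets) <- sprintf("S%02d", 1:12)
  r <- loading_ranksum_enrichment(l, gene_set_collection(sets))
  expect_true(all(r$q_value >= r$p_value - 1e-15))
  o <- order(r$p_value)
  expect_true(all(diff(r$q_value[o]) >= -1e-15))
})

test_that("GWAS association is a rank correlation with sane guards", {
  set.seed(53)
  l <- stats::setNames(rexp(60), sprintf("G%03d", 1:60))
  # any strictly increasing transform gives rho = 1
  sc <- stats::setNames(exp(2 * l + 1), names(l))
  a <- gwas_loading_association(l, sc)
  expect_equal(a$estimate, 1)
  expect_equal(a$n_shared, 60)

  expect_error(
    gwas_loading_association(l[1:8], sc[1:8]),
    "only 8 genes shared"
  )

  # under independence the type-I error at 0.05 is calibrated
  set.seed(59)
  genes <- sprintf("G%04d", 1:500)
  rej <- mean(replicate(1000, {
    gwas_loading_association(stats::setNames(rnorm(500), genes),
                             stats::setNames(rnorm(500), genes))$p_value < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("top-cell selection is a deterministic sort-and-slice", {
  set.seed(61)
  emb <- stats::setNames(runif(1000), sprintf("c%04d", 1:1000))
  sel <- select_top_cells(emb, quantile = 0.99, min_cells = 50)
  expect_length(sel, 50)  # ceiling(10) < min_cells floor
  expect_gte(min(emb[sel]), max(emb[setdiff(names(emb), sel)]))

  # brute-force oracle: order and slice
  m <- max(ceiling(1000 * 0.01), 50)
  oracle <- names(sort(emb, decreasing = TRUE))[1:m]
  expect_setequal(sel, oracle)

  # with a larger cut the quantile drives the size
  sel2 <- select_top_cells(emb, quantile = 0.9, min_cells = 50)
  expect_length(sel2, 100)

  # constant embeddings: first min_cells by sample id
  flat <- stats::setNames(rep(1, 200), sprintf("c%03d", 1:200))
  self <- select_top_cells(flat, quantile = 0.99, min_cells = 20)
  expect_identical(sort(self), sprintf("c%03d", 1:20))

  expect_error(select_top_cells(emb[1:30], min_cells = 50), "only 30 cells")
})

test_that("loading-expression profiles are exact on linear data", {
  genes <- sprintf("G%03d", 1:40)
  x <- seq(0.1, 4, length.out = 40)
  d <- expression_dataset(
    matrix(rep(2 * x, 3), ncol = 3), genes,
    data.frame(sample_id = c("c1", "c2", "c3")), "lin"
  )
  prof <- loading_expression_profile(d, stats::setNames(x, genes),
                                     cells = c("c1", "c2", "c3"))
  expect_equal(prof$correlation$estimate, 1, tolerance = 1e-12)
  interior <- prof$loess$x > min(x) & prof$loess$x < max(x)
  expect_lt(max(abs(prof$loess$fitted[interior] - 2 * prof$loess$x[interior])),
            1e-6)
  expect_true(all(diff(prof$loess$x) > 0))

  # span 1 on 10 collinear points reproduces ordinary least squares
  g10 <- sprintf("G%02d", 1:10)
  x10 <- 1:10
  y10 <- 3 * x10 + 1
  d10 <- expression_dataset(matrix(y10, ncol = 1), g10,
                            data.frame(sample_id = "c1"), "ols")
  p10 <- loading_expression_profile(d10, stats::setNames(x10, g10),
                                    cells = "c1", loess_span = 1)
  ols <- stats::lm(y10 ~ x10)
  pred <- stats::predict(ols, data.frame(x10 = p10$loess$x))
  expect_lt(max(abs(p10$loess$fitted - pred)), 1e-9)

  # zero variance on the expression axis: correlation reported missing
  dz <- expression_dataset(matrix(5, 40, 1), genes,
                           data.frame(sample_id = "c1"), "flat")
  expect_warning(
    pz <- loading_expression_profile(dz, stats::setNames(x, genes), "c1"),
    "zero variance"
  )
  expect_true(is.na(pz$correlation$estimate))
})

test_that("a planted loading shift produces an overwhelming rank-sum signal", {
  set.seed(67)
  genes <- sprintf("G%05d", 1:10000)
  l <- stats::setNames(rnorm(10000, 5, 1), genes)
  memb <- sample(genes, 100)
  l[memb] <- l[memb] + 2 * stats::sd(l)
  r <- loading_ranksum_enrichment(l, gene_set_collection(list(HIT = memb)))
  expect_lt(r$p_value, 1e-6)
})
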