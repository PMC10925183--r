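make_pair <- function(seed = 1, g = 20, n = c(8, 12), k = 3) {
  set.seed(seed)
  lapply(seq_along(n), function(d) {
    m <- matrix(rexp(g * n[d], rate = 0.5), g, n[d])
    expression_dataset(
      m, sprintf("G%03d", seq_len(g)),
      data.frame(sample_id = sprintf("d%d_c%02d", d, seq_len(n[d]))),
      sprintf("d%d", d)
    )
  })
}

test_that("initialization is deterministic, scaled, and validates k", {
  ds <- make_pair(5)
  f1 <- init_factors(ds, k = 3, seed = 7)
  f2 <- init_factors(ds, k = 3, seed = 7)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_error(init_factors(ds, k = 0, seed = 1), "positive integer")
  expect_error(init_factors(ds, k = 21, seed = 1), "exceeds")

  # entries are U(0,1) * sqrt(mean(X)/k): empirical mean of many draws
  # approaches 0.5 * sqrt(mean/k)
  set.seed(3)
  big <- list(expression_dataset(
    matrix(rexp(200 * 500, rate = 1), 200),  # mean ~= 1
    sprintf("G%03d", 1:200),
    data.frame(sample_id = sprintf("c%03d", 1:500)), "big"
  ))
  mean_x <- mean(as.matrix(big[[1]]$matrix))
  f <- init_factors(big, k = 4, seed = 11)
  draws <- c(as.numeric(f$W), as.numeric(f$H[[1]]))
  expect_equal(mean(draws), 0.5 * sqrt(mean_x / 4), tolerance = 0.02)
  expect_equal(max(draws), sqrt(mean_x / 4), tolerance = 0.02)
})

test_that("a factorization reproducing the data exactly is a fixed point", {
  set.seed(13)
  g <- 15; k <- 2
  W <- matrix(rexp(g * k), g, k)
  H1 <- matrix(rexp(k * 6), k, 6)
  H2 <- matrix(rexp(k * 9), k, 9)
  ds <- list(
    expression_dataset(W %*% H1, sprintf("G%02d", 1:g),
                       data.frame(sample_id = sprintf("a%d", 1:6)), "a"),
    expression_dataset(W %*% H2, sprintf("G%02d", 1:g),
                       data.frame(sample_id = sprintf("b%d", 1:9)), "b")
  )
  f <- init_factors(ds, k = k, seed = 1)
  f$W <- W
  rownames(f$W) <- ds[[1]]$genes
  colnames(f$W) <- f$pattern_names
  f$H <- list(a = H1, b = H2)
  obj0 <- joint_objective(f, ds)
  expect_lt(obj0, 1e-18)
  f1 <- update_step(f, ds)
  expect_lt(f1$objective_trace[1], 1e-10)
})

test_that("the objective never increases over multiplicative updates", {
  ds <- make_pair(17, g = 20, n = c(10, 14), k = 3)
  f <- init_factors(ds, k = 3, seed = 2)
  for (i in 1:100) f <- update_step(f, ds)
  tr <- f$objective_trace
  expect_length(tr, 100)
  expect_true(all(diff(tr) <= 1e-10 * tr[-length(tr)]))
  expect_true(all(f$W >= 0))
  expect_true(all(vapply(f$H, function(h) all(h >= 0), logical(1))))
})

test_that("rank-1 instances are recovered against analytic and SVD oracles", {
  set.seed(23)
  g <- 30
  w <- rexp(g) + 0.1
  h <- rexp(25) + 0.1
  ds <- list(expression_dataset(
    outer(w, h), sprintf("G%03d", 1:g),
    data.frame(sample_id = sprintf("c%02d", 1:25)), "r1"
  ))
  f <- fit_jointnmf(ds, k = 1, seed = 4, max_iter = 500)
  cosine <- sum(f$W[, 1] * w) / sqrt(sum(f$W[, 1]^2) * sum(w^2))
  expect_gte(cosine, 1 - 1e-6)

  # strictly positive noisy matrix: NMF rank-1 reconstruction matches the
  # Eckart--Young best rank-1 approximation (positive leading factors)
  X <- outer(w, h) + matrix(rexp(g * 25, 2), g)
  ds2 <- list(expression_dataset(
    X, sprintf("G%03d", 1:g),
    data.frame(sample_id = sprintf("c%02d", 1:25)), "r1b"
  ))
  f2 <- fit_jointnmf(ds2, k = 1, seed = 4, max_iter = 1000, rel_tol = 1e-10)
  sv <- svd(X, nu = 1, nv = 1)
  best1 <- sv$d[1] * abs(sv$u) %*% t(abs(sv$v))
  recon <- f2$W %*% f2$H[[1]]
  cosine2 <- sum(recon * best1) / sqrt(sum(recon^2) * sum(best1^2))
  expect_gte(cosine2, 0.999)
})

test_that("rel_tol = 0 runs exactly max_iter sweeps", {
  ds <- make_pair(31)
  f <- fit_jointnmf(ds, k = 2, seed = 1, max_iter = 5, rel_tol = 0)
  expect_length(f$objective_trace, 5)
  expect_false(f$converged)
})

test_that("normalize_factorization rescales without changing reconstructions", {
  ds <- make_pair(37)
  f <- fit_jointnmf(ds, k = 3, seed = 2, max_iter = 50, rel_tol = 0)
  # manual de-normalization: double a W column, halve its H rows
  g <- f
  g$W[, 2] <- g$W[, 2] * 2
  g$H <- lapply(g$H, function(h) { h[2, ] <- h[2, ] / 2; h })
  gn <- normalize_factorization(g)
  expect_equal(unname(sqrt(colSums(gn$W^2))), rep(1, 3), tolerance = 1e-12)
  for (d in 1:2) {
    r0 <- g$W %*% g$H[[d]]
    r1 <- gn$W %*% gn$H[[d]]
    expect_lt(max(abs(r1 - r0)) / max(r0), 1e-9)
  }
  # idempotence
  gnn <- normalize_factorization(gn)
  expect_equal(gnn$W, gn$W, tolerance = 1e-14)
})

test_that("rescaling all inputs scales the objective by c^2 and not W", {
  ds <- make_pair(41)
  c_scale <- 3.7
  ds_scaled <- lapply(ds, function(d) {
    expression_dataset(as.matrix(d$matrix) * c_scale, d$genes,
                       d$sample_meta, d$dataset_id)
  })
  f1 <- fit_jointnmf(ds, k = 2, seed = 6, max_iter = 200, rel_tol = 0)
  f2 <- fit_jointnmf(ds_scaled, k = 2, seed = 6, max_iter = 200, rel_tol = 0)
  expect_equal(f2$objective_trace[200] / f1$objective_trace[200], c_scale^2,
               tolerance = 1e-6)
  expect_equal(f2$W, f1$W, tolerance = 1e-6)
})

test_that("identical inputs and seed give identical fits", {
  ds <- make_pair(43)
  f1 <- fit_jointnmf(ds, k = 3, seed = 9, max_iter = 60)
  f2 <- fit_jointnmf(ds, k = 3, seed = 9, max_iter = 60)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_identical(f1$objective_trace, f2$objective_trace)
})

test_that("top_loading_genes ranks, slices and breaks ties deterministically", {
  set.seed(47)
  genes <- sprintf("G%05d", 1:20000)
  W <- matrix(runif(20000), dimnames = list(genes, "p1of1"))
  expect_length(top_loading_genes(W, "p1of1", 0.002), 40)

  all_genes <- top_loading_genes(W, "p1of1", 1.0)
  expect_identical(all_genes, genes[order(-W[, 1], genes)])

  # tie exactly at the cutoff: alphabetically earlier gene wins
  W2 <- matrix(c(ZZB = 5, ZZA = 5, AAC = 9, AAD = 1),
               dimnames = list(c("ZZB", "ZZA", "AAC", "AAD"), "p1of1"))
  expect_identical(top_loading_genes(W2, "p1of1", 0.5), c("AAC", "ZZA"))

  expect_error(top_loading_genes(W, "p1of1", 0), "fraction")
  expect_error(top_loading_genes(W, "p1of1", 1.2), "fraction")
  expect_error(top_loading_genes(W, "nope", 0.5), "unknown pattern")
})
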