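# Brute-force oracles and small fixture builders shared across tests.
# Oracles are kept deliberately independent of the implementation paths
# they check.

# Tiny deterministic dataset: counts chosen by hand.
tiny_dataset <- function() {
  m <- matrix(c(1, 0, 2,
                0, 3, 0), nrow = 3,
              dimnames = NULL)
  expression_dataset(
    m, genes = c("GA", "GB", "GC"),
    sample_meta = data.frame(sample_id = c("c1", "c2"),
                             cell_type = c("t1", "t2"),
                             age = c(1, 2), species = "human"),
    dataset_id = "tiny"
  )
}

random_dataset <- function(seed, n_genes = 40, n_cells = 15, density = 0.3,
                           id = "rand", species = "human") {
  set.seed(seed)
  m <- matrix(0, n_genes, n_cells)
  nz <- sample(length(m), ceiling(density * length(m)))
  m[nz] <- rpois(length(nz), 5) + 1
  expression_dataset(
    Matrix::Matrix(m, sparse = TRUE),
    genes = sprintf("G%03d", seq_len(n_genes)),
    sample_meta = data.frame(sample_id = sprintf("%s_c%02d", id, seq_len(n_cells)),
                             cell_type = sample(c("t1", "t2"), n_cells, TRUE),
                             age = sample(1:4, n_cells, TRUE),
                             species = species),
    dataset_id = id
  )
}

# Exact one-sided rank-sum p by enumerating every member placement.
enum_ranksum_p <- function(loadings, members) {
  n <- length(loadings)
  m <- length(members)
  r <- rank(loadings)
  obs <- sum(r[names(loadings) %in% members]) - m * (m + 1) / 2
  combos <- utils::combn(n, m)
  stats <- apply(combos, 2, function(idx) sum(r[idx]) - m * (m + 1) / 2)
  mean(stats >= obs - 1e-9)
}

# Upper hypergeometric tail from first principles (log-scale binomials).
enum_hyper_tail <- function(x, m, N, k_top) {
  j <- x:min(m, k_top)
  sum(exp(lchoose(m, j) + lchoose(N - m, k_top - j) - lchoose(N, k_top)))
}

# Exhaustive assignment oracle for small k.
enum_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- rev(expand.grid(rep(list(seq_len(n)), n)))
  best <- Inf
  for (i in seq_len(nrow(perms))) {
    p <- as.integer(perms[i, ])
    if (length(unique(p)) != n) next
    tot <- sum(cost[cbind(seq_len(n), p)])
    if (tot < best) best <- tot
  }
  best
}
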