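# Lawson--Hanson active-set NNLS on the normal equations.
# AtA: k x k crossprod of the design, Atb: length-k vector. Suitable here
# because k (the pattern count) is small; the design itself can have
# thousands of rows.
nnls_normal <- function(AtA, Atb, tol = 1e-10) {
  k <- length(Atb)
  x <- numeric(k)
  passive <- logical(k)
  w <- as.numeric(Atb)
  maxit <- 50L * (k + 1L)
  it <- 0L
  while (it < maxit) {
    it <- it + 1L
    cand <- which(!passive & w > tol)
    if (length(cand) == 0L) break
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(k)
      P <- which(passive)
      sol <- tryCatch(
        solve(AtA[P, P, drop = FALSE], Atb[P]),
        error = function(e) qr.solve(AtA[P, P, drop = FALSE], Atb[P])
      )
      s[P] <- sol
      if (all(s[P] > tol)) {
        x <- s
        break
      }
      viol <- P[s[P] <= tol]
      alpha <- min(x[viol] / (x[viol] - s[viol]))
      x <- x + alpha * (s - x)
      passive[x <= tol & passive] <- FALSE
      x[!passive] <- 0
    }
    w <- as.numeric(Atb - AtA %*% x)
  }
  x[x < 0] <- 0
  x
}

# Exhaustive-support NNLS used as an oracle in tests: solve the
# unconstrained least-squares on every subset of columns, keep feasible
# solutions, return the one with smallest residual. Exact for any k small
# enough to enumerate.
nnls_enumerate <- function(A, b) {
  k <- ncol(A)
  best <- list(x = numeric(k), rss = sum(b^2))
  for (m in seq_len(2^k - 1L)) {
    S <- which(bitwAnd(m, bitwShiftL(1L, seq_len(k) - 1L)) != 0L)
    As <- A[, S, drop = FALSE]
    coef <- tryCatch(qr.solve(As, b), error = function(e) NULL)
    if (is.null(coef) || any(coef < 0)) next
    rss <- sum((b - As %*% coef)^2)
    if (rss < best$rss - 1e-12) {
      x <- numeric(k)
      x[S] <- coef
      best <- list(x = x, rss = rss)
    }
  }
  best$x
}

# O(n^3) Hungarian algorithm (shortest augmenting path formulation) for the
# square min-cost assignment problem. Returns, for each row, the assigned
# column. Indices shifted by one so that "column 0" of the classical
# formulation lives at position 1.
hungarian_assign <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0L) return(integer(0))
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)    # p[j+1]: row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) assignment[p[j + 1L]] <- j
  assignment
}
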