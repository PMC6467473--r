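# Independent oracles used across tests. These deliberately re-derive the
# quantities by the most literal route available (loops, enumeration, grids)
# and share no code with the package internals.

# fuzzy c-means by literal per-element loops over the update equations
oracle_fcm <- function(x, centroids, m, tol, max_iter) {
  n <- nrow(x); k <- nrow(centroids)
  u <- matrix(0, n, k)
  memberships <- function(cent) {
    uu <- matrix(0, n, k)
    for (g in seq_len(n)) {
      d <- sapply(seq_len(k), function(c) sqrt(sum((x[g, ] - cent[c, ])^2)))
      if (any(d == 0)) {
        uu[g, ] <- as.numeric(d == 0) / sum(d == 0)
      } else {
        for (c in seq_len(k))
          uu[g, c] <- 1 / sum((d[c] / d)^(2 / (m - 1)))
      }
    }
    uu
  }
  for (it in seq_len(max_iter)) {
    u <- memberships(centroids)
    new_c <- centroids
    for (c in seq_len(k)) {
      w <- u[, c]^m
      new_c[c, ] <- colSums(w * x) / sum(w)
    }
    shift <- max(abs(new_c - centroids))
    centroids <- new_c
    if (shift < tol) break
  }
  list(u = memberships(centroids), centroids = centroids)
}

# hypergeometric upper tail by direct summation of terms
oracle_hyper_upper <- function(overlap, K, N, n) {
  ks <- overlap:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Benjamini-Hochberg step-up by the textbook definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Welch two-sample t-test p-value via stats::t.test (reference route)
oracle_welch_p <- function(a, b) stats::t.test(a, b)$p.value

# exhaustive grid search on the 1-simplex for two-stage deconvolution
oracle_grid_2stage <- function(S, x, step = 1e-4) {
  f1 <- seq(0, 1, by = step)
  obj <- sapply(f1, function(f) sum((S %*% c(f, 1 - f) - x)^2))
  c(f1[which.min(obj)], 1 - f1[which.min(obj)])
}

# penalty + renormalization solver: the sum-to-one constraint as a heavy
# penalty row appended to the least-squares system, solved by nonnegative
# least squares, then renormalized onto the simplex
oracle_penalty_qp <- function(S, x, penalty = 1e6) {
  k <- ncol(S)
  A <- rbind(S, sqrt(penalty) * rep(1, k))
  b <- c(x, sqrt(penalty))
  f <- pracma::lsqnonneg(A, b)$x
  f / sum(f)
}

# uniform random point on the probability simplex
runif_simplex <- function(n, k) {
  e <- matrix(stats::rexp(n * k), n, k)
  e / rowSums(e)
}

# PCA scores via eigendecomposition of the sample covariance matrix
oracle_pca_scores <- function(x_centered_genes_by_samples, n_comp) {
  m <- t(x_centered_genes_by_samples)   # samples x genes
  cv <- m %*% t(m)
  ei <- eigen(cv, symmetric = TRUE)
  sc <- ei$vectors[, seq_len(n_comp), drop = FALSE] *
    rep(sqrt(pmax(ei$values[seq_len(n_comp)], 0)), each = nrow(m))
  sc
}
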