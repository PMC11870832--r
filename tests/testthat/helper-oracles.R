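# Independent oracles and small fixture builders used across the suite.

# All-pairs shortest paths by Floyd-Warshall on a boolean adjacency matrix;
# independent of the package's breadth-first search.
fw_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj] <- 1
  diag(d) <- 0
  for (k in seq_len(n))
    for (i in seq_len(n))
      d[i, ] <- pmin(d[i, ], d[i, k] + d[k, ])
  d
}

fw_efficiency <- function(adj) {
  n <- nrow(adj)
  d <- fw_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Naive double-loop mean of off-diagonal entries.
naive_offdiag_mean <- function(m) {
  total <- 0; count <- 0
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (i != j) { total <- total + m[i, j]; count <- count + 1 }
  }
  total / count
}

# Random symmetric adjacency with edge density p.
random_adjacency <- function(n, p) {
  a <- matrix(FALSE, n, n)
  up <- upper.tri(a)
  a[up] <- stats::runif(sum(up)) < p
  a | t(a)
}

# Partial correlation via the inverse correlation matrix of [x, y, covs]:
# r_xy.c = -P_12 / sqrt(P_11 * P_22) with P the precision matrix.
precision_partial_cor <- function(x, y, covs) {
  m <- cbind(x, y, as.matrix(covs))
  P <- solve(stats::cor(m))
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# Wrap a plain symmetric r matrix as an fc_matrix (window 30 min).
as_fc <- function(r, window = 30, subject_id = "T") {
  diag(r) <- 1
  fisher_z(structure(list(r = r, z = NULL, window = window_spec(window),
                          subject_id = subject_id),
                     class = "fc_matrix"))
}

# A tiny clean hb_series with a planted compound-symmetric correlation.
make_test_hb <- function(nch = 6, n_t = 4000, fs = 10, rho = 0.6, seed = 1) {
  set.seed(seed)
  sigma <- matrix(rho, nch, nch); diag(sigma) <- 1
  x <- t(chol(sigma)) %*% matrix(rnorm(nch * n_t), nch, n_t)
  hb_series(x, -0.4 * x, fs)
}
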