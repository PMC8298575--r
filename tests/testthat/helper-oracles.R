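# Independent oracles and tiny fixture builders shared across test files.

# Brute-force PCA oracle: correlation matrix by explicit double loop,
# eigenpairs by power iteration with deflation. Deliberately avoids eigen()
# and prcomp() so it is independent of the implementation under test.
oracle_pca <- function(M, max_iter = 50000L, tol = 1e-14) {
  n <- nrow(M); p <- ncol(M)
  Z <- M
  for (j in seq_len(p)) {
    mu <- sum(M[, j]) / n
    s <- sqrt(sum((M[, j] - mu)^2) / (n - 1))
    Z[, j] <- (M[, j] - mu) / s
  }
  C <- matrix(0, p, p)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      C[i, j] <- sum(Z[, i] * Z[, j]) / (n - 1)
    }
  }
  vals <- numeric(p)
  vecs <- matrix(0, p, p)
  A <- C
  set.seed(991)
  for (k in seq_len(p)) {
    v <- rnorm(p)
    v <- v / sqrt(sum(v^2))
    for (it in seq_len(max_iter)) {
      w <- as.numeric(A %*% v)
      nw <- sqrt(sum(w^2))
      if (nw < 1e-300) break
      w <- w / nw
      conv <- min(max(abs(w - v)), max(abs(w + v))) < tol
      v <- w
      if (conv) break
    }
    lam <- as.numeric(t(v) %*% A %*% v)
    vals[k] <- lam
    vecs[, k] <- v
    A <- A - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs, cor = C)
}

# Align the sign of each oracle eigenvector column to a reference matrix.
align_signs <- function(V, ref) {
  for (k in seq_len(ncol(V))) {
    if (sum(V[, k] * ref[, k]) < 0) V[, k] <- -V[, k]
  }
  V
}

# A noise-free truth spec on a linear age model, for identity checks.
zero_noise_spec <- function(kind = "marine", seed = 1L) {
  truth_spec(
    record_kind = kind,
    true_age_fn = function(d) d * 10,
    signal_fns = list(
      a = sig_ramp(3000, 500, value_old = 5, value_young = 1),
      b = sig_step(2000, value_old = 1, value_young = 3)),
    change_ages = 2000,
    noise_spec = list(a = list(mode = "relative", magnitude = 0),
                      b = list(mode = "absolute", magnitude = 0)),
    depth_max = 400, n_dates = 9L,
    age_sigma_fn = function(d) rep(0, length(d)),
    sigma_convention = 2, sample_spacing = 5, seed = seed)
}

# Build an ensemble_summary by hand (for envelope-propagation unit tests).
fake_summary <- function(name, time_grid, median, half_width = 0) {
  structure(
    list(name = name, time_grid = time_grid, median = median,
         p5 = median - half_width, p95 = median + half_width,
         density = NULL, value_breaks = NULL, n_draws = 100L, draws = NULL),
    class = "ensemble_summary")
}
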