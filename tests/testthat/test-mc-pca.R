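make_ensemble <- function(n_draws = 200, seed = 1, sigma = c(0, 0)) {
  h <- dated_horizons(c(0, 100), c(0, 1000), rep(sigma[1], 2))
  ages <- sample_age_models(h, n_draws = n_draws,
                            depth_grid = seq(0, 100, 5), seed = seed)
  series <- proxy_series("p", seq(0, 100, 10), 10 + seq(0, 100, 10) / 10,
                         unc_mode = "relative", unc_magnitude = sigma[2])
  list(ages = ages, series = series)
}

test_that("zero noise and zero age error give a degenerate ensemble", {
  f <- make_ensemble(sigma = c(0, 0))
  es <- simulate_ensemble(f$series, f$ages, n_draws = 200, seed = 2)
  # truth: value = 10 + depth/10, age = 10*depth -> value = 10 + age/100
  expect_equal(es$median, 10 + es$time_grid / 100, tolerance = 1e-9)
  expect_equal(es$p95 - es$p5, rep(0, length(es$time_grid)), tolerance = 1e-12)
})

test_that("median of a noisy constant converges to the constant", {
  h <- dated_horizons(c(0, 100), c(0, 1000), c(0, 0))
  ages <- sample_age_models(h, n_draws = 2000, depth_grid = c(0, 50, 100),
                            seed = 3)
  v <- 40
  series <- proxy_series("c", c(0, 50, 100), rep(v, 3),
                         unc_mode = "relative", unc_magnitude = 0.075)
  es <- simulate_ensemble(series, ages, n_draws = 2000, seed = 4)
  # sd of a sample median of n normals ~ 1.2533 sigma / sqrt(n); allow 4 sd
  bound <- 4 * 1.2533 * 0.075 * v / sqrt(2000)
  expect_true(all(abs(es$median - v) < bound))
})

test_that("the 90% envelope contains 90% of draws at every grid time", {
  f <- make_ensemble(n_draws = 1000, sigma = c(30, 0.1))
  es <- simulate_ensemble(f$series, f$ages, n_draws = 1000, seed = 5)
  cov <- envelope_coverage(es)
  expect_true(all(abs(cov - 0.9) < 0.005))
})

test_that("density histogram conserves draws per time bin", {
  f <- make_ensemble(n_draws = 300, sigma = c(20, 0.05))
  es <- simulate_ensemble(f$series, f$ages, n_draws = 300, seed = 6)
  expect_true(all(colSums(es$density) == es$n_draws))
  expect_equal(nrow(es$density), 50L)
})

test_that("ensembles are bit-identical under a fixed seed", {
  f <- make_ensemble(n_draws = 200, sigma = c(15, 0.05))
  e1 <- simulate_ensemble(f$series, f$ages, n_draws = 200, seed = 42)
  e2 <- simulate_ensemble(f$series, f$ages, n_draws = 200, seed = 42)
  expect_identical(e1$draws, e2$draws)
  expect_identical(e1$median, e2$median)
})

test_that("user grid points outside the common age span are dropped", {
  f <- make_ensemble(n_draws = 150, sigma = c(25, 0))
  expect_message(
    es <- simulate_ensemble(f$series, f$ages, n_draws = 150,
                            time_grid = c(-500, 200, 500, 800, 99999),
                            seed = 7),
    "dropping")
  expect_true(all(es$time_grid %in% c(200, 500, 800)))
  expect_true(all(colSums(es$density) == es$n_draws))
})

test_that("three perfectly correlated series put all variance on PC1", {
  tg <- seq(100, 900, 20)
  base <- sin(tg / 150)
  ss <- list(fake_summary("x", tg, base),
             fake_summary("y", tg, 5 + 2 * base),
             fake_summary("z", tg, -1 + 0.1 * base))
  syn <- pca_median(ss)
  expect_equal(syn$var_explained[1], 1, tolerance = 1e-12)
  expect_equal(abs(syn$loadings[, 1]), rep(1 / sqrt(3), 3),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("two exactly uncorrelated series split the variance evenly", {
  tg <- seq_len(8)
  a <- rep(c(1, -1), 4)        # orthogonal pattern
  b <- rep(c(1, 1, -1, -1), 2) # zero correlation with a
  syn <- pca_median(list(fake_summary("a", tg, a), fake_summary("b", tg, b)))
  expect_equal(syn$var_explained, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("loadings match the brute-force eigendecomposition oracle", {
  set.seed(20)
  for (p in 3:5) {
    tg <- seq(0, 2000, 25)
    common <- cumsum(rnorm(length(tg)))
    ss <- lapply(seq_len(p), function(k) {
      fake_summary(paste0("s", k), tg,
                   rnorm(1, 0, 2) * common + rnorm(length(tg)))
    })
    syn <- pca_median(ss)
    orc <- oracle_pca(vapply(ss, function(s) s$median, numeric(length(tg))))
    expect_equal(syn$var_explained, orc$values / sum(orc$values),
                 tolerance = 1e-8)
    V <- align_signs(orc$vectors, syn$loadings)
    expect_equal(unname(syn$loadings), V, tolerance = 1e-8)
  }
})

test_that("loading columns are orthonormal and variance fractions sum to 1", {
  set.seed(21)
  tg <- seq(0, 1000, 20)
  ss <- lapply(1:4, function(k) {
    fake_summary(paste0("s", k), tg, cumsum(rnorm(length(tg))))
  })
  syn <- pca_median(ss)
  G <- crossprod(syn$loadings)
  expect_equal(G, diag(4), ignore_attr = TRUE, tolerance = 1e-9)
  expect_equal(sum(syn$var_explained), 1, tolerance = 1e-12)
})

test_that("rescaling one raw series leaves the loadings unchanged", {
  set.seed(22)
  tg <- seq(0, 1000, 20)
  m1 <- cumsum(rnorm(length(tg)))
  m2 <- cumsum(rnorm(length(tg)))
  m3 <- cumsum(rnorm(length(tg)))
  s_a <- list(fake_summary("x", tg, m1), fake_summary("y", tg, m2),
              fake_summary("z", tg, m3))
  s_b <- list(fake_summary("x", tg, 10 * m1), fake_summary("y", tg, m2),
              fake_summary("z", tg, m3))
  expect_equal(pca_median(s_a)$loadings, pca_median(s_b)$loadings,
               tolerance = 1e-12)
})

test_that("zero-variance input series are rejected by name", {
  tg <- seq_len(20)
  ss <- list(fake_summary("flat", tg, rep(1, 20)),
             fake_summary("ok", tg, seq_len(20)))
  expect_error(pca_median(ss), "flat")
})

test_that("PC1 envelope propagation follows the fractional-mean rule", {
  tg <- seq(100, 900, 50)
  base <- sin(tg / 100)
  # equal loadings: two identical-shape series
  ss0 <- list(fake_summary("a", tg, 10 + base, half_width = 0),
              fake_summary("b", tg, 20 + 2 * base, half_width = 0))
  syn0 <- propagate_pc_envelope(pca_median(ss0), ss0)
  expect_equal(syn0$pc1_lo, syn0$pc1_series, tolerance = 1e-12)
  expect_equal(syn0$pc1_hi, syn0$pc1_series, tolerance = 1e-12)

  # uniform fractional uncertainty 0.1: half-width = 0.1 * |PC1|
  ss1 <- list(fake_summary("a", tg, 10 + base, half_width = 0.1 * abs(10 + base)),
              fake_summary("b", tg, 20 + 2 * base,
                           half_width = 0.1 * abs(20 + 2 * base)))
  syn1 <- propagate_pc_envelope(pca_median(ss1), ss1)
  expect_equal(syn1$pc1_hi - syn1$pc1_series, 0.1 * abs(syn1$pc1_series),
               tolerance = 1e-9)

  # doubling one series' envelope widens the PC1 envelope everywhere
  ss2 <- list(fake_summary("a", tg, 10 + base, half_width = 0.2 * abs(10 + base)),
              fake_summary("b", tg, 20 + 2 * base,
                           half_width = 0.1 * abs(20 + 2 * base)))
  syn2 <- propagate_pc_envelope(pca_median(ss2), ss2)
  w1 <- syn1$pc1_hi - syn1$pc1_lo
  w2 <- syn2$pc1_hi - syn2$pc1_lo
  nz <- abs(syn1$pc1_series) > 1e-12
  expect_true(all(w2[nz] > w1[nz]))
})

test_that("injected marine correlation structure fixes the loading signs", {
  ok <- 0L
  n_rep <- 100L
  for (r in seq_len(n_rep)) {
    rec <- generate_record(marine_preset(seed = 1000 + r))
    ages <- sample_age_models(rec$horizons, n_draws = 100,
                              depth_grid = rec$proxies[[1]]$depth,
                              seed = 2000 + r)
    tg <- NULL
    ss <- list()
    for (ps in rec$proxies) {
      es <- simulate_ensemble(ps, ages, n_draws = 100, time_grid = tg,
                              seed = 3000 + r, keep_draws = FALSE)
      if (is.null(tg)) tg <- es$time_grid
      ss[[ps$name]] <- es
    }
    syn <- pca_median(ss, orient_proxy = "diatom_flux")
    l <- syn$loadings[, 1]
    if (l[["diatom_flux"]] > 0 && l[["chaetoceros_flux"]] > 0 &&
          l[["hbi3_flux"]] < 0) {
      ok <- ok + 1L
    }
  }
  expect_gte(ok / n_rep, 0.95)
})
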