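linear_series <- function(n = 60) {
  t_b2k <- seq(3000, 100, length.out = n)
  list(time = t_b2k, value = 10 - t_b2k / 500) # rises towards the present
}

test_that("a noiseless linear trend is fitted exactly with constant derivative", {
  s <- linear_series()
  # mgcv warns about a smoothing step failure on exactly-linear data; the
  # fit itself is checked below
  fit <- suppressWarnings(fit_trend(s$time, s$value, n_post = 100, seed = 1))
  truth <- 10 - fit$time_b2k / 500
  expect_lt(max(abs(fit$fitted - truth)), 1e-6)
  res <- derivative_ci(fit)
  # derivative wrt calendar time: +1/500 per yr
  expect_lt(max(abs(res$deriv_mean - 1 / 500)), 1e-5)
  expect_equal(nrow(res$significant_intervals), 1L)
  expect_equal(res$significant_intervals$sign, 1L)
  expect_equal(res$significant_intervals$t_start_b2k, 3000)
  expect_equal(res$significant_intervals$t_end_b2k, 100)
})

test_that("a flat series with small noise yields no significant change", {
  set.seed(30)
  t_b2k <- seq(4000, 200, length.out = 80)
  y <- 5 + rnorm(80, 0, 0.3)
  fit <- fit_trend(t_b2k, y, n_post = 400, seed = 2)
  res <- derivative_ci(fit)
  expect_equal(nrow(res$significant_intervals), 0L)
  expect_equal(nrow(changepoints(res)), 0L)
})

test_that("posterior draws are reproducible under a fixed seed", {
  s <- linear_series()
  set.seed(31)
  y <- s$value + rnorm(length(s$value), 0, 0.2)
  f1 <- fit_trend(s$time, y, n_post = 50, seed = 9)
  f2 <- fit_trend(s$time, y, n_post = 50, seed = 9)
  expect_identical(f1$posterior_draws, f2$posterior_draws)
  f3 <- fit_trend(s$time, y, n_post = 50, seed = 10)
  expect_false(identical(f1$posterior_draws, f3$posterior_draws))
})

test_that("CAR(1) fit estimates a correlation parameter in [0, 1)", {
  set.seed(32)
  n <- 90
  t_b2k <- sort(runif(n, 0, 5000), decreasing = TRUE)
  tcal <- -t_b2k
  # AR-like residuals on top of a gentle trend
  e <- numeric(n)
  for (i in 2:n) {
    rho <- 0.7^((tcal[i] - tcal[i - 1]) / 25)
    e[i] <- rho * e[i - 1] + rnorm(1, 0, sqrt(1 - rho^2) * 0.5)
  }
  y <- tcal / 2000 + e
  fit <- fit_trend(t_b2k, y, car1 = TRUE, n_post = 50, seed = 3)
  expect_gt(fit$car1_phi, 0)
  expect_lt(fit$car1_phi, 1)
  expect_true(all(is.finite(fit$fitted)))
})

test_that("a CAR(1) term forced to (nearly) zero reduces to the plain spline", {
  set.seed(33)
  t_b2k <- seq(5000, 100, length.out = 100)
  y <- sin(-t_b2k / 800) + rnorm(100, 0, 0.2)
  plain <- fit_trend(t_b2k, y, car1 = FALSE, n_post = 20, seed = 4)
  g <- mgcv::gamm(y ~ s(tcal, k = 20, bs = "cr"),
                  data = data.frame(tcal = -t_b2k, y = y),
                  correlation = nlme::corCAR1(value = 1e-6, fixed = TRUE,
                                              form = ~tcal),
                  method = "REML")
  pred <- predict(g$gam,
                  newdata = data.frame(tcal = -plain$time_b2k))
  expect_lt(max(abs(as.numeric(pred) - plain$fitted)), 1e-6)
})

test_that("GCV smoothing is available and CAR(1) is refused under it", {
  set.seed(34)
  t_b2k <- seq(3000, 100, length.out = 70)
  y <- cos(-t_b2k / 400) + rnorm(70, 0, 0.2)
  fit <- fit_trend(t_b2k, y, method = "GCV", n_post = 30, seed = 5)
  expect_equal(fit$method, "GCV")
  expect_equal(fit$car1_phi, 0)
  expect_warning(fit_trend(t_b2k, y, method = "GCV", car1 = TRUE,
                           n_post = 30, seed = 5),
                 "CAR\\(1\\)")
})

test_that("the mean derivative lies inside its own confidence band", {
  set.seed(35)
  t_b2k <- seq(4000, 100, length.out = 80)
  y <- as.numeric(t_b2k < 2000) * 2 + rnorm(80, 0, 0.4)
  fit <- fit_trend(t_b2k, y, n_post = 500, seed = 6)
  res <- derivative_ci(fit)
  expect_true(all(res$deriv_mean >= res$deriv_lo - 1e-12))
  expect_true(all(res$deriv_mean <= res$deriv_hi + 1e-12))
  expect_true(all(res$deriv_lo <= res$deriv_hi))
})

test_that("significant intervals are disjoint, ordered and correctly signed", {
  set.seed(36)
  t_b2k <- seq(6000, 100, length.out = 120)
  y <- sin(-t_b2k / 600) * 3 + rnorm(120, 0, 0.2)
  fit <- fit_trend(t_b2k, y, n_post = 500, seed = 7)
  res <- derivative_ci(fit)
  si <- res$significant_intervals
  expect_gt(nrow(si), 0L)
  expect_true(all(si$t_start_b2k >= si$t_end_b2k))
  if (nrow(si) > 1L) {
    expect_true(all(si$t_end_b2k[-nrow(si)] >= si$t_start_b2k[-1]))
  }
  # inside each interval the CI excludes zero with the reported sign
  for (k in seq_len(nrow(si))) {
    inside <- res$time_b2k <= si$t_start_b2k[k] &
      res$time_b2k >= si$t_end_b2k[k]
    if (si$sign[k] > 0) expect_true(all(res$deriv_lo[inside] > 0))
    else expect_true(all(res$deriv_hi[inside] < 0))
  }
})

test_that("changepoints are interval midpoints with attached sign", {
  res <- structure(
    list(time_b2k = seq(3000, 100, -100), deriv_mean = NULL,
         deriv_lo = NULL, deriv_hi = NULL,
         significant_intervals = data.frame(
           t_start_b2k = c(2000, 900), t_end_b2k = c(1800, 500),
           sign = c(-1L, 1L)),
         level = 0.95),
    class = "change_result")
  cp <- changepoints(res)
  expect_equal(cp$age_b2k, c(1900, 700))
  expect_equal(cp$sign, c(-1L, 1L))
})

test_that("degenerate fitting inputs are rejected or repaired", {
  expect_error(fit_trend(1:5, 1:5), "at least 10")
  expect_error(fit_trend(c(1:19, 19), rnorm(20)), "distinct")
  expect_error(fit_trend(1:20, c(rnorm(19), NA)), "finite")
  expect_warning(fit_trend(seq(1000, 100, length.out = 12),
                           rnorm(12), basis_dim = 20, n_post = 20, seed = 1),
                 "shrunk")
  s <- linear_series()
  fit <- suppressWarnings(fit_trend(s$time, s$value, n_post = 20, seed = 1))
  expect_error(derivative_ci(fit, level = 1.2), "level")
})
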