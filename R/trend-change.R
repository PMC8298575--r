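#' Fit a penalized-spline trend with optional CAR(1) errors
#'
#' Models a proxy (or principal component) time series as a smooth trend
#' plus noise, using a cubic penalized regression spline whose smoothness is
#' chosen by REML or GCV. With `car1 = TRUE` the residuals follow a
#' continuous-time first-order autoregressive process, which accommodates
#' the uneven sample spacing of sediment records; its correlation parameter
#' is estimated jointly with the smooth (REML only — with GCV the CAR(1)
#' term is dropped with a warning). Uncertainty in the trend is represented
#' by draws from the Gaussian approximation to the coefficient posterior at
#' the fit, evaluated on an even time grid.
#'
#' Ages are accepted in cal yrs b2k; internally the fit runs on increasing
#' calendar time (negated age), and derivative signs downstream follow the
#' calendar-time convention (positive = increasing towards the present).
#'
#' @param time_b2k sample ages (cal yrs b2k), distinct; any order.
#' @param value response values, finite.
#' @param method smoothing selection: `"REML"` (default) or `"GCV"`.
#' @param car1 include a CAR(1) residual process (REML only).
#' @param basis_dim spline basis dimension (default 20 knots); shrunk with a
#'   warning when the series is shorter.
#' @param n_post number of posterior draws. 20 mirrors a common
#'   display-oriented choice but yields unstable CI quantiles; the default
#'   of 1000 gives stable derivative CIs.
#' @param grid_n number of evaluation grid points.
#' @param seed integer seed for the posterior draws.
#' @return an object of class `trend_fit`: `time_b2k` (evaluation grid,
#'   decreasing b2k = forward time), `fitted`, `posterior_draws`
#'   (n_post x grid_n), `basis_dim`, `smoothing`, `method`, `car1_phi`
#'   (correlation at 1-year lag, 0 when no CAR(1) term), `seed`.
#' @export
fit_trend <- function(time_b2k, value, method = c("REML", "GCV"),
                      car1 = FALSE, basis_dim = 20L, n_post = 1000L,
                      grid_n = 200L, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(time_b2k) == length(value))
  if (any(!is.finite(time_b2k)) || any(!is.finite(value))) {
    stop("times and values must be finite", call. = FALSE)
  }
  if (anyDuplicated(time_b2k)) stop("times must be distinct", call. = FALSE)
  n <- length(value)
  if (n < 10L) stop("need at least 10 points to fit a trend", call. = FALSE)
  if (n_post < 2L) stop("n_post must be >= 2", call. = FALSE)
  if (basis_dim > n - 2L) {
    warning("basis_dim ", basis_dim, " too large for ", n,
            " points; shrunk to ", n - 2L, call. = FALSE)
    basis_dim <- n - 2L
  }
  ord <- order(time_b2k, decreasing = TRUE) # forward calendar time
  dat <- data.frame(tcal = -time_b2k[ord], y = value[ord])

  phi <- 0
  if (car1 && method == "GCV") {
    warning("CAR(1) residuals require REML; car1 dropped for GCV fit",
            call. = FALSE)
    car1 <- FALSE
  }
  if (car1) {
    m <- mgcv::gamm(y ~ s(tcal, k = basis_dim, bs = "cr"), data = dat,
                    correlation = nlme::corCAR1(form = ~tcal),
                    method = "REML")
    g <- m$gam
    phi <- as.numeric(coef(m$lme$modelStruct$corStruct, unconstrained = FALSE))
  } else {
    g <- mgcv::gam(y ~ s(tcal, k = basis_dim, bs = "cr"), data = dat,
                   method = if (method == "REML") "REML" else "GCV.Cp")
  }

  grid <- data.frame(tcal = seq(min(dat$tcal), max(dat$tcal),
                                length.out = grid_n))
  Xp <- predict(g, newdata = grid, type = "lpmatrix")
  fitted <- as.numeric(Xp %*% coef(g))
  beta <- with_seed(seed, MASS::mvrnorm(n_post, coef(g), g$Vp))
  draws <- beta %*% t(Xp)

  structure(
    list(time_b2k = -grid$tcal, fitted = fitted, posterior_draws = draws,
         basis_dim = as.integer(basis_dim),
         smoothing = as.numeric(g$sp), method = method,
         car1_phi = phi, n_post = as.integer(n_post), seed = seed,
         gam = g),
    class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("<trend_fit> %s%s, k=%d, %d posterior draws, grid %d pts\n",
              x$method, if (x$car1_phi > 0) sprintf(" + CAR(1) phi=%.3f", x$car1_phi) else "",
              x$basis_dim, nrow(x$posterior_draws), length(x$time_b2k)))
  invisible(x)
}

#' First-derivative confidence intervals and significant-change intervals
#'
#' Differentiates every posterior trend draw by finite differences on the
#' evaluation grid (central differences; one-sided at the endpoints), takes
#' pointwise quantile confidence intervals, and flags a significant change
#' wherever the interval excludes zero. Contiguous flagged grid points are
#' assembled into non-overlapping, time-ordered intervals with the sign of
#' the derivative (calendar-time convention: `+` means values increasing
#' towards the present).
#'
#' @param fit a `trend_fit`.
#' @param level confidence level in (0, 1), default 0.95.
#' @return an object of class `change_result`: `time_b2k`, `deriv_mean`,
#'   `deriv_lo`, `deriv_hi` (per-year, calendar-time sign),
#'   `significant_intervals` (data.frame `t_start_b2k, t_end_b2k, sign` with
#'   `t_start_b2k >= t_end_b2k`, i.e. start is older), `level`.
#' @export
derivative_ci <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "trend_fit"))
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("level must lie in (0, 1)", call. = FALSE)
  }
  tcal <- -fit$time_b2k # increasing
  D <- t(apply(fit$posterior_draws, 1L, finite_diff, x = tcal))
  alpha <- (1 - level) / 2
  qs <- apply(D, 2L, quantile, probs = c(alpha, 1 - alpha), names = FALSE)
  lo <- qs[1L, ]; hi <- qs[2L, ]
  dmean <- colMeans(D)

  sig <- lo > 0 | hi < 0
  sgn <- ifelse(lo > 0, 1L, ifelse(hi < 0, -1L, 0L))
  intervals <- collect_runs(sig, sgn, fit$time_b2k)

  structure(
    list(time_b2k = fit$time_b2k, deriv_mean = dmean,
         deriv_lo = lo, deriv_hi = hi,
         significant_intervals = intervals, level = level),
    class = "change_result")
}

# Central finite differences with one-sided endpoints.
finite_diff <- function(y, x) {
  n <- length(y)
  d <- numeric(n)
  d[1L] <- (y[2L] - y[1L]) / (x[2L] - x[1L])
  d[n] <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
  if (n > 2L) {
    d[2:(n - 1L)] <- (y[3:n] - y[1:(n - 2L)]) / (x[3:n] - x[1:(n - 2L)])
  }
  d
}

# Assemble maximal runs of TRUE (split on sign change) into intervals.
collect_runs <- function(flag, sgn, time_b2k) {
  out <- data.frame(t_start_b2k = numeric(), t_end_b2k = numeric(),
                    sign = integer())
  key <- flag * sgn
  r <- rle(key)
  pos <- cumsum(c(1L, r$lengths))
  for (k in seq_along(r$values)) {
    if (r$values[k] == 0) next
    i0 <- pos[k]; i1 <- pos[k + 1L] - 1L
    out <- rbind(out, data.frame(t_start_b2k = time_b2k[i0],
                                 t_end_b2k = time_b2k[i1],
                                 sign = as.integer(r$values[k])))
  }
  out
}

#' Representative change points from significant intervals
#'
#' One age per significant-change interval: its midpoint, with the sign of
#' the change attached.
#'
#' @param result a `change_result` from [derivative_ci()].
#' @return data.frame `age_b2k, sign` (empty when no significant change).
#' @export
changepoints <- function(result) {
  stopifnot(inherits(result, "change_result"))
  si <- result$significant_intervals
  data.frame(age_b2k = (si$t_start_b2k + si$t_end_b2k) / 2,
             sign = si$sign)
}

#' Write a trend fit and its derivative diagnostics to CSV
#'
#' Columns: `time_b2k, fitted, deriv_mean, deriv_lo, deriv_hi, significant`
#' (0 outside significant intervals, otherwise the sign of the change).
#'
#' @param fit a `trend_fit`.
#' @param result the matching `change_result`.
#' @param path output path.
#' @export
write_trend_csv <- function(fit, result, path) {
  stopifnot(inherits(fit, "trend_fit"), inherits(result, "change_result"))
  sig <- integer(length(fit$time_b2k))
  si <- result$significant_intervals
  for (k in seq_len(nrow(si))) {
    inside <- fit$time_b2k <= si$t_start_b2k[k] &
      fit$time_b2k >= si$t_end_b2k[k]
    sig[inside] <- si$sign[k]
  }
  write.csv(data.frame(time_b2k = fit$time_b2k, fitted = fit$fitted,
                       deriv_mean = result$deriv_mean,
                       deriv_lo = result$deriv_lo,
                       deriv_hi = result$deriv_hi,
                       significant = sig),
            path, row.names = FALSE)
  invisible(path)
}
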