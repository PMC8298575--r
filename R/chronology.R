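#' Construct a table of dated horizons
#'
#' @param depth_cm depths (cm below surface), non-negative, strictly
#'   increasing.
#' @param age_b2k calibrated ages (cal yrs b2k).
#' @param age_err stated age uncertainties in years, at `sigma_convention`
#'   sigma.
#' @param sigma_convention multiplier k such that `age_err` is a k-sigma
#'   value (2 is the common marine convention here, 3 the lake one). Recycled.
#' @return a validated data.frame of class `dated_horizons`.
#' @export
dated_horizons <- function(depth_cm, age_b2k, age_err,
                           sigma_convention = 1) {
  stopifnot(length(depth_cm) == length(age_b2k),
            length(age_b2k) == length(age_err))
  if (any(depth_cm < 0)) stop("depths must be non-negative", call. = FALSE)
  stop_if_not_strictly_increasing(depth_cm, "horizon depths")
  if (any(age_err < 0)) stop("age_err must be non-negative", call. = FALSE)
  if (any(sigma_convention <= 0)) stop("sigma_convention must be positive", call. = FALSE)
  structure(
    data.frame(depth_cm = as.numeric(depth_cm), age_b2k = as.numeric(age_b2k),
               age_err = as.numeric(age_err),
               sigma_convention = rep_len(sigma_convention, length(depth_cm))),
    class = c("dated_horizons", "data.frame"))
}

#' Apply a marine reservoir offset to a radiocarbon-derived age
#'
#' Subtracts a local reservoir correction Delta-R from an age and combines
#' the two uncertainties in quadrature. The default offset of 140 +/- 60
#' years is appropriate for deep sites under the West Greenland Current.
#'
#' @param age age in years (vectorised).
#' @param age_sigma 1-sigma age uncertainty, years.
#' @param delta_r reservoir offset to subtract, years.
#' @param delta_r_sigma 1-sigma uncertainty of the offset, years.
#' @return list with elements `age` and `sigma`.
#' @examples
#' apply_reservoir_offset(1000, 50) # age 860, sigma sqrt(50^2 + 60^2)
#' @export
apply_reservoir_offset <- function(age, age_sigma, delta_r = 140,
                                   delta_r_sigma = 60) {
  if (any(age_sigma < 0) || any(delta_r_sigma < 0)) {
    stop("sigmas must be non-negative", call. = FALSE)
  }
  list(age = age - delta_r,
       sigma = sqrt(age_sigma^2 + delta_r_sigma^2))
}

#' Sample an ensemble of monotone age-depth models
#'
#' A deliberately simple perturb-project-interpolate sampler standing in for
#' full Bayesian accumulation modelling: each draw perturbs every dated
#' horizon by Gaussian noise at its 1-sigma magnitude (stated k-sigma
#' uncertainties are divided by their convention first), restores
#' monotonicity by isotonic (pool-adjacent-violators) projection of age on
#' depth, and interpolates piecewise-linearly onto the requested depth grid.
#' It reproduces depth-dependent dating uncertainty — the only property the
#' downstream Monte Carlo propagation consumes — but makes no attempt to
#' model accumulation-rate priors.
#'
#' @param horizons a [dated_horizons()] table (plain data.frames with the
#'   same columns are accepted).
#' @param n_draws number of realisations (>= 2).
#' @param depth_grid depths (cm) at which to evaluate the models; must lie
#'   within the dated span unless `extrapolate = TRUE`, in which case the
#'   end-interval accumulation rate is extended.
#' @param seed integer seed.
#' @param extrapolate allow constant-rate extension beyond the outermost
#'   dates (off by default).
#' @return an object of class `age_ensemble`: list with `depth_grid`,
#'   `draws` (n_draws x n_depths matrix, every row strictly increasing),
#'   `median_ages`, `p5`, `p95`, `n_draws`.
#' @export
sample_age_models <- function(horizons, n_draws = 1000L, depth_grid = NULL,
                              seed = NULL, extrapolate = FALSE) {
  h <- as.data.frame(horizons)
  req <- c("depth_cm", "age_b2k", "age_err")
  if (!all(req %in% names(h))) {
    stop("horizons must have columns ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (nrow(h) < 2L) stop("need at least 2 dated horizons", call. = FALSE)
  if (n_draws < 2L) stop("n_draws must be >= 2", call. = FALSE)
  stop_if_not_strictly_increasing(h$depth_cm, "horizon depths")
  k <- if ("sigma_convention" %in% names(h)) h$sigma_convention else 1
  sigma1 <- h$age_err / k

  if (is.null(depth_grid)) depth_grid <- h$depth_cm
  depth_grid <- sort(as.numeric(depth_grid))
  span <- range(h$depth_cm)
  outside <- depth_grid < span[1] | depth_grid > span[2]
  if (any(outside) && !extrapolate) {
    stop("depth_grid extends beyond the dated span [", span[1], ", ", span[2],
         "] cm; set extrapolate = TRUE for constant-rate extension",
         call. = FALSE)
  }

  n_h <- nrow(h)
  eps <- 1e-9 * max(1, diff(range(h$age_b2k)))
  draws <- with_seed(seed, {
    out <- matrix(NA_real_, n_draws, length(depth_grid))
    for (i in seq_len(n_draws)) {
      a <- h$age_b2k + rnorm(n_h, 0, sigma1)
      # isotonic least-squares projection onto non-decreasing ages,
      # then strictness via a cumulative epsilon across tied blocks only
      a <- isoreg(h$depth_cm, a)$yf
      d <- diff(a)
      if (any(d <= 0)) a <- a + eps * cumsum(c(0, d <= 0))
      out[i, ] <- interp_extrap(h$depth_cm, a, depth_grid, extrapolate)
    }
    out
  })
  qs <- apply(draws, 2L, quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
  structure(
    list(depth_grid = depth_grid, draws = draws,
         median_ages = qs[2L, ], p5 = qs[1L, ], p95 = qs[3L, ],
         n_draws = as.integer(n_draws)),
    class = "age_ensemble")
}

# Piecewise-linear interpolation with optional constant-rate extension.
interp_extrap <- function(x, y, xout, extrapolate) {
  res <- approx(x, y, xout = xout, rule = 1L, ties = "ordered")$y
  if (extrapolate && anyNA(res)) {
    n <- length(x)
    lo <- xout < x[1L]; hi <- xout > x[n]
    r0 <- (y[2L] - y[1L]) / (x[2L] - x[1L])
    r1 <- (y[n] - y[n - 1L]) / (x[n] - x[n - 1L])
    res[lo] <- y[1L] + (xout[lo] - x[1L]) * r0
    res[hi] <- y[n] + (xout[hi] - x[n]) * r1
  }
  res
}

#' @export
print.age_ensemble <- function(x, ...) {
  cat(sprintf("<age_ensemble> %d draws x %d depths, ages %.0f-%.0f yrs b2k (median)\n",
              x$n_draws, length(x$depth_grid),
              min(x$median_ages), max(x$median_ages)))
  invisible(x)
}

#' Sedimentation rates from an age ensemble
#'
#' Median accumulation rate per grid interval, computed as depth increment
#' over median-age increment, with a 90% envelope from the per-draw rates.
#' Intervals whose median-age increment is zero are dropped with a message.
#'
#' @param ensemble an `age_ensemble` from [sample_age_models()].
#' @return data.frame `depth_from, depth_to, rate_median, rate_p5, rate_p95`
#'   (cm yr-1).
#' @export
accumulation_rates <- function(ensemble) {
  stopifnot(inherits(ensemble, "age_ensemble"))
  dd <- diff(ensemble$depth_grid)
  da_med <- diff(ensemble$median_ages)
  keep <- da_med > 0
  if (!all(keep)) msg("dropping ", sum(!keep), " zero-age-increment interval(s)")
  da_draws <- ensemble$draws[, -1L, drop = FALSE] -
    ensemble$draws[, -ncol(ensemble$draws), drop = FALSE]
  rate_draws <- sweep(1 / da_draws, 2L, dd, `*`)
  qs <- apply(rate_draws[, keep, drop = FALSE], 2L, quantile,
              probs = c(0.05, 0.95), names = FALSE)
  data.frame(
    depth_from = ensemble$depth_grid[-length(ensemble$depth_grid)][keep],
    depth_to = ensemble$depth_grid[-1L][keep],
    rate_median = (dd / da_med)[keep],
    rate_p5 = qs[1L, ], rate_p95 = qs[2L, ])
}

#' Read dated horizons / write an age-model summary
#'
#' `read_dates_csv` expects columns `depth_cm, age_b2k, age_err,
#' sigma_convention` with a header row and '.' decimal separator.
#' `write_agemodel_csv` writes `depth_cm, age_median, age_p5, age_p95`.
#'
#' @param path CSV file path.
#' @param ensemble an `age_ensemble`.
#' @return `read_dates_csv`: a [dated_horizons()] table.
#' @export
read_dates_csv <- function(path) {
  d <- read.csv(path)
  dated_horizons(d$depth_cm, d$age_b2k, d$age_err,
                 if ("sigma_convention" %in% names(d)) d$sigma_convention else 1)
}

#' @rdname read_dates_csv
#' @export
write_agemodel_csv <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "age_ensemble"))
  write.csv(data.frame(depth_cm = ensemble$depth_grid,
                       age_median = ensemble$median_ages,
                       age_p5 = ensemble$p5, age_p95 = ensemble$p95),
            path, row.names = FALSE)
  invisible(path)
}
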