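#' Monte Carlo propagation of measurement and dating uncertainty
#'
#' Propagates the two uncertainty sources of a depth-indexed proxy series
#' onto a common time grid. Each of `n_draws` realisations pairs one
#' age-model draw (draw i of the ensemble uses age realisation i — joint
#' propagation) with one measurement-noise realisation (relative noise:
#' `value * (1 + e)`, absolute: `value + e`, `e ~ N(0, sigma)`), and linearly
#' interpolates the perturbed (age, value) path onto `time_grid`. The draws
#' are summarised per grid time by their median (the "most likely" series),
#' the 5th/95th percentiles (a 90% confidence envelope), and a 2D frequency
#' histogram of value against time.
#'
#' The default time grid runs in 20-year steps over the intersection of all
#' draws' age spans, so every draw contributes to every grid time and each
#' histogram column sums exactly to `n_draws`. Grid points supplied outside
#' that intersection are dropped with a message.
#'
#' @param series a [proxy_series()] whose depths lie within the ensemble's
#'   depth grid.
#' @param ages an `age_ensemble` from [sample_age_models()] with at least
#'   `n_draws` draws.
#' @param n_draws number of Monte Carlo realisations (>= 100; 10,000 for
#'   production runs).
#' @param time_grid ages (yrs b2k) at which to summarise; `NULL` for the
#'   default grid.
#' @param time_step grid step in years for the default grid.
#' @param n_value_bins number of equal-width value bins for the 2D
#'   histogram.
#' @param seed integer seed for the measurement noise.
#' @param keep_draws retain the draw matrix in the result (needed for
#'   envelope-coverage checks).
#' @return an object of class `ensemble_summary`: list with `name`,
#'   `time_grid`, `median`, `p5`, `p95`, `density` (value bins x time),
#'   `value_breaks`, `n_draws`, and `draws` if kept.
#' @export
simulate_ensemble <- function(series, ages, n_draws = 10000L,
                              time_grid = NULL, time_step = 20,
                              n_value_bins = 50L, seed = NULL,
                              keep_draws = TRUE) {
  stopifnot(inherits(series, "proxy_series"), inherits(ages, "age_ensemble"))
  if (n_draws < 100L) stop("n_draws must be >= 100", call. = FALSE)
  if (ages$n_draws < n_draws) {
    stop("age ensemble has ", ages$n_draws, " draws; need >= ", n_draws,
         call. = FALSE)
  }
  dg <- ages$depth_grid
  s <- series$depth
  if (min(s) < min(dg) || max(s) > max(dg)) {
    stop("series depths extend beyond the age-model depth grid", call. = FALSE)
  }

  # ages of every draw at the series' sample depths, by shared linear weights
  j <- pmin(findInterval(s, dg), length(dg) - 1L)
  w <- (s - dg[j]) / (dg[j + 1L] - dg[j])
  A <- ages$draws[seq_len(n_draws), j, drop = FALSE] * rep(1 - w, each = n_draws) +
    ages$draws[seq_len(n_draws), j + 1L, drop = FALSE] * rep(w, each = n_draws)

  # one measurement-noise realisation per draw
  V <- with_seed(seed, {
    eps <- matrix(rnorm(n_draws * length(s), 0, series$meas_unc$magnitude),
                  n_draws, length(s))
    if (series$meas_unc$mode == "relative") {
      rep(series$value, each = n_draws) * (1 + eps)
    } else {
      rep(series$value, each = n_draws) + eps
    }
  })

  # common span every draw covers
  lo <- max(A[, 1L]); hi <- min(A[, ncol(A)])
  if (is.null(time_grid)) {
    time_grid <- seq(ceiling(lo / time_step) * time_step,
                     floor(hi / time_step) * time_step, by = time_step)
  } else {
    drop <- time_grid < lo | time_grid > hi
    if (any(drop)) {
      msg("dropping ", sum(drop),
          " time-grid point(s) outside the common age span of all draws")
      time_grid <- time_grid[!drop]
    }
  }
  if (!length(time_grid)) stop("empty time grid after span restriction", call. = FALSE)

  Y <- matrix(NA_real_, n_draws, length(time_grid))
  for (i in seq_len(n_draws)) {
    Y[i, ] <- approx(A[i, ], V[i, ], xout = time_grid, ties = "ordered")$y
  }

  qs <- apply(Y, 2L, quantile, probs = c(0.05, 0.5, 0.95), names = FALSE)
  rng <- range(Y)
  if (rng[1L] == rng[2L]) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1L], rng[2L], length.out = n_value_bins + 1L)
  dens <- apply(Y, 2L, function(col) {
    tabulate(findInterval(col, breaks, rightmost.closed = TRUE),
             nbins = n_value_bins)
  })

  structure(
    list(name = series$name, time_grid = time_grid,
         median = qs[2L, ], p5 = qs[1L, ], p95 = qs[3L, ],
         density = dens, value_breaks = breaks,
         n_draws = as.integer(n_draws),
         draws = if (keep_draws) Y else NULL),
    class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary '%s'> %d draws x %d times, %.0f-%.0f yrs b2k\n",
              x$name, x$n_draws, length(x$time_grid),
              min(x$time_grid), max(x$time_grid)))
  invisible(x)
}

#' Fraction of ensemble draws inside the confidence envelope
#'
#' Per grid time, the fraction of Monte Carlo draw values lying inside
#' `[p5, p95]`. By construction this is 90% up to quantile interpolation and
#' ties.
#'
#' @param summary an `ensemble_summary` built with `keep_draws = TRUE`.
#' @return numeric vector of per-time coverage fractions.
#' @export
envelope_coverage <- function(summary) {
  stopifnot(inherits(summary, "ensemble_summary"))
  if (is.null(summary$draws)) {
    stop("summary was built with keep_draws = FALSE", call. = FALSE)
  }
  inside <- sweep(summary$draws, 2L, summary$p5, `>=`) &
    sweep(summary$draws, 2L, summary$p95, `<=`)
  colMeans(inside)
}

#' Principal component synthesis of median proxy series
#'
#' Z-scores each proxy's median time series over time and eigendecomposes
#' their correlation matrix. Components are ordered by decreasing
#' eigenvalue; loading columns are orthonormal; the sign of each component
#' is fixed so that `orient_proxy` loads positively (the component scale is
#' otherwise sign-ambiguous).
#'
#' @param summaries list of `ensemble_summary` objects on an identical time
#'   grid (at least two), each with nonzero variance.
#' @param orient_proxy name of the proxy whose loading fixes the sign
#'   convention; defaults to the first summary.
#' @return an object of class `pc_synthesis`: `loadings` (proxies x
#'   components), `var_explained` (fractions summing to 1), `scores`,
#'   `pc1_series`, `time_grid`, `sign_convention`; `pc1_lo`/`pc1_hi` are
#'   filled by [propagate_pc_envelope()].
#' @export
pca_median <- function(summaries, orient_proxy = NULL) {
  stopifnot(is.list(summaries), length(summaries) >= 2L)
  nms <- unname(vapply(summaries, function(s) s$name, character(1L)))
  tg <- summaries[[1L]]$time_grid
  for (s in summaries) {
    stopifnot(inherits(s, "ensemble_summary"))
    if (!isTRUE(all.equal(s$time_grid, tg))) {
      stop("summaries are not on a common time grid", call. = FALSE)
    }
  }
  M <- vapply(summaries, function(s) s$median, numeric(length(tg)))
  colnames(M) <- nms
  sds <- apply(M, 2L, sd)
  if (any(sds == 0)) {
    stop("zero-variance median series: ", paste(nms[sds == 0], collapse = ", "),
         call. = FALSE)
  }
  Z <- scale(M)
  R <- stats::cor(M)
  e <- eigen(R, symmetric = TRUE)
  L <- e$vectors
  if (is.null(orient_proxy)) orient_proxy <- nms[1L]
  oi <- match(orient_proxy, nms)
  if (is.na(oi)) stop("orient_proxy '", orient_proxy, "' not among series", call. = FALSE)
  for (c in seq_len(ncol(L))) {
    if (L[oi, c] < 0) L[, c] <- -L[, c]
  }
  dimnames(L) <- list(nms, paste0("PC", seq_len(ncol(L))))
  scores <- Z %*% L
  structure(
    list(loadings = L, var_explained = e$values / sum(e$values),
         scores = scores, pc1_series = scores[, 1L],
         pc1_lo = NULL, pc1_hi = NULL, time_grid = tg,
         sign_convention = paste0("positive loading of '", orient_proxy, "'")),
    class = "pc_synthesis")
}

#' @export
print.pc_synthesis <- function(x, ...) {
  cat(sprintf("<pc_synthesis> %d proxies, PC1 explains %.1f%% (sign: %s)\n",
              nrow(x$loadings), 100 * x$var_explained[1L], x$sign_convention))
  print(round(x$loadings, 3))
  invisible(x)
}

#' Propagate Monte Carlo envelopes onto the first principal component
#'
#' Bounds PC1 by the fractional mean uncertainties of its constituent
#' series: for each proxy, `f_i` is the time-mean of the envelope half-width
#' relative to the median magnitude, `(p95 - p5) / (2 * |median|)` (where
#' `|median|` falls below 5% of its time-mean it is floored there, so
#' near-zero crossings do not blow up the fraction); the PC1 envelope
#' half-width at each time is `|PC1|` times the loading-weighted mean
#' `sum(|l_i| * f_i) / sum(|l_i|)`. This yields the vertical (magnitude)
#' envelope. When an `age_ensemble` is supplied, a horizontal (time)
#' envelope is also computed by mapping each grid time through the
#' ensemble's 5th/95th-percentile age-depth relations.
#'
#' @param synthesis a `pc_synthesis` built from `summaries`.
#' @param summaries the same list of `ensemble_summary` objects.
#' @param ages optional `age_ensemble` for the time envelope.
#' @return the synthesis with `pc1_lo`, `pc1_hi` (and `time_envelope`, a
#'   data.frame `time, time_early, time_late`, when `ages` is given) filled.
#' @export
propagate_pc_envelope <- function(synthesis, summaries, ages = NULL) {
  stopifnot(inherits(synthesis, "pc_synthesis"), length(summaries) >= 2L)
  nms <- unname(vapply(summaries, function(s) s$name, character(1L)))
  if (!identical(nms, rownames(synthesis$loadings))) {
    stop("summaries do not match the synthesis' proxies", call. = FALSE)
  }
  f <- vapply(summaries, function(s) {
    hw <- (s$p95 - s$p5) / 2
    scale <- mean(abs(s$median))
    if (scale == 0) return(mean(hw))
    mean(hw / pmax(abs(s$median), 0.05 * scale))
  }, numeric(1L))
  l1 <- abs(synthesis$loadings[, 1L])
  f_pc <- sum(l1 * f) / sum(l1)
  hw <- abs(synthesis$pc1_series) * f_pc
  synthesis$pc1_lo <- synthesis$pc1_series - hw
  synthesis$pc1_hi <- synthesis$pc1_series + hw
  synthesis$fractional_uncertainty <- setNames(f, nms)
  if (!is.null(ages)) {
    stopifnot(inherits(ages, "age_ensemble"))
    # invert the median age-depth relation, then read off the envelope ages
    d_at_t <- approx(ages$median_ages, ages$depth_grid,
                     xout = synthesis$time_grid, rule = 2L, ties = "ordered")$y
    synthesis$time_envelope <- data.frame(
      time = synthesis$time_grid,
      time_early = approx(ages$depth_grid, ages$p95, xout = d_at_t,
                          ties = "ordered")$y,
      time_late = approx(ages$depth_grid, ages$p5, xout = d_at_t,
                         ties = "ordered")$y)
  }
  synthesis
}

#' Write ensemble and PCA results to CSV
#'
#' `write_ensemble_csv` writes `time_b2k, median, p5, p95`;
#' `write_density_csv` writes the 2D histogram in long form
#' (`time_bin, value_bin, count`); `write_pca_csv` writes a loadings block
#' followed by the PC time-series block, separated by a blank line.
#'
#' @param summary an `ensemble_summary`.
#' @param synthesis a `pc_synthesis`.
#' @param path output file path.
#' @export
write_ensemble_csv <- function(summary, path) {
  stopifnot(inherits(summary, "ensemble_summary"))
  write.csv(data.frame(time_b2k = summary$time_grid, median = summary$median,
                       p5 = summary$p5, p95 = summary$p95),
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
write_density_csv <- function(summary, path) {
  stopifnot(inherits(summary, "ensemble_summary"))
  nb <- nrow(summary$density)
  mids <- (summary$value_breaks[-1L] + summary$value_breaks[-(nb + 1L)]) / 2
  long <- data.frame(
    time_bin = rep(summary$time_grid, each = nb),
    value_bin = rep(mids, times = length(summary$time_grid)),
    count = as.vector(summary$density))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble_csv
#' @export
write_pca_csv <- function(synthesis, path) {
  stopifnot(inherits(synthesis, "pc_synthesis"))
  con <- file(path, "w")
  ld <- data.frame(proxy = rownames(synthesis$loadings),
                   round(synthesis$loadings, 6))
  writeLines("# loadings (columns PC1..; var_explained in last row)", con)
  write.table(ld, con, sep = ",", row.names = FALSE, quote = FALSE)
  writeLines(paste(c("var_explained",
                     round(synthesis$var_explained, 6)), collapse = ","), con)
  writeLines("", con)
  ts <- data.frame(time_b2k = synthesis$time_grid,
                   pc1 = synthesis$pc1_series)
  if (!is.null(synthesis$pc1_lo)) {
    ts$pc1_lo <- synthesis$pc1_lo
    ts$pc1_hi <- synthesis$pc1_hi
  }
  write.table(ts, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}
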