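#' Convert a concentration series to a flux series
#'
#' Multiplies per-mass concentrations (e.g. diatom valves per gram) by mass
#' accumulation rates to obtain fluxes per area and year. Depth vectors must
#' match exactly; unit strings are composed, never inferred.
#'
#' @param concentration [proxy_series()] of concentrations (e.g. ind g-1).
#' @param mar [proxy_series()] or numeric vector of mass accumulation rates
#'   (g cm-2 yr-1), aligned on the same depths, strictly positive.
#' @param units unit string for the result.
#' @return a [proxy_series()] of fluxes, inheriting the concentration
#'   series' uncertainty model.
#' @export
compute_flux <- function(concentration, mar, units = NULL) {
  stopifnot(inherits(concentration, "proxy_series"))
  mv <- if (inherits(mar, "proxy_series")) {
    if (!isTRUE(all.equal(mar$depth, concentration$depth))) {
      stop("concentration and MAR depths do not match", call. = FALSE)
    }
    mar$value
  } else {
    if (length(mar) != length(concentration$depth)) {
      stop("MAR length does not match concentration depths", call. = FALSE)
    }
    as.numeric(mar)
  }
  if (any(mv <= 0)) stop("mass accumulation rates must be positive", call. = FALSE)
  if (is.null(units)) {
    units <- sub(" g-1", " cm-2 yr-1", concentration$units, fixed = TRUE)
  }
  proxy_series(paste0(concentration$name, "_flux"),
               concentration$depth, concentration$value * mv, units = units,
               unc_mode = concentration$meas_unc$mode,
               unc_magnitude = concentration$meas_unc$magnitude)
}

#' Normalise a biomarker concentration by total organic carbon
#'
#' Expresses a sediment biomarker concentration per gram of organic carbon:
#' `value / (toc / 100)` with TOC in percent weight. Samples with
#' non-positive TOC are set to `NA` with a warning.
#'
#' @param value biomarker concentrations (e.g. ng g-1 sediment).
#' @param toc_percent total organic carbon, percent dry weight.
#' @return concentrations per gram TOC.
#' @export
toc_normalise <- function(value, toc_percent) {
  stopifnot(length(value) == length(toc_percent))
  bad <- toc_percent <= 0
  if (any(bad)) {
    warning(sum(bad), " sample(s) with TOC <= 0% set to NA", call. = FALSE)
  }
  out <- value / (toc_percent / 100)
  out[bad] <- NA_real_
  out
}

#' Cholesterol fraction of total sterols
#'
#' The seabird-influence sterol index: cholesterol divided by cholesterol
#' plus beta-sitosterol. Marine zooplankton (and hence planktivorous seabird
#' guano) are cholesterol-rich and essentially sitosterol-free, while
#' terrestrial and freshwater primary producers are sitosterol-rich, so the
#' index approaches 1 under strong seabird influence and 0 without it. The
#' index is scale-invariant in the two concentrations. Samples where both
#' sterols are zero are undefined and returned as `NA` with a warning.
#'
#' @param cholesterol,beta_sitosterol concentrations in common units
#'   (e.g. ug g-1), non-negative, vectorised.
#' @return ratio in `[0, 1]`.
#' @examples
#' sterol_index(1497, 15) # little-auk-like excrement, ~0.99
#' sterol_index(16, 159)  # goose-like excrement, ~0.09
#' @export
sterol_index <- function(cholesterol, beta_sitosterol) {
  stopifnot(length(cholesterol) == length(beta_sitosterol))
  if (any(cholesterol < 0) || any(beta_sitosterol < 0)) {
    stop("sterol concentrations must be non-negative", call. = FALSE)
  }
  tot <- cholesterol + beta_sitosterol
  und <- tot == 0
  if (any(und)) {
    warning(sum(und), " sample(s) with both sterols zero set to NA", call. = FALSE)
  }
  out <- cholesterol / tot
  out[und] <- NA_real_
  out
}

#' Fractional sterol: sterol flux weighted by its marine fraction
#'
#' Multiplies the total sterol flux by the [sterol_index()] so that the two
#' sterol measurements enter a principal component analysis as a single
#' seabird-influence variable rather than two correlated ones.
#'
#' @param sterol_flux flux (mg cm-2 yr-1), non-negative.
#' @param index sterol index in `[0, 1]`.
#' @return weighted flux, same units as `sterol_flux`.
#' @export
fractional_sterol <- function(sterol_flux, index) {
  stopifnot(length(sterol_flux) == length(index))
  if (any(sterol_flux < 0, na.rm = TRUE)) {
    stop("sterol flux must be non-negative", call. = FALSE)
  }
  if (any(index < 0 | index > 1, na.rm = TRUE)) {
    stop("sterol index must lie in [0, 1]", call. = FALSE)
  }
  sterol_flux * index
}

#' Cd:Ti ratio from XRF scanner counts
#'
#' Bins high-resolution XRF count readings into intervals of at least
#' `bin_mm` and forms the cadmium-to-titanium count ratio per bin. Summing
#' before dividing stabilises the ratio where dwell-time counts of the
#' scarcer element are low. Bins whose Ti total is zero are dropped with a
#' warning.
#'
#' @param depth_mm reading depths in mm, strictly increasing.
#' @param cd,ti counts per reading, non-negative.
#' @param bin_mm bin width in mm (default 1, the minimum recommended for
#'   low-count elements; configurable upward).
#' @return data.frame `depth_mm` (bin midpoint) and `cd_ti`.
#' @export
cd_ti_ratio <- function(depth_mm, cd, ti, bin_mm = 1) {
  stopifnot(length(depth_mm) == length(cd), length(cd) == length(ti),
            bin_mm > 0)
  stop_if_not_strictly_increasing(depth_mm, "XRF depths")
  if (any(cd < 0) || any(ti < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  bin <- floor((depth_mm - depth_mm[1L]) / bin_mm)
  cd_s <- tapply(cd, bin, sum)
  ti_s <- tapply(ti, bin, sum)
  mid <- tapply(depth_mm, bin, function(d) mean(range(d)))
  keep <- ti_s > 0
  if (!all(keep)) {
    warning(sum(!keep), " bin(s) with zero Ti counts dropped", call. = FALSE)
  }
  data.frame(depth_mm = as.numeric(mid[keep]),
             cd_ti = as.numeric(cd_s[keep] / ti_s[keep]),
             row.names = NULL)
}

#' Relative abundances from an assemblage count table
#'
#' Converts per-taxon valve counts to percentages of the per-sample total.
#' Samples counted below `min_count` valves (the conventional quantitative
#' threshold is 400) trigger a warning; samples with zero total are an
#' error.
#'
#' @param counts data.frame with a `depth_cm` column and one non-negative
#'   integer count column per taxon.
#' @param min_count minimum total valves per sample for a quantitative
#'   sample.
#' @return data.frame of the same shape with taxa as percentages; each row
#'   of taxon columns sums to 100.
#' @export
relative_abundance <- function(counts, min_count = 400L) {
  stopifnot(is.data.frame(counts), "depth_cm" %in% names(counts))
  taxa <- setdiff(names(counts), "depth_cm")
  if (!length(taxa)) stop("no taxon columns", call. = FALSE)
  m <- as.matrix(counts[taxa])
  if (any(m < 0) || any(m != round(m))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  tot <- rowSums(m)
  if (any(tot == 0)) {
    stop("sample(s) with zero total counts at depth(s) ",
         paste(counts$depth_cm[tot == 0], collapse = ", "), call. = FALSE)
  }
  low <- tot < min_count
  if (any(low)) {
    warning(sum(low), " sample(s) below the ", min_count,
            "-valve quantitative threshold", call. = FALSE)
  }
  out <- counts
  out[taxa] <- 100 * m / tot
  out
}

#' Ordinate a diatom assemblage and collapse it to a single index
#'
#' `assemblage_pca()` runs a principal component analysis on centred,
#' standardised, square-root-transformed relative abundances (the square
#' root is applied to proportions in `[0, 1]`; standardisation removes the
#' resulting constant factor). `diatom_index()` then combines the first two
#' component score series into one index by a weighted sum proportional to
#' the variance fraction each component explains, so the assemblage enters a
#' multi-proxy synthesis as one variable.
#'
#' @param rel_abund output of [relative_abundance()] (percentages with a
#'   `depth_cm` column).
#' @return `assemblage_pca`: list with `scores` (samples x components),
#'   `var_explained` (fractions summing to 1), `loadings`, `depth_cm`.
#' @export
assemblage_pca <- function(rel_abund) {
  stopifnot(is.data.frame(rel_abund), "depth_cm" %in% names(rel_abund))
  taxa <- setdiff(names(rel_abund), "depth_cm")
  x <- sqrt(as.matrix(rel_abund[taxa]) / 100)
  keep <- apply(x, 2L, sd) > 0
  if (!all(keep)) msg("dropping ", sum(!keep), " zero-variance taxa from PCA")
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  list(scores = p$x, var_explained = p$sdev^2 / sum(p$sdev^2),
       loadings = p$rotation, depth_cm = rel_abund$depth_cm)
}

#' @rdname assemblage_pca
#' @param pc_scores matrix or data.frame with two columns: the PC1 and PC2
#'   score series.
#' @param var_explained length-2 positive weights, the variance fractions of
#'   the two components (e.g. `c(0.34, 0.27)`).
#' @return `diatom_index`: numeric index series,
#'   `(v1*PC1 + v2*PC2) / (v1 + v2)`.
#' @export
diatom_index <- function(pc_scores, var_explained) {
  pc_scores <- as.matrix(pc_scores)
  if (ncol(pc_scores) != 2L || length(var_explained) != 2L) {
    stop("need two score series and two variance fractions", call. = FALSE)
  }
  if (any(var_explained < 0) || sum(var_explained) == 0) {
    stop("variance fractions must be non-negative and not all zero",
         call. = FALSE)
  }
  as.numeric(pc_scores %*% var_explained) / sum(var_explained)
}

#' Read a proxy measurement table / write derived series
#'
#' `read_proxies_csv` reads the `proxies.csv` dialect: a header row of
#' column names, a second header line `#units:cm,<unit>,...`, then data rows
#' with '.' decimal separator. Returns a named list of [proxy_series()] (a
#' measurement-uncertainty model can be attached per column via `unc`).
#' `write_derived_csv` writes depth plus derived series columns.
#'
#' @param path CSV path.
#' @param unc optional named list of `list(mode=, magnitude=)` per column.
#' @export
read_proxies_csv <- function(path, unc = NULL) {
  lines <- readLines(path, n = 2L)
  cols <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  units <- rep("", length(cols))
  skip <- 1L
  if (startsWith(lines[2L], "#units:")) {
    units <- strsplit(sub("^#units:", "", lines[2L]), ",", fixed = TRUE)[[1L]]
    skip <- 2L
  }
  d <- read.csv(path, header = FALSE, skip = skip, col.names = cols)
  if (!"depth_cm" %in% cols) stop("proxies.csv needs a depth_cm column", call. = FALSE)
  out <- list()
  for (i in seq_along(cols)) {
    nm <- cols[i]
    if (nm == "depth_cm") next
    u <- if (!is.null(unc) && nm %in% names(unc)) unc[[nm]] else
      list(mode = "relative", magnitude = 0)
    out[[nm]] <- proxy_series(nm, d$depth_cm, d[[nm]], units = units[i],
                              unc_mode = u$mode, unc_magnitude = u$magnitude)
  }
  out
}

#' @rdname read_proxies_csv
#' @param series named list of [proxy_series()] on a common depth vector.
#' @export
write_derived_csv <- function(series, path) {
  tab <- data.frame(depth_cm = series[[1L]]$depth)
  for (ps in series) tab[[ps$name]] <- ps$value
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
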