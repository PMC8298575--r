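#' Depth-indexed proxy measurement series
#'
#' Container for one measured proxy: strictly increasing depths, finite
#' values, a units string (carried verbatim, never inferred), and a
#' measurement-uncertainty model used by the Monte Carlo propagation.
#'
#' @param name identifier, e.g. `"diatom_flux"`.
#' @param depth depths in cm below surface, strictly increasing.
#' @param value measurements, finite, same length as `depth`.
#' @param units unit string, e.g. `"ind cm-2 yr-1"`.
#' @param unc_mode `"relative"` (noise sd as a fraction of the value, in
#'   `[0, 1]`) or `"absolute"` (noise sd in measurement units, `>= 0`).
#' @param unc_magnitude the 1-sigma noise magnitude under `unc_mode`.
#' @return an object of class `proxy_series`.
#' @export
proxy_series <- function(name, depth, value, units = "",
                         unc_mode = c("relative", "absolute"),
                         unc_magnitude = 0) {
  unc_mode <- match.arg(unc_mode)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stop_if_not_strictly_increasing(depth, paste0("depth of '", name, "'"))
  if (length(value) != length(depth) || any(!is.finite(value))) {
    stop("values of '", name, "' must be finite and match depth length",
         call. = FALSE)
  }
  if (unc_mode == "relative" && (unc_magnitude < 0 || unc_magnitude > 1)) {
    stop("relative uncertainty magnitude must lie in [0, 1]", call. = FALSE)
  }
  if (unc_magnitude < 0) stop("uncertainty magnitude must be >= 0", call. = FALSE)
  structure(
    list(name = name, depth = as.numeric(depth), value = as.numeric(value),
         units = units,
         meas_unc = list(mode = unc_mode, magnitude = unc_magnitude)),
    class = "proxy_series")
}

#' @export
print.proxy_series <- function(x, ...) {
  cat(sprintf("<proxy_series '%s'> %d samples, %.1f-%.1f cm, units '%s', %s unc %g\n",
              x$name, length(x$depth), min(x$depth), max(x$depth), x$units,
              x$meas_unc$mode, x$meas_unc$magnitude))
  invisible(x)
}
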