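#' Signal library for synthetic proxy histories
#'
#' Constructors returning functions of age (cal yrs b2k) that describe a true
#' proxy history. Ages count backwards from the year 2000, so "before" a
#' change means *older*, i.e. larger age. The library is deliberately small —
#' constant, linear ramp, hard step, logistic step — which is enough to
#' emulate the abrupt transitions and gradual declines seen in late-Holocene
#' proxy records.
#'
#' @param value constant value (`sig_constant`).
#' @param age_old,age_young ages (yrs b2k) bounding a ramp; `age_old >
#'   age_young`.
#' @param value_old,value_young values at (and beyond) the old and young ends.
#' @param age_change age (yrs b2k) of a step or logistic midpoint.
#' @param width logistic transition width in years (the transition runs over
#'   roughly `width` years centred on `age_change`).
#' @return a vectorised function `age -> value`.
#' @examples
#' f <- sig_step(age_change = 2200, value_old = 2, value_young = 0.8)
#' f(c(3000, 1000)) # 2 before (older than) the step, 0.8 after
#' @name signals
NULL

#' @rdname signals
#' @export
sig_constant <- function(value) {
  force(value)
  function(age) rep_len(value, length(age))
}

#' @rdname signals
#' @export
sig_ramp <- function(age_old, age_young, value_old, value_young) {
  stopifnot(age_old > age_young)
  function(age) {
    w <- (age_old - age) / (age_old - age_young)
    w <- pmin(pmax(w, 0), 1)
    value_old + w * (value_young - value_old)
  }
}

#' @rdname signals
#' @export
sig_step <- function(age_change, value_old, value_young) {
  function(age) ifelse(age > age_change, value_old, value_young)
}

#' @rdname signals
#' @export
sig_logistic <- function(age_change, value_old, value_young, width = 100) {
  stopifnot(width > 0)
  # plogis scale chosen so ~98% of the transition happens within `width` yrs
  function(age) {
    value_old + (value_young - value_old) *
      plogis((age_change - age) / (width / 8))
  }
}
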