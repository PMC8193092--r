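# Three-parameter logistic accumulation model and derived rate quantities.
#
# The cumulative trajectory of biomass (g/individual) or nutrient uptake
# (mg/individual) over weeks since seedling emergence is
#   NU(t) = NU_max / (1 + exp(r * (t_max - t)))
# with asymptote NU_max, relative rate r (week^-1) and inflection week t_max,
# where the instantaneous rate dNU/dt = r * NU * (1 - NU/NU_max) peaks at
# I_max = r * NU_max / 4.

# exp() overflows past ~709.78 in double precision; clamping keeps the
# logistic exact (the clamped tail is already 0 or NU_max to machine eps).
.EXP_CAP <- 709

#' Logistic trajectory parameters
#'
#' Bundle and validate the three parameters of the logistic accumulation
#' model: the asymptote `nu_max` (maximum cumulative uptake or biomass per
#' individual; g for biomass, mg for N and P), the relative rate `r`
#' (week^-1) and the inflection week `t_max`, at which the instantaneous
#' accumulation rate peaks and the cumulative curve reaches half saturation.
#'
#' @param nu_max Asymptote, must be > 0.
#' @param r Relative rate per week, must be > 0.
#' @param t_max Week of peak instantaneous rate; any finite number.
#' @return An object of class `logistic_params` (a named list).
#' @examples
#' p <- logistic_params(nu_max = 10, r = 1, t_max = 5)
#' logistic_value(p, 5) # half saturation: 5
#' @export
logistic_params <- function(nu_max, r, t_max) {
  stopifnot(
    is.numeric(nu_max), length(nu_max) == 1L, is.finite(nu_max), nu_max > 0,
    is.numeric(r), length(r) == 1L, is.finite(r), r > 0,
    is.numeric(t_max), length(t_max) == 1L, is.finite(t_max)
  )
  structure(
    list(nu_max = as.numeric(nu_max), r = as.numeric(r),
         t_max = as.numeric(t_max)),
    class = "logistic_params"
  )
}

#' @export
print.logistic_params <- function(x, ...) {
  cat(sprintf("<logistic_params> NU_max = %g, r = %g /week, t_max = %g weeks\n",
              x$nu_max, x$r, x$t_max))
  invisible(x)
}

as_logistic_params <- function(x) {
  if (inherits(x, "logistic_params")) return(x)
  if (is.list(x) || (is.numeric(x) && !is.null(names(x)))) {
    x <- as.list(x)
    if (all(c("nu_max", "r", "t_max") %in% names(x))) {
      return(logistic_params(x$nu_max, x$r, x$t_max))
    }
  }
  stop("cannot interpret `params` as logistic parameters; ",
       "expected fields nu_max, r, t_max", call. = FALSE)
}

#' Cumulative value of the logistic accumulation curve
#'
#' Evaluates NU(t) = NU_max / (1 + exp(r * (t_max - t))). The curve is
#' strictly increasing in `t`, bounded in (0, NU_max), equals NU_max/2 at
#' `t = t_max`, and is point-symmetric about (t_max, NU_max/2).
#'
#' @param params A [logistic_params()] object (or named list/vector with
#'   fields `nu_max`, `r`, `t_max`).
#' @param t Week(s) since seedling emergence; vectorised.
#' @return Numeric vector of cumulative amounts, same length as `t`.
#' @export
logistic_value <- function(params, t) {
  p <- as_logistic_params(params)
  stopifnot(is.numeric(t))
  x <- pmin(pmax(p$r * (p$t_max - t), -.EXP_CAP), .EXP_CAP)
  p$nu_max / (1 + exp(x))
}

#' Instantaneous accumulation rate of the logistic curve
#'
#' Evaluates dNU/dt = r * NU(t) * (1 - NU(t)/NU_max), the instantaneous
#' biomass accumulation (g individual^-1 week^-1) or nutrient uptake rate
#' (mg individual^-1 week^-1). The rate is non-negative and unimodal in `t`
#' with its mode at `t_max`.
#'
#' @inheritParams logistic_value
#' @return Numeric vector of rates, same length as `t`.
#' @export
instantaneous_rate <- function(params, t) {
  p <- as_logistic_params(params)
  nu <- logistic_value(p, t)
  p$r * nu * (1 - nu / p$nu_max)
}

#' Peak instantaneous rate and its timing
#'
#' The maximum of the instantaneous rate over time has the closed form
#' I_max = r * NU_max / 4 and occurs at `t_max` (half saturation of the
#' cumulative curve).
#'
#' @inheritParams logistic_value
#' @return A list of class `peak_rate` with elements `i_max` (per week) and
#'   `t_at_peak` (weeks).
#' @examples
#' peak_rate(logistic_params(10, 1, 5)) # i_max 2.5 at week 5
#' @export
peak_rate <- function(params) {
  p <- as_logistic_params(params)
  structure(list(i_max = p$r * p$nu_max / 4, t_at_peak = p$t_max),
            class = "peak_rate")
}

#' @export
print.peak_rate <- function(x, ...) {
  cat(sprintf("<peak_rate> I_max = %g per week at week %g\n",
              x$i_max, x$t_at_peak))
  invisible(x)
}

#' Convert a weekly rate to a daily rate
#'
#' Rates are modelled on the weekly harvest axis (r in week^-1, I_max per
#' week); divide by 7 to report per-day rates.
#'
#' @param rate_per_week Numeric vector of weekly rates.
#' @return The same rates per day.
#' @export
weekly_to_daily <- function(rate_per_week) rate_per_week / 7
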