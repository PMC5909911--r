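#' Convert a drug half-life to an exponential decay rate
#'
#' The concentration model assumes first-order elimination, so the decay rate
#' \eqn{\alpha} and the physiological half-life are linked by
#' \eqn{T_{1/2} = \ln 2 / \alpha}.
#'
#' @param half_life Half-life in hours (strictly positive).
#' @return Decay rate in units of 1/hour.
#' @seealso [half_life_from_rate()]
#' @examples
#' rate_from_half_life(12)    # twice-daily dosing interval
#' @export
rate_from_half_life <- function(half_life) {
  if (!is.numeric(half_life) || any(!is.finite(half_life)) || any(half_life <= 0)) {
    stop("`half_life` must be a finite positive number of hours", call. = FALSE)
  }
  log(2) / half_life
}

#' Convert an exponential decay rate to a half-life
#'
#' @param alpha Decay rate per hour (strictly positive).
#' @return Half-life in hours.
#' @seealso [rate_from_half_life()]
#' @export
half_life_from_rate <- function(alpha) {
  if (!is.numeric(alpha) || any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("`alpha` must be a finite positive rate per hour", call. = FALSE)
  }
  log(2) / alpha
}

#' Model parameters for the time-above-threshold adherence metric
#'
#' Bundles the four physiological parameters of the metric: the drug decay
#' rate `alpha` (per hour), the threshold sharpness `beta` (per concentration
#' unit; large values make the sigmoid response step-like), the threshold
#' concentration `theta` (in units of one prescribed dose), and the outcome
#' lag `tau` (hours; only used when relating daily adherence to peak-flow
#' series).
#'
#' @param alpha Decay rate per hour, strictly positive. Alternatively supply
#'   `half_life` and leave `alpha` missing.
#' @param beta Threshold sharpness, strictly positive.
#' @param theta Threshold concentration, non-negative, in units of the
#'   prescribed dose.
#' @param tau Outcome lag in hours, non-negative; `NA` when unused.
#' @param half_life Optional half-life in hours used to derive `alpha`.
#' @return An object of class `tat_params`.
#' @examples
#' tat_params(half_life = 12, beta = 73, theta = 0.69)
#' @export
tat_params <- function(alpha = NULL, beta, theta, tau = NA_real_,
                       half_life = NULL) {
  if (is.null(alpha)) {
    if (is.null(half_life)) stop("supply either `alpha` or `half_life`", call. = FALSE)
    alpha <- rate_from_half_life(half_life)
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L,
            is.numeric(beta), length(beta) == 1L,
            is.numeric(theta), length(theta) == 1L)
  if (!is.finite(alpha) || alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (!is.finite(beta) || beta <= 0) stop("`beta` must be > 0", call. = FALSE)
  if (!is.finite(theta) || theta < 0) stop("`theta` must be >= 0", call. = FALSE)
  if (!is.na(tau) && tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, beta = beta, theta = theta, tau = tau),
            class = "tat_params")
}

#' @export
print.tat_params <- function(x, ...) {
  cat(sprintf(
    "TAT model parameters: alpha = %.4g /h (half-life %.3g h), beta = %.4g, theta = %.4g%s\n",
    x$alpha, half_life_from_rate(x$alpha), x$beta, x$theta,
    if (is.na(x$tau)) "" else sprintf(", tau = %.4g h", x$tau)))
  invisible(x)
}

#' Named parameter presets
#'
#' Two cohort-level parameter sets are shipped: `"copd-ae"`, fitted against
#' monthly adverse-event (exacerbation) rate, and `"asthma-pefr"`, fitted
#' against daily peak expiratory flow rate.
#'
#' @param name One of `"copd-ae"` or `"asthma-pefr"`.
#' @return A [tat_params()] object.
#' @examples
#' tat_preset("copd-ae")
#' @export
tat_preset <- function(name = c("copd-ae", "asthma-pefr")) {
  name <- match.arg(name)
  switch(name,
    "copd-ae"     = tat_params(alpha = 0.056, beta = 73, theta = 0.69),
    "asthma-pefr" = tat_params(alpha = 0.062, beta = 63, theta = 0.56, tau = 18.2))
}
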