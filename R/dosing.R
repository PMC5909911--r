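#' Dose required to hold the steady-state trough at the threshold
#'
#' Under perfect adherence at a fixed dosing interval, the concentration
#' settles into a geometric steady state. The dose per administration (in
#' units of the currently prescribed dose) whose steady-state trough equals
#' the threshold `theta` is
#' \deqn{\delta_r = \frac{-(0.5^h - 1)}{0.5^h}\,\theta = \theta\,\frac{1 - 0.5^h}{0.5^h},}
#' where `h` is the dosing interval expressed in half-lives. When the
#' interval equals one half-life (`h = 1`), \eqn{\delta_r = \theta}: the
#' fitted threshold is directly the fraction of the current dose needed
#' under perfect adherence.
#'
#' @param theta Threshold concentration (units of prescribed dose), >= 0.
#' @param h Dosing interval in half-lives, > 0.
#' @return Required dose in units of the current prescribed dose.
#' @examples
#' required_dose(0.56, h = 1)   # threshold fitted against peak flow
#' required_dose(0.69, h = 1)   # threshold fitted against exacerbation rate
#' @export
required_dose <- function(theta, h) {
  if (!is.numeric(theta) || any(theta < 0)) stop("`theta` must be >= 0", call. = FALSE)
  if (!is.numeric(h) || any(h <= 0)) stop("`h` must be > 0", call. = FALSE)
  theta * (1 - 0.5^h) / 0.5^h
}

#' Steady-state peak and trough under perfect adherence
#'
#' For repeated doses of size `dose` every `h` half-lives, the steady-state
#' peak is `dose / (1 - 0.5^h)` (geometric series of decayed doses) and the
#' trough is the peak decayed over one interval, `peak * 0.5^h`. The trough
#' equals `theta` exactly when `dose = required_dose(theta, h)` — the
#' identity linking the concentration model to the dosage formula.
#'
#' @param dose Dose per administration, >= 0, in units of prescribed dose.
#' @param h Dosing interval in half-lives, > 0.
#' @return Named numeric vector with elements `peak` and `trough`.
#' @export
steady_state_extremes <- function(dose, h) {
  if (!is.numeric(dose) || any(dose < 0)) stop("`dose` must be >= 0", call. = FALSE)
  if (!is.numeric(h) || any(h <= 0)) stop("`h` must be > 0", call. = FALSE)
  peak <- dose / (1 - 0.5^h)
  c(peak = peak, trough = peak * 0.5^h)
}

#' Patient-adjusted dose given an average adherence rate
#'
#' Scales the required dose up by a patient's mean effective adherence
#' (fraction of prescribed drug effectively received), so that the average
#' delivery still holds the trough near the threshold. This is deliberately
#' the simplest such rule — dividing by mean adherence — and is an
#' extrapolation beyond the steady-state algebra; it is capped at a safety
#' multiple of the current dose and the rule used is recorded on the result.
#'
#' @param theta Threshold concentration, >= 0.
#' @param h Dosing interval in half-lives, > 0.
#' @param mean_adherence Mean fraction of doses effectively taken, in (0, 1].
#' @param cap Maximum returned dose in units of the current dose
#'   (default 2).
#' @return Adjusted dose (units of current dose) with attributes `capped`
#'   (logical) and `rule`.
#' @examples
#' adjusted_dose(0.5, h = 1, mean_adherence = 0.5)  # 1.0 current dose
#' @export
adjusted_dose <- function(theta, h, mean_adherence, cap = 2) {
  if (!is.numeric(mean_adherence) || length(mean_adherence) != 1L ||
      mean_adherence <= 0 || mean_adherence > 1) {
    stop("`mean_adherence` must lie in (0, 1]: no finite dose compensates for zero adherence",
         call. = FALSE)
  }
  raw <- required_dose(theta, h) / mean_adherence
  capped <- raw > cap
  structure(if (capped) cap else raw, capped = capped,
            rule = "required_dose / mean_adherence")
}

#' Dosage report for a fitted threshold
#'
#' Convenience summary combining [required_dose()], [steady_state_extremes()]
#' and (optionally) [adjusted_dose()] for a fitted parameter set.
#'
#' @param theta Threshold concentration.
#' @param h Dosing interval in half-lives (default 1: interval equals the
#'   half-life, the regime observed for twice-daily inhaled steroids with
#'   a roughly 12-hour half-life).
#' @param mean_adherence Optional mean adherence for a patient-specific
#'   adjustment.
#' @param cap Safety cap passed to [adjusted_dose()].
#' @return A tibble with one row: `theta`, `h`, `required_dose`,
#'   `ss_peak`, `ss_trough`, `adjusted_dose`, `capped`.
#' @export
dose_report <- function(theta, h = 1, mean_adherence = NULL, cap = 2) {
  dr <- required_dose(theta, h)
  ss <- steady_state_extremes(dr, h)
  adj <- if (is.null(mean_adherence)) {
    list(dose = NA_real_, capped = NA)
  } else {
    a <- adjusted_dose(theta, h, mean_adherence, cap = cap)
    list(dose = as.numeric(a), capped = attr(a, "capped"))
  }
  tibble::tibble(theta = theta, h = h, required_dose = dr,
                 ss_peak = ss[["peak"]], ss_trough = ss[["trough"]],
                 adjusted_dose = adj$dose, capped = adj$capped)
}
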