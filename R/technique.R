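#' Technique-error rule table
#'
#' Maps inhaler-technique error labels to the multiplicative fraction of the
#' full dose still received when that error is made. The default table ships
#' the calibration values for an acoustically monitored dry powder inhaler:
#'
#' | label           | delta factor | meaning                                   |
#' |-----------------|-------------:|-------------------------------------------|
#' | `low_pifr`      | 0.7          | low peak inspiratory flow (< 35 L/min)     |
#' | `exhalation`    | 0.5          | patient exhaled into the inhaler           |
#' | `no_blister`    | 0.0          | drug never released                        |
#' | `no_inhalation` | 0.0          | no inhalation detected                     |
#'
#' Errors combine multiplicatively, so a dose taken with both low
#' inspiratory flow and an exhalation error scores 0.7 x 0.5 = 0.35, and the
#' zero-valued errors dominate any combination. Other devices or drugs can
#' supply their own table (e.g. via a CSV with columns `error_label`,
#' `delta_factor`).
#'
#' @param extra Optional data frame with columns `error_label` and
#'   `delta_factor` appended to (or overriding) the defaults.
#' @return A tibble with columns `error_label`, `delta_factor`.
#' @export
technique_rules <- function(extra = NULL) {
  rules <- tibble::tibble(
    error_label  = c("low_pifr", "exhalation", "no_blister", "no_inhalation"),
    delta_factor = c(0.7, 0.5, 0, 0))
  if (!is.null(extra)) {
    stopifnot(all(c("error_label", "delta_factor") %in% names(extra)))
    extra <- tibble::as_tibble(extra[, c("error_label", "delta_factor")])
    rules <- rbind(rules[!rules$error_label %in% extra$error_label, ], extra)
  }
  if (anyDuplicated(rules$error_label)) {
    stop("technique rule labels must be unique", call. = FALSE)
  }
  if (any(rules$delta_factor < 0 | rules$delta_factor > 1)) {
    stop("`delta_factor` must lie in [0, 1]", call. = FALSE)
  }
  rules
}

#' Technique score for a set of error labels
#'
#' Returns the fraction of the full dose received given the technique errors
#' made on one actuation: the product of the per-error dose factors, 1 for an
#' error-free dose. Zero-valued errors (no drug released, no inhalation)
#' absorb the product, and the result is invariant to label order.
#'
#' @param error_labels Character vector of error labels (possibly empty).
#' @param rules Rule table from [technique_rules()].
#' @return A dose fraction in \[0, 1\].
#' @examples
#' delta_for_errors(character(0))                  # 1.0
#' delta_for_errors(c("low_pifr", "exhalation"))   # 0.35
#' @export
delta_for_errors <- function(error_labels, rules = technique_rules()) {
  error_labels <- error_labels[nzchar(error_labels) & error_labels != "none"]
  if (!length(error_labels)) return(1.0)
  idx <- match(error_labels, rules$error_label)
  if (anyNA(idx)) {
    stop(sprintf("unknown technique error label(s): %s",
                 paste(unique(error_labels[is.na(idx)]), collapse = ", ")),
         call. = FALSE)
  }
  prod(rules$delta_factor[idx])
}
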