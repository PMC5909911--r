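#' Construct a table of dose events
#'
#' A dose event is one inhaler actuation: a time (hours since the start of
#' observation) and a technique score `delta`, the fraction of the full dose
#' effectively received (1 for a correctly taken dose, down to 0 when no drug
#' was released or inhaled). An optional `error_labels` column records the
#' technique errors behind the score; when both are supplied the score must
#' agree with the technique rule table.
#'
#' @param time Numeric vector of event times in hours, finite and
#'   non-negative.
#' @param delta Technique scores in \[0, 1\]; recycled if length 1.
#' @param error_labels Optional list (or character vector) of technique-error
#'   labels per event; `character(0)` / `""` means correct use.
#' @param rules Technique rule table used to cross-check `delta` against
#'   `error_labels` when both are given; see [technique_rules()].
#' @return A tibble of class `dose_events`, sorted by time, with columns
#'   `time`, `delta` and (if given) `error_labels`.
#' @examples
#' dose_events(time = c(0, 12, 24), delta = c(1, 0.7, 1))
#' @export
dose_events <- function(time, delta = 1, error_labels = NULL, rules = NULL) {
  time <- as.numeric(time)
  if (any(!is.finite(time)) || any(time < 0)) {
    stop("event times must be finite and non-negative", call. = FALSE)
  }
  delta <- rep_len(as.numeric(delta), length(time))
  if (any(!is.finite(delta)) || any(delta < 0) || any(delta > 1)) {
    stop("`delta` must lie in [0, 1]", call. = FALSE)
  }
  out <- tibble::tibble(time = time, delta = delta)
  if (!is.null(error_labels)) {
    if (is.character(error_labels)) {
      error_labels <- strsplit(error_labels, ";", fixed = TRUE)
    }
    stopifnot(length(error_labels) == length(time))
    error_labels <- lapply(error_labels, function(l) l[nzchar(l)])
    out$error_labels <- error_labels
    if (!is.null(rules)) {
      implied <- vapply(error_labels, delta_for_errors, numeric(1), rules = rules)
      bad <- which(abs(implied - out$delta) > 1e-8)
      if (length(bad)) {
        stop(sprintf(
          "delta inconsistent with error labels at event(s) %s (expected %s)",
          paste(head(bad, 5L), collapse = ", "),
          paste(signif(implied[head(bad, 5L)], 3), collapse = ", ")),
          call. = FALSE)
      }
    }
  }
  out <- out[order(out$time), , drop = FALSE]
  class(out) <- c("dose_events", class(out))
  out
}

#' Construct an observation window
#'
#' A half-open time interval `[start, end)` in hours over which adherence is
#' scored; events falling exactly on a boundary belong to the later window.
#'
#' @param start,end Window bounds in hours, `end > start`.
#' @param label Optional identifier (e.g. a month index).
#' @return A list of class `obs_window` with elements `start`, `end`,
#'   `length` and `label`.
#' @export
obs_window <- function(start, end, label = NA) {
  stopifnot(is.numeric(start), is.numeric(end), length(start) == 1L,
            length(end) == 1L, is.finite(start), is.finite(end))
  if (end <= start) stop("window must have `end` > `start`", call. = FALSE)
  structure(list(start = start, end = end, length = end - start, label = label),
            class = "obs_window")
}

#' Construct a patient record
#'
#' Bundles one patient's monitored dose events with the monitoring span,
#' demographic covariates and clinical outcomes used for model fitting and
#' validation.
#'
#' @param patient_id Identifier.
#' @param events A [dose_events()] table.
#' @param span_hours Length of the monitoring span in hours (span runs from
#'   0 to `span_hours`), or an [obs_window()].
#' @param age Age in years (optional).
#' @param sex `"male"` or `"female"` (optional).
#' @param exacerbations Optional integer/logical vector: one binary indicator
#'   per consecutive monthly window of the span.
#' @param pefr Optional numeric vector of daily peak expiratory flow readings
#'   (L/min), one per day of the span.
#' @return A list of class `patient_record`.
#' @export
patient_record <- function(patient_id, events, span_hours,
                           age = NA_real_, sex = NA_character_,
                           exacerbations = NULL, pefr = NULL) {
  if (inherits(span_hours, "obs_window")) {
    span <- span_hours
  } else {
    stopifnot(is.numeric(span_hours), length(span_hours) == 1L, span_hours > 0)
    span <- obs_window(0, span_hours)
  }
  if (!inherits(events, "dose_events")) {
    events <- dose_events(events$time, events$delta,
                          error_labels = events$error_labels)
  }
  if (nrow(events) && max(events$time) > span$end) {
    stop("events extend beyond the monitoring span", call. = FALSE)
  }
  if (!is.null(exacerbations)) exacerbations <- as.integer(exacerbations)
  structure(list(patient_id = patient_id, events = events, span = span,
                 age = age, sex = sex,
                 exacerbations = exacerbations, pefr = pefr),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s: %d dose events over %.1f days\n",
              x$patient_id, nrow(x$events), x$span$length / 24))
  invisible(x)
}
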