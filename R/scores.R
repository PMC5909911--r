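#' Time-above-threshold adherence score for one window
#'
#' The summary adherence score is the threshold response averaged over an
#' observation window,
#' \deqn{A(\alpha, \beta, \theta) = \frac{1}{T} \int_0^T \sigma(t)\,dt,}
#' a number between 0 and 1 interpretable as the (sigmoid-smoothed)
#' proportion of the window during which the modelled concentration exceeds
#' the threshold. The integral is evaluated by the trapezoidal rule on a
#' uniform grid.
#'
#' Events before the window start contribute their residual concentration,
#' so a window opening mid-treatment is scored against the true carried-over
#' curve. When scoring from a cold start (no events before time zero) an
#' optional burn-in can be excluded so the inevitable sub-threshold ramp-up
#' does not penalise the score.
#'
#' @param events A [dose_events()] table; events after the window end are
#'   ignored.
#' @param params A [tat_params()] object.
#' @param window An [obs_window()].
#' @param step Integration step in hours (default 0.1 h = 6 minutes).
#' @param burn_in Hours excluded from the start of the window before
#'   integrating (default 0).
#' @return An object of class `adherence_score`: a list with `value` (in
#'   \[0, 1\]), `window`, `params` and `n_doses` (events inside the window).
#' @examples
#' ev <- dose_events(seq(0, 72, by = 12))
#' time_above_threshold(ev, tat_preset("copd-ae"), obs_window(0, 72))
#' @export
time_above_threshold <- function(events, params, window, step = 0.1,
                                 burn_in = 0) {
  stopifnot(inherits(params, "tat_params"), inherits(window, "obs_window"))
  if (!is.numeric(step) || step <= 0) stop("`step` must be > 0", call. = FALSE)
  if (burn_in < 0 || burn_in >= window$length) {
    stop("`burn_in` must be in [0, window length)", call. = FALSE)
  }
  from <- window$start + burn_in
  grid <- seq(from, window$end, by = step)
  if (grid[length(grid)] < window$end) grid <- c(grid, window$end)
  if (is.null(events) || nrow(events) == 0L) {
    n_doses <- 0L
    value <- as.numeric(sigmoid(-params$beta * params$theta))
  } else {
    keep <- events$time <= window$end
    ts <- events$time[keep]
    ds <- events$delta[keep]
    n_doses <- sum(events$time >= window$start & events$time < window$end)
    # each dose is a jump in C(t): make event times integration nodes and
    # integrate with the left limit on the incoming side of each jump, so
    # the trapezoid never smears a jump across a grid step
    inside <- ts > from & ts <= grid[length(grid)]
    nodes <- sort(unique(c(grid, ts[inside])))
    C_right <- conc_on_grid(ts, ds, params$alpha, nodes)
    C_left <- C_right
    if (any(inside)) {
      j <- match(ts[inside], nodes)
      drop <- rowsum(ds[inside], group = j)
      jj <- as.integer(rownames(drop))
      C_left[jj] <- C_left[jj] - drop
    }
    s_right <- sigmoid(params$beta * (C_right - params$theta))
    s_left <- sigmoid(params$beta * (C_left - params$theta))
    n <- length(nodes)
    value <- sum(diff(nodes) * (s_right[-n] + s_left[-1L])) / 2 /
      (nodes[n] - nodes[1L])
  }
  structure(list(value = value, window = window, params = params,
                 n_doses = n_doses),
            class = "adherence_score")
}

#' @export
print.adherence_score <- function(x, ...) {
  cat(sprintf("Adherence (time above threshold): %.3f over [%.1f, %.1f] h (%d doses)\n",
              x$value, x$window$start, x$window$end, x$n_doses))
  invisible(x)
}

#' Adherence scores over consecutive windows of a monitoring span
#'
#' Partitions a patient's monitoring span into consecutive windows of fixed
#' length starting at the patient's monitoring start (default 30 days, the
#' unit at which exacerbation outcomes are recorded), and scores each with
#' [time_above_threshold()]. Windows are half-open `[start, end)` for dose
#' counting; a final partial window is scored over its actual length and
#' flagged.
#'
#' @param record A [patient_record()].
#' @param params A [tat_params()] object.
#' @param window_hours Window length in hours (default 720 = 30 days).
#' @param step,burn_in Passed to [time_above_threshold()]; `burn_in` applies
#'   to the first window only (later windows inherit real carry-over).
#' @return A tibble with columns `patient_id`, `window`, `start`, `end`,
#'   `adherence`, `n_doses`, `partial`.
#' @export
windowed_scores <- function(record, params, window_hours = 720, step = 0.1,
                            burn_in = 0) {
  stopifnot(inherits(record, "patient_record"))
  if (!is.numeric(window_hours) || window_hours <= 0) {
    stop("`window_hours` must be > 0", call. = FALSE)
  }
  span <- record$span$length
  n_win <- ceiling(span / window_hours - 1e-9)
  starts <- record$span$start + (seq_len(n_win) - 1L) * window_hours
  ends <- pmin(starts + window_hours, record$span$end)
  res <- lapply(seq_along(starts), function(w) {
    win <- obs_window(starts[w], ends[w], label = w)
    sc <- time_above_threshold(record$events, params, win, step = step,
                               burn_in = if (w == 1L) burn_in else 0)
    tibble::tibble(window = w, start = starts[w], end = ends[w],
                   adherence = sc$value, n_doses = sc$n_doses,
                   partial = (ends[w] - starts[w]) < window_hours - 1e-9)
  })
  out <- do.call(rbind, res)
  tibble::tibble(patient_id = record$patient_id, out)
}

#' Daily adherence scores with a lagged moving average
#'
#' Scores each 24-hour day of the monitoring span, then applies a trailing
#' exponentially weighted moving average whose mean lag is `tau` hours
#' (kernel \eqn{e^{-t/\tau}/\tau}, discretised on the daily series and
#' renormalised over the available history). The smoothed series is the
#' predictor used when relating adherence to daily peak-flow measurements:
#' the clinical response to a change in adherence is not instantaneous, and
#' `tau` captures that physiological lag. `tau = 0` returns the raw daily
#' scores.
#'
#' @param record A [patient_record()].
#' @param params A [tat_params()] object; its `tau` (hours) sets the lag
#'   (`NA` is treated as 0).
#' @param step Integration step in hours for the daily scores.
#' @return A tibble with columns `day` (1-based), `adherence` (raw daily
#'   score) and `smoothed`.
#' @export
lagged_daily_scores <- function(record, params, step = 0.1) {
  stopifnot(inherits(record, "patient_record"))
  tau <- params$tau
  if (is.na(tau)) tau <- 0
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  n_days <- floor(record$span$length / 24)
  if (n_days < 1L) stop("monitoring span shorter than one day", call. = FALSE)
  daily <- vapply(seq_len(n_days), function(d) {
    win <- obs_window((d - 1) * 24, d * 24, label = d)
    time_above_threshold(record$events, params, win, step = step)$value
  }, numeric(1))
  tibble::tibble(day = seq_len(n_days), adherence = daily,
                 smoothed = ewma_lag(daily, tau, dt = 24))
}

# Trailing exponentially weighted moving average with mean lag `tau` (hours)
# on a series sampled every `dt` hours. Weights are renormalised over the
# points actually available, so early points average over a shorter history.
ewma_lag <- function(x, tau, dt = 24) {
  if (tau < 0) stop("`tau` must be >= 0", call. = FALSE)
  if (tau == 0) return(x)
  n <- length(x)
  w_full <- exp(-(seq_len(n) - 1L) * dt / tau)
  vapply(seq_len(n), function(i) {
    w <- w_full[seq_len(i)]
    sum(w * x[i:1]) / sum(w)
  }, numeric(1))
}
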