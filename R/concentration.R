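#' Reconstruct the drug concentration profile from dose events
#'
#' Models the relative drug concentration as a superposition of
#' exponentially decaying unit doses,
#' \deqn{C(t) = \sum_{t_s \le t} \delta_s e^{-\alpha (t - t_s)},}
#' where each correctly taken dose contributes one unit of the prescribed
#' dosage at its instant and decays at rate `alpha`. Concentration (and the
#' threshold it is later compared with) is therefore expressed in units of
#' the prescribed dose, independent of the drug's absolute strength.
#'
#' The recursion between consecutive grid points is exact — between events
#' the curve decays exponentially, and events are folded in with their exact
#' partial decay — so grid resolution affects only where the curve is
#' sampled, not its values.
#'
#' @param events A [dose_events()] table (or data frame with `time`,
#'   `delta`). May be empty. Events before the first grid point contribute
#'   their decayed residual.
#' @param alpha Decay rate per hour, strictly positive.
#' @param grid Strictly increasing numeric vector of times (hours) at which
#'   to sample the curve.
#' @return A tibble of class `tat_curve` with columns `time` and `conc`.
#' @examples
#' ev <- dose_events(c(0, 12), c(1, 1))
#' concentration(ev, alpha = log(2) / 12, grid = seq(0, 24, by = 1))
#' @export
concentration <- function(events, alpha, grid) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0) {
    stop("`alpha` must be a single positive rate", call. = FALSE)
  }
  grid <- as.numeric(grid)
  if (length(grid) < 1L || any(diff(grid) <= 0)) {
    stop("`grid` must be strictly increasing", call. = FALSE)
  }
  if (is.null(events) || nrow(events) == 0L) {
    return(structure(tibble::tibble(time = grid, conc = numeric(length(grid))),
                     class = c("tat_curve", class(tibble::tibble()))))
  }
  ts <- as.numeric(events$time)
  ds <- as.numeric(events$delta)
  if (any(ds < 0)) stop("event `delta` must be non-negative", call. = FALSE)
  keep <- ts <= grid[length(grid)]
  ts <- ts[keep]; ds <- ds[keep]
  vals <- conc_on_grid(ts, ds, alpha, grid)
  structure(tibble::tibble(time = grid, conc = vals),
            class = c("tat_curve", class(tibble::tibble())))
}

# Exact sampling of the superposed decay on an increasing grid.
# Each event is injected at the first grid point at or after its time, with
# the decay accrued between the event and that point; the between-point
# recursion C_j = C_{j-1} exp(-alpha dt_j) + inject_j is then exact.
conc_on_grid <- function(ts, ds, alpha, grid) {
  n <- length(grid)
  if (!length(ts)) return(numeric(n))
  j <- findInterval(ts, grid, left.open = TRUE) + 1L  # boundary events count at the point
  ok <- j <= n
  inject <- numeric(n)
  if (any(ok)) {
    w <- ds[ok] * exp(-alpha * (grid[j[ok]] - ts[ok]))
    acc <- rowsum(w, group = j[ok])
    inject[as.integer(rownames(acc))] <- acc
  }
  dt <- diff(grid)
  if (n > 1L && diff(range(dt)) < 1e-12 * max(dt)) {
    # uniform grid: single-pass recursive filter
    as.numeric(stats::filter(inject, exp(-alpha * dt[1L]), method = "recursive"))
  } else {
    r <- c(0, exp(-alpha * dt))
    out <- numeric(n)
    out[1L] <- inject[1L]
    for (i in seq_len(n - 1L) + 1L) out[i] <- out[i - 1L] * r[i] + inject[i]
    out
  }
}

#' Sigmoidal threshold response of a concentration curve
#'
#' Maps concentration through the standard dose-response sigmoid
#' \deqn{\sigma(t) = \frac{1}{1 + e^{-\beta (C(t) - \theta)}},}
#' which equals 0.5 exactly where the concentration crosses the threshold
#' `theta` and approaches a step function as `beta` grows. Arguments of the
#' exponential are clipped at +/-500, so extreme concentrations saturate
#' cleanly to 0 or 1 rather than overflowing.
#'
#' @param conc A `tat_curve` from [concentration()], or a bare numeric vector
#'   of concentrations.
#' @param beta Threshold sharpness, strictly positive.
#' @param theta Threshold concentration in units of the prescribed dose.
#' @return Numeric vector of responses in (0, 1) (a tibble with a `sigma`
#'   column when the input was a curve).
#' @export
threshold_response <- function(conc, beta, theta) {
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0) {
    stop("`beta` must be a single positive value", call. = FALSE)
  }
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0) {
    stop("`theta` must be a single non-negative value", call. = FALSE)
  }
  if (is.data.frame(conc)) {
    out <- conc
    out$sigma <- sigmoid(beta * (out$conc - theta))
    return(out)
  }
  sigmoid(beta * (conc - theta))
}

sigmoid <- function(x) stats::plogis(pmin(pmax(x, -500), 500))

# trapezoidal rule on a (possibly non-uniform) grid
trapz <- function(t, y) {
  n <- length(t)
  if (n < 2L) return(0)
  sum(diff(t) * (y[-1L] + y[-n])) / 2
}
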