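# Independent oracles, deliberately implemented with different algorithms
# from the package internals.

# Brute-force concentration: literal superposition sum at each time point.
oracle_concentration <- function(times, deltas, alpha, t) {
  vapply(t, function(tt) {
    sel <- times <= tt
    sum(deltas[sel] * exp(-alpha * (tt - times[sel])))
  }, numeric(1))
}

# Exact measure of {t in [w0, w1]: C(t) > theta} for a piecewise-exponential
# decay, by solving C(t) = theta on each inter-event segment. The curve only
# decays between events, so each segment contributes at most one downward
# crossing at t = t_k + log(C_k / theta) / alpha.
oracle_above_fraction <- function(times, deltas, alpha, theta, w0, w1) {
  knots <- sort(unique(c(w0, times[times > w0 & times < w1], w1)))
  above <- 0
  for (i in seq_len(length(knots) - 1L)) {
    a <- knots[i]; b <- knots[i + 1L]
    Ca <- oracle_concentration(times, deltas, alpha, a)
    if (Ca > theta) {
      t_cross <- a + log(Ca / theta) / alpha
      above <- above + min(b, t_cross) - a
    }
  }
  above / (w1 - w0)
}

# Bernoulli log-likelihood at given coefficients (direct formula).
oracle_bernoulli_ll <- function(scores, y, g0, g1) {
  p <- 1 / (1 + exp(-(g0 + g1 * scores)))
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# Direct O(n^2) trailing exponential moving average with mean lag tau.
oracle_ewma <- function(x, tau, dt = 24) {
  if (tau == 0) return(x)
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    w <- rev(exp(-(seq_len(i) - 1L) * dt / tau))
    out[i] <- sum(w * x[1:i]) / sum(w)
  }
  out
}

# Perfect twice-daily regimen helper.
regular_events <- function(days, interval = 12, delta = 1) {
  dose_events(seq(0, days * 24 - interval, by = interval), delta)
}
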