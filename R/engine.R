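# Internal vectorised scoring engine.
#
# Model fitting evaluates windowed adherence scores for a whole cohort at
# hundreds of candidate parameter sets. The expensive pieces are (i) the
# concentration profile, which depends only on alpha, and (ii) the sigmoid +
# trapezoid average, which is cheap once the profile is sampled. The engine
# therefore precomputes everything that does not depend on parameters
# (injection indices, window slicing, trapezoid weights), samples the
# concentration for a given alpha with one recursive filter pass over all
# patients, and turns a (beta, theta) pair into window scores with a single
# matrix product. The between-grid-point recursion is exact (see
# conc_on_grid); the only approximation is the trapezoidal average itself.

tat_engine <- function(cohort, window_hours = 720, step = 0.5) {
  stopifnot(is.list(cohort), length(cohort) >= 1L)
  spans <- vapply(cohort, function(r) r$span$length, numeric(1))
  if (diff(range(spans)) > 1e-9) {
    stop("cohort engine requires equal monitoring spans", call. = FALSE)
  }
  m <- window_hours / step
  if (abs(m - round(m)) > 1e-9) {
    stop("`window_hours` must be a whole multiple of `step`", call. = FALSE)
  }
  m <- as.integer(round(m))
  n_win_pp <- as.integer(floor(spans[1L] / window_hours + 1e-9))
  if (n_win_pp < 1L) stop("monitoring span shorter than one window", call. = FALSE)
  n_pts <- n_win_pp * m + 1L
  grid <- (seq_len(n_pts) - 1L) * step
  n_pat <- length(cohort)

  ev_pat <- vector("list", n_pat)
  ev_j <- vector("list", n_pat)
  ev_dtg <- vector("list", n_pat)
  ev_delta <- vector("list", n_pat)
  for (p in seq_len(n_pat)) {
    ev <- cohort[[p]]$events
    ts <- ev$time
    keep <- ts <= grid[n_pts] + 1e-9
    ts <- ts[keep]
    j <- findInterval(ts, grid, left.open = TRUE) + 1L
    ok <- j <= n_pts
    ev_pat[[p]] <- rep.int(p, sum(ok))
    ev_j[[p]] <- j[ok]
    ev_dtg[[p]] <- grid[j[ok]] - ts[ok]
    ev_delta[[p]] <- ev$delta[keep][ok]
  }
  win_offsets <- rep((seq_len(n_win_pp) - 1L) * m, times = n_pat) +
    rep((seq_len(n_pat) - 1L) * n_pts, each = n_win_pp)
  idx <- outer(seq_len(m + 1L), win_offsets, `+`)

  list(
    step = step, m = m, n_pts = n_pts, n_pat = n_pat, n_win_pp = n_win_pp,
    n_win = n_pat * n_win_pp,
    ev_pat = unlist(ev_pat), ev_j = unlist(ev_j),
    ev_dtg = unlist(ev_dtg), ev_delta = unlist(ev_delta),
    idx = idx,
    tw = matrix(c(0.5, rep(1, m - 1L), 0.5) / m, nrow = 1L),
    patient_id = vapply(cohort, function(r) as.character(r$patient_id), character(1)),
    win_patient = rep(seq_len(n_pat), each = n_win_pp),
    win_index = rep(seq_len(n_win_pp), times = n_pat))
}

# Concentration sampled for one alpha: (m+1) x n_win matrix, one column per
# patient-window, consecutive windows sharing their boundary sample.
engine_conc <- function(engine, alpha) {
  inject <- numeric(engine$n_pts * engine$n_pat)
  if (length(engine$ev_j)) {
    w <- engine$ev_delta * exp(-alpha * engine$ev_dtg)
    li <- (engine$ev_pat - 1L) * engine$n_pts + engine$ev_j
    acc <- rowsum(w, group = li)
    inject[as.integer(rownames(acc))] <- acc
  }
  dim(inject) <- c(engine$n_pts, engine$n_pat)
  C <- stats::filter(inject, exp(-alpha * engine$step), method = "recursive")
  Cv <- as.numeric(C)
  matrix(Cv[engine$idx], nrow = engine$m + 1L)
}

# Trapezoid-averaged sigmoid response per window. The raw exp form is used
# for speed; exp overflow saturates to exactly 0/1 rather than NaN.
engine_scores <- function(engine, Cw, beta, theta) {
  as.numeric(engine$tw %*% (1 / (1 + exp(-beta * (Cw - theta)))))
}

# Per-window binary outcomes aligned with the engine's window order.
engine_outcomes <- function(engine, cohort) {
  y <- unlist(lapply(cohort, function(r) {
    if (is.null(r$exacerbations) || length(r$exacerbations) < engine$n_win_pp) {
      stop(sprintf("patient %s lacks outcomes for %d complete window(s)",
                   r$patient_id, engine$n_win_pp), call. = FALSE)
    }
    r$exacerbations[seq_len(engine$n_win_pp)]
  }))
  as.integer(y)
}

# Daily PEFR matrix (days x patients) aligned with a daily engine.
engine_pefr <- function(engine, cohort) {
  stopifnot(engine$m * engine$step == 24)
  n_days <- engine$n_win_pp
  vals <- vapply(cohort, function(r) {
    if (is.null(r$pefr) || length(r$pefr) < n_days) {
      stop(sprintf("patient %s lacks a daily PEFR series of length %d",
                   r$patient_id, n_days), call. = FALSE)
    }
    as.numeric(r$pefr[seq_len(n_days)])
  }, numeric(n_days))
  matrix(vals, nrow = n_days)
}

# Trailing exponentially weighted moving average, column-wise on a matrix,
# with edge renormalisation; identical to ewma_lag() on each column.
ewma_lag_matrix <- function(x, tau, dt = 24) {
  if (tau == 0) return(x)
  r <- exp(-dt / tau)
  num <- stats::filter(x, r, method = "recursive")
  den <- (1 - r^seq_len(nrow(x))) / (1 - r)
  matrix(as.numeric(num) / rep(den, times = ncol(x)), nrow = nrow(x))
}
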