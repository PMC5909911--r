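#' Default parameter search space for model fitting
#'
#' The coarse grid used before local refinement: half-lives from 6 to 24
#' hours in 9 steps (bracketing the roughly 12-hour elimination of inhaled
#' steroids), a handful of threshold-sharpness values spanning the range
#' over which predictive power is known to be insensitive, thresholds from
#' 0.1 to 1.2 prescribed-dose units in steps of 0.05, and (for peak-flow
#' fits) lags from 0 to 48 hours.
#'
#' @param half_life,beta,theta,tau Numeric vectors overriding individual
#'   axes of the grid.
#' @return A named list of grid axes.
#' @export
tat_search_space <- function(half_life = seq(6, 24, length.out = 9),
                             beta = c(25, 50, 73, 100, 150),
                             theta = seq(0.1, 1.2, by = 0.05),
                             tau = c(0, 6, 12, 18, 24, 36, 48)) {
  stopifnot(all(half_life > 0), all(beta > 0), all(theta >= 0), all(tau >= 0))
  list(half_life = sort(half_life), beta = sort(beta), theta = sort(theta),
       tau = sort(tau))
}

#' Log-likelihood of monthly exacerbations given candidate parameters
#'
#' Computes each patient's monthly time-above-threshold scores at the
#' candidate parameters, then fits (by maximum likelihood) a logistic
#' regression of the window-level binary exacerbation indicator on the
#' score. The returned value is the maximised Bernoulli log-likelihood, with
#' the outcome-link coefficients (intercept `gamma0`, slope `gamma1`)
#' profiled out; they are attached as an attribute. Windows are treated as
#' independent observations.
#'
#' @param cohort List of [patient_record()]s, each with at least one
#'   complete monthly outcome window.
#' @param params A [tat_params()] candidate.
#' @param window_hours Outcome window length in hours (default 720).
#' @param step Integration step in hours used for cohort scoring
#'   (default 0.5).
#' @return The log-likelihood (scalar) with attributes `coefficients`
#'   (named `gamma0`, `gamma1`) and `scores`.
#' @export
exacerbation_log_likelihood <- function(cohort, params, window_hours = 720,
                                        step = 0.5) {
  stopifnot(inherits(params, "tat_params"))
  engine <- tat_engine(cohort, window_hours = window_hours, step = step)
  y <- engine_outcomes(engine, cohort)
  if (length(unique(y)) < 2L) {
    stop("outcomes show no variation: model is not identifiable", call. = FALSE)
  }
  Cw <- engine_conc(engine, params$alpha)
  A <- engine_scores(engine, Cw, params$beta, params$theta)
  ll <- bernoulli_profile_ll(A, y)
  ll
}

# Logistic regression of y on score; returns maximised log-likelihood with
# the fitted (gamma0, gamma1) attached. For Bernoulli data the saturated
# log-likelihood is zero, so ll = -deviance / 2.
bernoulli_profile_ll <- function(A, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, A), y, family = stats::binomial()))
  structure(-fit$deviance / 2,
            coefficients = c(gamma0 = unname(fit$coefficients[1L]),
                             gamma1 = unname(fit$coefficients[2L])),
            scores = A)
}

#' Fit the adherence model against monthly exacerbation outcomes
#'
#' Maximises [exacerbation_log_likelihood()] over the physiological
#' parameters: a deterministic coarse grid over (half-life, beta, theta)
#' followed by Nelder-Mead refinement (on log scales) from the best grid
#' cell. The profile log-likelihood over theta (maximised over the grid's
#' other axes) is returned together with a 95% profile-likelihood confidence
#' interval for theta, cut at a drop of `qchisq(0.95, 1) / 2 = 1.92` from
#' the maximum. The whole procedure is deterministic given the cohort and
#' settings.
#'
#' @param cohort List of [patient_record()]s with monthly exacerbation
#'   indicators.
#' @param search_space Grid axes from [tat_search_space()].
#' @param window_hours,step As in [exacerbation_log_likelihood()].
#' @param refine Run local refinement after the grid (default `TRUE`).
#' @return An object of class `tat_fit`: a list with `params` (the fitted
#'   [tat_params()]), `coefficients` (`gamma0`, `gamma1`), `log_likelihood`,
#'   `profile` (tibble of `theta`, `log_likelihood`), `ci` (tibble with the
#'   profile interval for `theta`), `converged`, `identifiable`,
#'   `n_patients`, `n_windows`, and `grid` (the full coarse-grid
#'   log-likelihood table).
#' @export
fit_exacerbation_model <- function(cohort, search_space = tat_search_space(),
                                   window_hours = 720, step = 0.5,
                                   refine = TRUE) {
  engine <- tat_engine(cohort, window_hours = window_hours, step = step)
  y <- engine_outcomes(engine, cohort)
  if (length(unique(y)) < 2L) {
    stop("outcomes show no variation: model is not identifiable", call. = FALSE)
  }
  obj <- function(A) bernoulli_profile_ll(A, y)
  fit_tat_common(engine, cohort, obj, search_space, refine, outcome = "exacerbation")
}

# Shared grid-then-refine driver for both outcome models. `objective` maps a
# vector of window scores to a log-likelihood (plus coefficient attributes).
fit_tat_common <- function(engine, cohort, objective, search_space, refine,
                           outcome) {
  hl <- search_space$half_life
  betas <- search_space$beta
  thetas <- search_space$theta
  grid_tbl <- expand.grid(half_life = hl, beta = betas, theta = thetas,
                          KEEP.OUT.ATTRS = FALSE)
  grid_tbl$log_likelihood <- NA_real_
  ll_arr <- array(NA_real_, dim = c(length(hl), length(betas), length(thetas)))
  for (i in seq_along(hl)) {
    Cw <- engine_conc(engine, log(2) / hl[i])
    for (j in seq_along(betas)) {
      for (k in seq_along(thetas)) {
        A <- engine_scores(engine, Cw, betas[j], thetas[k])
        ll_arr[i, j, k] <- as.numeric(objective(A))
      }
    }
  }
  grid_tbl$log_likelihood <- as.numeric(ll_arr)
  best <- arrayInd(which.max(ll_arr), dim(ll_arr))
  best_par <- c(alpha = log(2) / hl[best[1L]], beta = betas[best[2L]],
                theta = thetas[best[3L]])
  ll_best <- max(ll_arr, na.rm = TRUE)

  eval_at <- function(alpha, beta, theta) {
    Cw <- engine_conc(engine, alpha)
    objective(engine_scores(engine, Cw, beta, theta))
  }
  converged <- TRUE
  if (refine) {
    # refinement stays inside the declared search bounds: the likelihood has
    # long shallow ridges (notably towards very large beta) along which an
    # unconstrained simplex can drift without meaningful gain
    lo <- c(min(hl), min(betas), min(thetas))
    hi <- c(max(hl), max(betas), max(thetas))
    neg <- function(p) {  # p = (half_life, beta, theta)
      val <- tryCatch(as.numeric(eval_at(log(2) / p[1L], p[2L], p[3L])),
                      error = function(e) -Inf)
      if (!is.finite(val)) 1e10 else -val
    }
    start <- c(hl[best[1L]], betas[best[2L]], thetas[best[3L]])
    opt <- box_nelder_mead(start, lo, hi, neg, maxit = 300)
    converged <- opt$convergence == 0L
    if (-opt$value >= ll_best) {
      best_par <- c(alpha = log(2) / opt$par[1L], beta = opt$par[2L],
                    theta = opt$par[3L])
      ll_best <- -opt$value
    }
  }
  final <- eval_at(best_par[["alpha"]], best_par[["beta"]], best_par[["theta"]])

  prof <- apply(ll_arr, 3L, max, na.rm = TRUE)
  profile <- tibble::tibble(theta = thetas, log_likelihood = prof)
  ci_theta <- profile_ci(thetas, prof, ll_best)
  identifiable <- (max(prof) - min(prof)) > stats::qchisq(0.95, 1) / 2

  structure(list(
    params = tat_params(alpha = best_par[["alpha"]], beta = best_par[["beta"]],
                        theta = best_par[["theta"]]),
    coefficients = attr(final, "coefficients"),
    log_likelihood = ll_best,
    profile = profile,
    ci = tibble::tibble(parameter = "theta",
                        estimate = best_par[["theta"]],
                        lower = ci_theta[1L], upper = ci_theta[2L]),
    converged = converged,
    identifiable = identifiable,
    n_patients = engine$n_pat,
    n_windows = engine$n_win,
    outcome = outcome,
    grid = tibble::as_tibble(grid_tbl)),
    class = "tat_fit")
}

# Nelder-Mead inside a box, via a logistic reparameterisation of each
# coordinate; starting values are pulled slightly off the faces.
box_nelder_mead <- function(start, lo, hi, fn, maxit = 300) {
  u <- pmin(pmax((start - lo) / (hi - lo), 0.02), 0.98)
  opt <- stats::optim(stats::qlogis(u),
                      function(z) fn(lo + (hi - lo) * stats::plogis(z)),
                      method = "Nelder-Mead",
                      control = list(maxit = maxit, reltol = 1e-8))
  list(par = lo + (hi - lo) * stats::plogis(opt$par), value = opt$value,
       convergence = opt$convergence)
}

# 95% profile-likelihood interval by linear interpolation on the theta grid.
# The reference maximum may exceed the grid profile (it includes the refined
# optimum), which can only widen the interval.
profile_ci <- function(theta, prof, ll_max) {
  thr <- ll_max - stats::qchisq(0.95, 1) / 2
  above <- prof >= thr
  if (!any(above)) return(c(NA_real_, NA_real_))
  lo_i <- which(above)[1L]
  hi_i <- rev(which(above))[1L]
  lower <- if (lo_i == 1L) theta[1L] else {
    theta[lo_i - 1L] + (thr - prof[lo_i - 1L]) /
      (prof[lo_i] - prof[lo_i - 1L]) * (theta[lo_i] - theta[lo_i - 1L])
  }
  upper <- if (hi_i == length(theta)) theta[length(theta)] else {
    theta[hi_i] + (prof[hi_i] - thr) /
      (prof[hi_i] - prof[hi_i + 1L]) * (theta[hi_i + 1L] - theta[hi_i])
  }
  c(lower, upper)
}

#' @export
print.tat_fit <- function(x, ...) {
  cat(sprintf("TAT model fit (%s outcome), %d patients / %d windows\n",
              x$outcome, x$n_patients, x$n_windows))
  print(x$params)
  cat(sprintf("  log-likelihood %.2f; theta 95%% profile CI [%.3g, %.3g]%s\n",
              x$log_likelihood, x$ci$lower, x$ci$upper,
              if (x$converged) "" else " (refinement did not converge)"))
  if (!x$identifiable) cat("  note: flat likelihood in theta - parameter weakly identified\n")
  invisible(x)
}

#' Lag maximising the reverse correlation of peak flow with adherence
#'
#' Scans a grid of candidate lags; for each, smooths the daily adherence
#' series with the trailing exponential kernel of that mean lag and computes
#' the Pearson correlation with the daily peak-flow series. Returns the lag
#' with the highest correlation, breaking ties toward the smaller lag. A
#' result whose best correlation is indistinguishable from noise
#' (|r| < 2 / sqrt(n)) is flagged.
#'
#' @param daily_scores Numeric vector of daily adherence scores.
#' @param pefr Numeric vector of daily peak-flow readings, same indexing.
#' @param lag_grid Candidate lags in hours (default 0 to 72 by 6).
#' @return The selected lag (hours), with attributes `correlation` (vector
#'   over the grid) and `low_confidence`.
#' @export
reverse_correlation_lag <- function(daily_scores, pefr,
                                    lag_grid = seq(0, 72, by = 6)) {
  stopifnot(length(daily_scores) == length(pefr))
  ok <- is.finite(daily_scores) & is.finite(pefr)
  if (sum(ok) < 14L) {
    stop("need at least 14 overlapping daily observations", call. = FALSE)
  }
  lag_grid <- sort(lag_grid)
  cors <- vapply(lag_grid, function(tau) {
    sm <- ewma_lag(daily_scores, tau, dt = 24)
    suppressWarnings(stats::cor(sm[ok], pefr[ok]))
  }, numeric(1))
  cors[!is.finite(cors)] <- -Inf
  best <- which.max(cors)  # first maximum = smallest lag on ties
  structure(lag_grid[best], correlation = cors,
            low_confidence = !is.finite(cors[best]) ||
              abs(cors[best]) < 2 / sqrt(sum(ok)))
}

#' Fit the adherence model against daily peak-flow series
#'
#' Maximises the Gaussian log-likelihood of a linear model of daily PEFR on
#' the lag-smoothed daily adherence score, with a separate intercept per
#' patient absorbing baseline lung-function differences, over (half-life,
#' beta, theta, tau). Same deterministic grid-then-refine pattern as
#' [fit_exacerbation_model()]; the common slope is reported as `gamma1` and
#' the grand intercept as `gamma0`.
#'
#' @param cohort List of [patient_record()]s with daily `pefr` series.
#' @param search_space Grid axes from [tat_search_space()] (the `tau` axis is
#'   used here).
#' @param step Integration step in hours for the daily scores (default 0.5).
#' @return A `tat_fit` object (see [fit_exacerbation_model()]); `params$tau`
#'   carries the fitted lag.
#' @export
fit_pefr_model <- function(cohort, search_space = tat_search_space(),
                           step = 0.5) {
  engine <- tat_engine(cohort, window_hours = 24, step = step)
  P <- engine_pefr(engine, cohort)
  n_days <- nrow(P)
  n <- length(P)
  p_mean <- colMeans(P)
  Pc <- P - rep(p_mean, each = n_days)

  gauss_ll <- function(S) {  # S: smoothed scores, days x patients
    Sc <- S - rep(colMeans(S), each = n_days)
    sxx <- sum(Sc * Sc)
    if (sxx < 1e-12) return(structure(-Inf, coefficients = c(gamma0 = NA, gamma1 = 0)))
    b <- sum(Sc * Pc) / sxx
    rss <- sum((Pc - b * Sc)^2)
    sigma2 <- rss / n
    structure(-n / 2 * (log(2 * pi * sigma2) + 1),
              coefficients = c(gamma0 = mean(p_mean) - b * mean(S),
                               gamma1 = b))
  }

  hl <- search_space$half_life
  betas <- search_space$beta
  thetas <- search_space$theta
  taus <- search_space$tau
  ll_arr <- array(NA_real_,
                  dim = c(length(hl), length(betas), length(thetas), length(taus)))
  for (i in seq_along(hl)) {
    Cw <- engine_conc(engine, log(2) / hl[i])
    for (j in seq_along(betas)) {
      for (k in seq_along(thetas)) {
        A <- engine_scores(engine, Cw, betas[j], thetas[k])
        Am <- matrix(A, nrow = n_days)
        for (l in seq_along(taus)) {
          ll_arr[i, j, k, l] <- as.numeric(gauss_ll(ewma_lag_matrix(Am, taus[l])))
        }
      }
    }
  }
  best <- arrayInd(which.max(ll_arr), dim(ll_arr))
  best_par <- c(alpha = log(2) / hl[best[1L]], beta = betas[best[2L]],
                theta = thetas[best[3L]], tau = taus[best[4L]])
  ll_best <- max(ll_arr, na.rm = TRUE)

  eval_at <- function(alpha, beta, theta, tau) {
    Cw <- engine_conc(engine, alpha)
    Am <- matrix(engine_scores(engine, Cw, beta, theta), nrow = n_days)
    gauss_ll(ewma_lag_matrix(Am, tau))
  }
  neg <- function(p) {  # p = (half_life, beta, theta, tau)
    val <- tryCatch(
      as.numeric(eval_at(log(2) / p[1L], p[2L], p[3L], p[4L])),
      error = function(e) -Inf)
    if (!is.finite(val)) 1e10 else -val
  }
  lo <- c(min(hl), min(betas), min(thetas), min(taus))
  hi <- c(max(hl), max(betas), max(thetas), max(taus))
  start <- c(hl[best[1L]], betas[best[2L]], thetas[best[3L]], taus[best[4L]])
  opt <- box_nelder_mead(start, lo, hi, neg, maxit = 400)
  converged <- opt$convergence == 0L
  if (-opt$value >= ll_best) {
    best_par <- c(alpha = log(2) / opt$par[1L], beta = opt$par[2L],
                  theta = opt$par[3L], tau = opt$par[4L])
    ll_best <- -opt$value
  }
  final <- eval_at(best_par[["alpha"]], best_par[["beta"]], best_par[["theta"]],
                   best_par[["tau"]])

  prof <- apply(ll_arr, 3L, max, na.rm = TRUE)
  profile <- tibble::tibble(theta = thetas, log_likelihood = prof)
  ci_theta <- profile_ci(thetas, prof, ll_best)
  identifiable <- (max(prof) - min(prof)) > stats::qchisq(0.95, 1) / 2 &&
    abs(attr(final, "coefficients")[["gamma1"]]) > 1e-8

  grid_tbl <- expand.grid(half_life = hl, beta = betas, theta = thetas,
                          tau = taus, KEEP.OUT.ATTRS = FALSE)
  grid_tbl$log_likelihood <- as.numeric(ll_arr)

  structure(list(
    params = tat_params(alpha = best_par[["alpha"]], beta = best_par[["beta"]],
                        theta = best_par[["theta"]], tau = best_par[["tau"]]),
    coefficients = attr(final, "coefficients"),
    log_likelihood = ll_best,
    profile = profile,
    ci = tibble::tibble(parameter = "theta",
                        estimate = best_par[["theta"]],
                        lower = ci_theta[1L], upper = ci_theta[2L]),
    converged = converged,
    identifiable = identifiable,
    n_patients = engine$n_pat,
    n_windows = engine$n_win,
    outcome = "pefr",
    grid = tibble::as_tibble(grid_tbl)),
    class = "tat_fit")
}
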