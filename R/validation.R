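#' Standardize scores to z-scores
#'
#' Centres to mean 0 and scales to sample standard deviation 1 (denominator
#' n - 1), so logistic-regression odds ratios are reported per standard
#' deviation of the adherence score.
#'
#' @param scores Numeric vector with at least two distinct values.
#' @return Numeric vector of z-scores.
#' @export
standardize <- function(scores) {
  scores <- as.numeric(scores)
  s <- stats::sd(scores)
  if (!is.finite(s) || s == 0) {
    stop("scores are constant: cannot standardize", call. = FALSE)
  }
  (scores - mean(scores)) / s
}

#' Logistic regression of exacerbation on adherence with covariates
#'
#' Maximum-likelihood logistic regression of a window-level binary
#' exacerbation indicator on (standardized) adherence, plus age and sex
#' where supplied. Reports the odds ratio, Wald 95% confidence interval and
#' two-sided p-value per variable. Sex is coded as an indicator with
#' female = 1. An optional cluster-robust (sandwich) variance by patient is
#' available because windows from the same patient are correlated.
#'
#' @param windows Data frame with columns `exacerbation` (0/1), `adherence`,
#'   and optionally `age`, `sex` (`"male"`/`"female"` or 0/1) and
#'   `patient_id`.
#' @param cluster Optional column name for cluster-robust variance (e.g.
#'   `"patient_id"`).
#' @param metric Label recorded on the report (default `"adherence"`).
#' @return A tibble of class `tat_regression` with columns `term`,
#'   `odds_ratio`, `ci_lower`, `ci_upper`, `p_value`, plus attributes `n`,
#'   `metric`, `separation` and `model` (the underlying `glm`).
#' @export
logistic_validation <- function(windows, cluster = NULL, metric = "adherence") {
  stopifnot(all(c("exacerbation", "adherence") %in% names(windows)))
  y <- as.integer(windows$exacerbation)
  if (length(unique(y)) < 2L) {
    stop("binary outcome must include both classes", call. = FALSE)
  }
  dat <- data.frame(exacerbation = y, adherence = windows$adherence)
  form <- exacerbation ~ adherence
  if ("age" %in% names(windows)) {
    dat$age <- windows$age
    form <- stats::update(form, . ~ . + age)
  }
  if ("sex" %in% names(windows)) {
    sex <- windows$sex
    dat$sex <- if (is.numeric(sex)) sex else as.integer(tolower(sex) == "female")
    form <- stats::update(form, . ~ . + sex)
  }
  fit <- suppressWarnings(stats::glm(form, data = dat, family = stats::binomial()))
  separation <- !fit$converged || any(abs(stats::coef(fit)) > 15)

  vc <- if (is.null(cluster)) {
    summary(fit)$cov.scaled
  } else {
    sandwich::vcovCL(fit, cluster = windows[[cluster]])
  }
  est <- stats::coef(fit)
  se <- sqrt(diag(vc))[names(est)]
  names(se) <- names(est)
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  ord <- c(setdiff(names(est), "(Intercept)"), "(Intercept)")
  out <- tibble::tibble(
    term = ord,
    odds_ratio = unname(exp(est[ord])),
    ci_lower = unname(exp(est[ord] - 1.96 * se[ord])),
    ci_upper = unname(exp(est[ord] + 1.96 * se[ord])),
    p_value = unname(p[ord]))
  structure(out, n = nrow(dat), metric = metric, separation = separation,
            model = fit, class = c("tat_regression", class(out)))
}

#' Cumulative-dose (AUC-style) comparator adherence metric
#'
#' A comparator in the family of area-under-the-curve adherence metrics that
#' combine time-of-use with technique assessment: the technique-weighted
#' dose actually received in a window divided by the dose expected, with the
#' received dose capped at 1 within each scheduled dosing interval so that
#' extra actuations cannot compensate for missed intervals. Unlike the
#' time-above-threshold score it carries no pharmacokinetic decay, so it is
#' insensitive to *when* within the schedule doses are taken. This is a
#' documented stand-in for published AUC adherence metrics, not a line-by-line
#' reimplementation of any of them.
#'
#' @param record A [patient_record()].
#' @param window An [obs_window()]; must span at least one dosing interval.
#' @param interval_hours Prescribed dosing interval (default 12, twice
#'   daily).
#' @return A score in \[0, 1\].
#' @export
auc_comparator <- function(record, window, interval_hours = 12) {
  stopifnot(inherits(record, "patient_record"), inherits(window, "obs_window"))
  n_int <- floor(window$length / interval_hours + 1e-9)
  if (n_int < 1L) stop("window spans no complete dosing interval", call. = FALSE)
  ev <- record$events
  sel <- ev$time >= window$start & ev$time < window$start + n_int * interval_hours
  if (!any(sel)) return(0)
  slot <- floor((ev$time[sel] - window$start) / interval_hours)
  got <- rowsum(ev$delta[sel], group = slot)
  sum(pmin(got, 1)) / n_int
}

#' Side-by-side predictive validation of the TAT and AUC metrics
#'
#' Computes both adherence metrics on identical monthly patient windows,
#' standardizes each, and fits the same logistic regression of window-level
#' exacerbation (with age and sex covariates when available) per metric.
#' The result mirrors the usual reporting layout: one column block per
#' metric with odds ratio, 95% CI and p per variable.
#'
#' @param cohort List of [patient_record()]s with monthly exacerbation
#'   indicators.
#' @param params A [tat_params()] object for the TAT metric.
#' @param window_hours Window length in hours (default 720).
#' @param step Integration step for TAT scoring (default 0.1).
#' @param interval_hours Dosing interval for the comparator (default 12).
#' @param cluster Optional: `"patient_id"` for cluster-robust variances.
#' @return A list with `tat` and `auc` ([logistic_validation()] reports),
#'   `windows` (the assembled per-window table) and `comparison` (tidy
#'   two-metric summary table).
#' @export
compare_metrics <- function(cohort, params, window_hours = 720, step = 0.1,
                            interval_hours = 12, cluster = NULL) {
  engine <- tat_engine(cohort, window_hours = window_hours, step = step)
  y <- engine_outcomes(engine, cohort)
  Cw <- engine_conc(engine, params$alpha)
  tat <- engine_scores(engine, Cw, params$beta, params$theta)

  auc <- unlist(lapply(cohort, function(rec) {
    vapply(seq_len(engine$n_win_pp), function(w) {
      auc_comparator(rec, obs_window((w - 1) * window_hours, w * window_hours),
                     interval_hours = interval_hours)
    }, numeric(1))
  }))

  windows <- tibble::tibble(
    patient_id = engine$patient_id[engine$win_patient],
    window = engine$win_index,
    exacerbation = y,
    tat = tat,
    auc = auc,
    age = vapply(cohort, function(r) as.numeric(r$age), numeric(1))[engine$win_patient],
    sex = vapply(cohort, function(r) as.character(r$sex), character(1))[engine$win_patient])

  run_one <- function(metric) {
    d <- windows
    d$adherence <- standardize(d[[metric]])
    keep <- c("exacerbation", "adherence",
              if (!all(is.na(d$age))) "age",
              if (!all(is.na(d$sex))) "sex",
              "patient_id")
    logistic_validation(d[keep], cluster = cluster, metric = metric)
  }
  rep_tat <- run_one("tat")
  rep_auc <- run_one("auc")
  comparison <- rbind(
    tibble::tibble(metric = "tat", rep_tat[, ]),
    tibble::tibble(metric = "auc", rep_auc[, ]))
  list(tat = rep_tat, auc = rep_auc, windows = windows,
       comparison = tibble::as_tibble(comparison))
}
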