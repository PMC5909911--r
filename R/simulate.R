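#' Behavioural profile for the cohort simulator
#'
#' Describes how simulated patients deviate from a prescribed twice-daily
#' regimen: doses are missed with a per-patient probability, taken with
#' normally distributed timing jitter truncated at +/-6 hours (so doses
#' cannot swap order), occasionally "dumped" in short clusters of extra
#' actuations, and taken with technique errors drawn from a distribution
#' over the rule-table classes.
#'
#' `miss_probability` may be a single value (every patient identical) or a
#' length-2 range from which each patient's own miss probability is drawn
#' uniformly. The default range (0.05-0.7) produces a cohort taking on
#' average roughly 60% of prescribed doses with wide between-patient spread,
#' the regime reported for remotely monitored inhaler cohorts.
#'
#' Two presets are available: `"asthma"` (errors on ~15% of uses) and
#' `"copd"` (errors on ~60% of uses, matching the error burden described
#' for COPD cohorts).
#'
#' @param miss_probability Scalar or length-2 range in \[0, 1\].
#' @param timing_jitter_sd SD of dose-time jitter in hours (>= 0).
#' @param cluster_probability Probability that a day's two doses are taken
#'   together (evening dose merged onto the morning one, ~2 minutes apart):
#'   scalar or length-2 per-patient range (default 0). This emulates the
#'   common pattern of collapsing a twice-daily regimen into one sitting —
#'   a timing deviation that dose-count summaries misjudge.
#' @param dumping_rate Expected dumping clusters per month (>= 0; default 0).
#' @param error_distribution Named probability vector over
#'   `none`, `low_pifr`, `exhalation`, `low_pifr+exhalation`, `no_blister`,
#'   `no_inhalation`; must sum to 1.
#' @param drift Linear change in miss probability over the monitoring span
#'   (end-of-span minus start-of-span; default 0).
#' @param preset `"asthma"` or `"copd"` to load a canned error
#'   distribution.
#' @return A list of class `behavior_profile`.
#' @export
behavior_profile <- function(miss_probability = c(0.05, 0.7),
                             timing_jitter_sd = 2,
                             cluster_probability = 0,
                             dumping_rate = 0,
                             error_distribution = NULL,
                             drift = 0,
                             preset = c("asthma", "copd")) {
  preset <- match.arg(preset)
  if (is.null(error_distribution)) {
    error_distribution <- switch(preset,
      asthma = c(none = 0.85, low_pifr = 0.06, exhalation = 0.04,
                 `low_pifr+exhalation` = 0.02, no_blister = 0.015,
                 no_inhalation = 0.015),
      copd = c(none = 0.40, low_pifr = 0.25, exhalation = 0.15,
               `low_pifr+exhalation` = 0.10, no_blister = 0.05,
               no_inhalation = 0.05))
  }
  stopifnot(length(miss_probability) %in% 1:2,
            all(miss_probability >= 0 & miss_probability <= 1),
            length(cluster_probability) %in% 1:2,
            all(cluster_probability >= 0 & cluster_probability <= 1),
            timing_jitter_sd >= 0, dumping_rate >= 0)
  if (abs(sum(error_distribution) - 1) > 1e-8 || any(error_distribution < 0)) {
    stop("`error_distribution` must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(miss_probability = miss_probability,
                 timing_jitter_sd = timing_jitter_sd,
                 cluster_probability = cluster_probability,
                 dumping_rate = dumping_rate,
                 error_distribution = error_distribution,
                 drift = drift),
            class = "behavior_profile")
}

#' Outcome-generating model for the cohort simulator
#'
#' The inverse of the fitting module's likelihood: monthly exacerbations are
#' drawn Bernoulli with probability `plogis(gamma0 + gamma1 * x)` where `x`
#' is, by default, the true monthly time-above-threshold score computed at
#' `true_params` (`driver = "tat"`); setting `driver = "dose_count"` makes
#' outcomes depend only on the fraction of prescribed doses taken,
#' regardless of timing — a negative control for timing sensitivity. Daily
#' peak flow is drawn from a linear model on the lag-smoothed daily score
#' with a patient-specific baseline.
#'
#' Default slopes give a realistic signal: `gamma1 = -3` yields roughly a
#' halving of exacerbation odds per standard deviation of adherence when
#' scores spread over ~0.2-0.3 units, and `gamma0 = 0.75` puts the mean
#' monthly exacerbation probability near 35% at mid-range adherence.
#'
#' @param gamma0,gamma1 Logistic intercept and slope on the driver score.
#' @param true_params Ground-truth [tat_params()] (default: half-life 12 h,
#'   beta 73, theta 0.6, tau 18 h).
#' @param pefr_baseline_mean,pefr_baseline_sd Patient baseline peak flow
#'   (L/min).
#' @param pefr_slope L/min gained per unit of smoothed adherence.
#' @param pefr_noise_sd Daily measurement noise SD (L/min).
#' @param driver `"tat"` or `"dose_count"`.
#' @return A list of class `outcome_model`.
#' @export
outcome_model <- function(gamma0 = 0.75, gamma1 = -3,
                          true_params = tat_params(half_life = 12, beta = 73,
                                                   theta = 0.6, tau = 18),
                          pefr_baseline_mean = 350, pefr_baseline_sd = 60,
                          pefr_slope = 60, pefr_noise_sd = 25,
                          driver = c("tat", "dose_count")) {
  driver <- match.arg(driver)
  stopifnot(inherits(true_params, "tat_params"), pefr_noise_sd >= 0,
            pefr_baseline_sd >= 0)
  structure(list(gamma0 = gamma0, gamma1 = gamma1, true_params = true_params,
                 pefr_baseline_mean = pefr_baseline_mean,
                 pefr_baseline_sd = pefr_baseline_sd,
                 pefr_slope = pefr_slope, pefr_noise_sd = pefr_noise_sd,
                 driver = driver),
            class = "outcome_model")
}

# normal jitter truncated to [-lim, lim] via the inverse-CDF method
truncated_jitter <- function(n, sd, lim = 6) {
  if (sd == 0) return(numeric(n))
  lo <- stats::pnorm(-lim, sd = sd)
  hi <- stats::pnorm(lim, sd = sd)
  stats::qnorm(stats::runif(n, lo, hi), sd = sd)
}

#' Simulate a cohort of monitored patients
#'
#' Generates patients on a twice-daily regimen over `months` 30-day months:
#' scheduled dose times are jittered, thinned by misses, optionally
#' augmented by dumping clusters; each taken dose receives a technique-error
#' class (and hence a dose fraction via the rule table); monthly
#' exacerbations and daily peak flow are then drawn from the outcome model
#' evaluated on the patient's true adherence scores. Fully reproducible: the
#' seed is a required argument.
#'
#' @param n_patients Number of patients (>= 1).
#' @param months Number of 30-day months monitored (default 3).
#' @param profile A [behavior_profile()].
#' @param outcome An [outcome_model()].
#' @param seed Integer random seed (required).
#' @param interval_hours Prescribed dosing interval (default 12).
#' @param step Integration step (hours) used when computing the true scores
#'   (default 0.5).
#' @param pefr Also generate daily peak-flow series (default `TRUE`).
#' @param rules Technique rule table.
#' @return A list of [patient_record()]s, each carrying attributes
#'   `true_monthly_tat` and `miss_probability`.
#' @export
generate_cohort <- function(n_patients, months = 3,
                            profile = behavior_profile(),
                            outcome = outcome_model(),
                            seed,
                            interval_hours = 12, step = 0.5, pefr = TRUE,
                            rules = technique_rules()) {
  if (missing(seed)) stop("`seed` is required for reproducibility", call. = FALSE)
  stopifnot(n_patients >= 1, months >= 1,
            inherits(profile, "behavior_profile"),
            inherits(outcome, "outcome_model"))
  set.seed(seed)
  span <- months * 720
  sched <- seq(0, span - interval_hours, by = interval_hours)
  classes <- names(profile$error_distribution)
  label_sets <- strsplit(classes, "+", fixed = TRUE)
  label_sets[classes == "none"] <- list(character(0))
  deltas_by_class <- vapply(label_sets, delta_for_errors, numeric(1), rules = rules)

  miss_range <- rep_len(profile$miss_probability, 2L)
  clus_range <- rep_len(profile$cluster_probability, 2L)
  use_clus <- clus_range[2L] > 0
  records <- vector("list", n_patients)
  miss_ps <- stats::runif(n_patients, miss_range[1L], miss_range[2L])
  clus_ps <- if (use_clus) {
    stats::runif(n_patients, clus_range[1L], clus_range[2L])
  } else {
    numeric(n_patients)
  }
  for (p in seq_len(n_patients)) {
    miss_p <- miss_ps[p]
    p_miss_t <- pmin(pmax(miss_p + profile$drift * (sched / span - 0.5), 0), 1)
    if (clus_ps[p] > 0) {
      # dose-clustering phenotype: on a clustered day the evening dose is
      # taken ~2 minutes after the morning one
      times_all <- sched + truncated_jitter(length(sched),
                                            profile$timing_jitter_sd)
      clustered <- stats::runif(length(sched) %/% 2L) < clus_ps[p]
      if (any(clustered)) {
        ev_idx <- 2L * which(clustered)
        times_all[ev_idx] <- times_all[ev_idx - 1L] + 2 / 60
      }
      taken <- stats::runif(length(sched)) >= p_miss_t
      times <- times_all[taken]
    } else {
      taken <- stats::runif(length(sched)) >= p_miss_t
      times <- sched[taken] +
        truncated_jitter(sum(taken), profile$timing_jitter_sd)
    }
    times <- pmin(pmax(times, 0), span)
    if (profile$dumping_rate > 0) {
      n_clusters <- stats::rpois(1L, profile$dumping_rate * months)
      if (n_clusters > 0) {
        for (cl in seq_len(n_clusters)) {
          t0 <- stats::runif(1, 0, span)
          sz <- sample(1:3, 1L)
          times <- c(times, t0 + (seq_len(sz) - 1L) * (2 / 60))
        }
        times <- pmin(times, span)
      }
    }
    cls <- sample(classes, length(times), replace = TRUE,
                  prob = profile$error_distribution)
    ord <- order(times)
    ev <- dose_events(times[ord],
                      deltas_by_class[match(cls, classes)][ord],
                      error_labels = label_sets[match(cls, classes)][ord])
    records[[p]] <- patient_record(sprintf("sim%04d", p), ev, span_hours = span,
                                   age = round(stats::rnorm(1, 67, 10)),
                                   sex = sample(c("female", "male"), 1L,
                                                prob = c(0.53, 0.47)))
    attr(records[[p]], "miss_probability") <- miss_p
  }

  engine <- tat_engine(records, window_hours = 720, step = step)
  tp <- outcome$true_params
  Cw <- engine_conc(engine, tp$alpha)
  A_true <- matrix(engine_scores(engine, Cw, tp$beta, tp$theta),
                   nrow = engine$n_win_pp)

  for (p in seq_len(n_patients)) {
    x <- switch(outcome$driver,
      tat = A_true[, p],
      dose_count = vapply(seq_len(months), function(w) {
        ev <- records[[p]]$events
        min(1, sum(ev$time >= (w - 1) * 720 & ev$time < w * 720) /
              (720 / interval_hours))
      }, numeric(1)))
    pr <- stats::plogis(outcome$gamma0 + outcome$gamma1 * x)
    records[[p]]$exacerbations <- stats::rbinom(months, 1L, pr)
    attr(records[[p]], "true_monthly_tat") <- A_true[, p]
  }

  if (pefr) {
    daily_eng <- tat_engine(records, window_hours = 24, step = step)
    Cd <- engine_conc(daily_eng, tp$alpha)
    D <- matrix(engine_scores(daily_eng, Cd, tp$beta, tp$theta),
                nrow = daily_eng$n_win_pp)
    tau <- if (is.na(tp$tau)) 0 else tp$tau
    Ds <- ewma_lag_matrix(D, tau)
    base <- stats::rnorm(n_patients, outcome$pefr_baseline_mean,
                         outcome$pefr_baseline_sd)
    for (p in seq_len(n_patients)) {
      records[[p]]$pefr <- base[p] + outcome$pefr_slope * Ds[, p] +
        stats::rnorm(nrow(Ds), 0, outcome$pefr_noise_sd)
    }
  }
  records
}

#' Write the canonical small fixtures used across the test-suite
#'
#' Produces, under `output_dir`: `regular_erratic.csv` (two patients with
#' identical monthly dose counts — one dosing regularly every 12 hours, one
#' taking the same number of doses in dense bursts followed by long gaps, so
#' its concentration spends a known, analytically computed fraction of time
#' below threshold), `parse_fixture.csv` (a tiny two-patient log exercising
#' the CSV dialect), and a simulated recovery cohort
#' (`recovery_events.csv`, `recovery_outcomes.csv`). A `manifest.csv`
#' records the construction constants, including the erratic patient's
#' below-threshold fraction at threshold 0.56 and half-life 12 h.
#'
#' @param output_dir Writable directory (created if needed).
#' @param seed Integer seed for the simulated cohort.
#' @param n_recovery Patients in the recovery cohort (default 50; the
#'   fixture is meant to be small).
#' @return Invisibly, a list with file paths and the constructed
#'   `erratic_below_fraction`.
#' @export
make_fixture_suite <- function(output_dir, seed, n_recovery = 50) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  alpha <- log(2) / 12
  theta <- 0.56
  span <- 720

  # regular: delta-1 dose every 12 h for 30 days
  regular <- patient_record("regular", dose_events(seq(0, span - 12, by = 12)),
                            span_hours = span)
  # erratic: 144-h cycles, 12 doses 4 h apart then a 100-h gap; same monthly
  # dose count as the regular patient (60)
  burst <- seq(0, 44, by = 4)
  erratic_times <- as.vector(outer(burst, seq(0, span - 144, by = 144), `+`))
  erratic <- patient_record("erratic", dose_events(sort(erratic_times)),
                            span_hours = span)

  # analytic below-threshold fraction of the erratic steady-state cycle:
  # peak after the burst decays through the gap and crosses theta at
  # 44 + log(C44 / theta) / alpha hours into the 144-h cycle
  S0 <- (1 - exp(-48 * alpha)) / (1 - exp(-4 * alpha))
  C44 <- S0 / (1 - exp(-144 * alpha))
  t_cross <- 44 + log(C44 / theta) / alpha
  below_fraction <- (144 - t_cross) / 144

  f_regular <- file.path(output_dir, "regular_erratic.csv")
  write_event_log(list(regular, erratic), f_regular)

  f_parse <- file.path(output_dir, "parse_fixture.csv")
  parse_df <- data.frame(
    patient_id = rep(c("p1", "p2"), each = 4L),
    timestamp = rep(sprintf("2000-01-%02dT08:00:00", 1:4), 2L),
    error_labels = c("", "low_pifr", "", "low_pifr;exhalation",
                     "", "", "no_blister", ""),
    stringsAsFactors = FALSE)
  utils::write.csv(parse_df, f_parse, row.names = FALSE)

  cohort <- generate_cohort(n_recovery, months = 3, seed = seed, pefr = FALSE)
  f_events <- file.path(output_dir, "recovery_events.csv")
  write_event_log(cohort, f_events)
  f_outcomes <- file.path(output_dir, "recovery_outcomes.csv")
  out_df <- do.call(rbind, lapply(cohort, function(r) {
    data.frame(patient_id = r$patient_id, window = seq_along(r$exacerbations),
               exacerbation = r$exacerbations, age = r$age, sex = r$sex,
               stringsAsFactors = FALSE)
  }))
  utils::write.csv(out_df, f_outcomes, row.names = FALSE)

  f_manifest <- file.path(output_dir, "manifest.csv")
  utils::write.csv(data.frame(
    key = c("seed", "alpha", "theta", "erratic_below_fraction"),
    value = c(seed, alpha, theta, below_fraction)),
    f_manifest, row.names = FALSE)

  invisible(list(regular_erratic = f_regular, parse = f_parse,
                 recovery_events = f_events, recovery_outcomes = f_outcomes,
                 manifest = f_manifest,
                 erratic_below_fraction = below_fraction))
}
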