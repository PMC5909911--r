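test_that("standardize centres and scales with the sample SD", {
  expect_equal(standardize(c(0, 1)), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  set.seed(21)
  x <- rnorm(50, 3, 7)
  z <- standardize(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  # affine invariance
  expect_equal(standardize(2.5 * x + 4), z, tolerance = 1e-12)
  expect_error(standardize(rep(1, 5)), "constant")
})

test_that("logistic validation reproduces the closed-form 2x2 odds ratio", {
  tab <- data.frame(
    exacerbation = rep(c(1, 0, 1, 0), c(10, 40, 20, 30)),
    adherence = rep(c(1, 1, 0, 0), c(10, 40, 20, 30)))
  rep <- logistic_validation(tab)
  or <- rep$odds_ratio[rep$term == "adherence"]
  expect_equal(or, (10 * 30) / (40 * 20), tolerance = 1e-6)
  expect_equal(attr(rep, "n"), 100L)
  # brute-force likelihood-grid oracle for the coefficient (intercept
  # profiled by 1-d optimisation at each slope)
  b_grid <- seq(-2, 0, by = 1e-4)
  ll <- vapply(b_grid, function(b) {
    -stats::optimize(function(a)
      -oracle_bernoulli_ll(tab$adherence, tab$exacerbation, a, b),
      interval = c(-3, 2), tol = 1e-9)$objective
  }, numeric(1))
  expect_equal(log(or), b_grid[which.max(ll)], tolerance = 1e-3)
})

test_that("null simulations give odds ratios near one", {
  set.seed(33)
  n <- 1000
  d <- data.frame(exacerbation = rbinom(n, 1, 0.3), adherence = rnorm(n))
  rep <- logistic_validation(d)
  expect_equal(rep$odds_ratio[rep$term == "adherence"], 1, tolerance = 0.2)
  expect_gt(rep$p_value[rep$term == "adherence"], 0.001)
})

test_that("covariates and cluster-robust variance are supported", {
  set.seed(34)
  n <- 300
  d <- data.frame(
    exacerbation = rbinom(n, 1, 0.35),
    adherence = rnorm(n),
    age = rnorm(n, 67, 8),
    sex = sample(c("female", "male"), n, replace = TRUE),
    patient_id = rep(1:100, each = 3))
  rep1 <- logistic_validation(d)
  expect_setequal(rep1$term, c("adherence", "age", "sex", "(Intercept)"))
  expect_true(all(rep1$ci_lower < rep1$odds_ratio & rep1$odds_ratio < rep1$ci_upper))
  rep2 <- logistic_validation(d, cluster = "patient_id")
  # same point estimates, different variance
  expect_equal(rep2$odds_ratio, rep1$odds_ratio, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(rep2$ci_lower, rep1$ci_lower)))
  expect_error(logistic_validation(data.frame(exacerbation = rep(1, 5),
                                              adherence = rnorm(5))), "classes")
})

test_that("separation is flagged rather than reported silently", {
  d <- data.frame(exacerbation = rep(c(0, 1), each = 20),
                  adherence = rep(c(-1, 1), each = 20))
  rep <- suppressWarnings(logistic_validation(d))
  expect_true(attr(rep, "separation"))
})

test_that("the cumulative-dose comparator scores schedule compliance", {
  win <- obs_window(0, 240)  # 10 days, 20 intervals
  # all doses taken correctly on schedule
  rec <- patient_record("a", regular_events(10), 240)
  expect_equal(auc_comparator(rec, win), 1.0)
  # half the intervals missed, remainder perfect
  t_half <- seq(0, 228, by = 12)[rep(c(TRUE, FALSE), 10)]
  rec2 <- patient_record("b", dose_events(t_half), 240)
  expect_equal(auc_comparator(rec2, win), 0.5)
  # every dose taken but with low PIFR + exhalation error
  rec3 <- patient_record("c", dose_events(seq(0, 228, by = 12), 0.35), 240)
  expect_equal(auc_comparator(rec3, win), 0.35)
  # doubling up cannot compensate missed intervals
  t_dump <- c(0, 0.02, 0.04, 0.06)
  rec4 <- patient_record("d", dose_events(t_dump), 240)
  expect_equal(auc_comparator(rec4, obs_window(0, 24)), 0.5)
  # no events
  rec5 <- patient_record("e", dose_events(numeric(0)), 240)
  expect_equal(auc_comparator(rec5, win), 0)
  expect_error(auc_comparator(rec, obs_window(0, 6)), "interval")
})

test_that("the comparator equals mean technique delta under one dose per interval", {
  set.seed(8)
  d <- sample(c(1, 0.7, 0.5, 0.35), 20, replace = TRUE)
  t <- seq(0, 228, by = 12) + runif(20, 0, 11.9)
  rec <- patient_record("a", dose_events(t, d), 240)
  expect_equal(auc_comparator(rec, obs_window(0, 240)), mean(d), tolerance = 1e-12)
})

test_that("metrics perform comparably when outcomes depend only on dose counts", {
  p_fit <- tat_params(alpha = log(2) / 12, beta = 73, theta = 0.6)
  om <- outcome_model(driver = "dose_count")
  diffs <- vapply(1:6, function(s) {
    coh <- generate_cohort(200, months = 3, outcome = om, seed = 3000 + s,
                           pefr = FALSE)
    cmp <- compare_metrics(coh, p_fit, step = 0.5)
    abs(log(cmp$tat$odds_ratio[cmp$tat$term == "adherence"])) -
      abs(log(cmp$auc$odds_ratio[cmp$auc$term == "adherence"]))
  }, numeric(1))
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("identical metrics produce identical regression reports", {
  cohort <- generate_cohort(40, months = 3, seed = 12, pefr = FALSE)
  cmp <- compare_metrics(cohort, tat_params(alpha = log(2) / 12, beta = 73,
                                            theta = 0.6), step = 0.5)
  # reports are deterministic and aligned on the same windows
  cmp2 <- compare_metrics(cohort, tat_params(alpha = log(2) / 12, beta = 73,
                                             theta = 0.6), step = 0.5)
  expect_equal(cmp$tat$odds_ratio, cmp2$tat$odds_ratio, tolerance = 1e-12)
  expect_equal(nrow(cmp$windows), 120L)
  expect_true(all(c("tat", "auc") %in% cmp$comparison$metric))
  # outcomes were generated from the TAT model, so its association is negative
  expect_lt(cmp$tat$odds_ratio[cmp$tat$term == "adherence"], 1)
})
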