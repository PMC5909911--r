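true_p <- tat_params(alpha = log(2) / 12, beta = 73, theta = 0.6)

test_that("the exacerbation likelihood equals the direct Bernoulli sum", {
  # hand-set scores and outcomes on a 10-window toy cohort
  A <- c(0.05, 0.15, 0.3, 0.42, 0.5, 0.61, 0.7, 0.82, 0.9, 0.97)
  y <- c(1, 1, 1, 0, 1, 0, 0, 0, 1, 0)
  ll <- tatadherence:::bernoulli_profile_ll(A, y)
  g <- attr(ll, "coefficients")
  expect_equal(as.numeric(ll),
               oracle_bernoulli_ll(A, y, g[["gamma0"]], g[["gamma1"]]),
               tolerance = 1e-8)
  # profiled coefficients maximise: nudging either coefficient lowers the sum
  for (eps in c(-0.05, 0.05)) {
    expect_lt(oracle_bernoulli_ll(A, y, g[["gamma0"]] + eps, g[["gamma1"]]),
              as.numeric(ll) + 1e-10)
    expect_lt(oracle_bernoulli_ll(A, y, g[["gamma0"]], g[["gamma1"]] + eps),
              as.numeric(ll) + 1e-10)
  }
})

test_that("cohort likelihood agrees with the public per-record scoring path", {
  coh <- generate_cohort(8, months = 3, seed = 19, pefr = FALSE)
  ll <- exacerbation_log_likelihood(coh, true_p, step = 0.5)
  A_eng <- attr(ll, "scores")
  A_pub <- unlist(lapply(coh, function(r)
    windowed_scores(r, true_p, step = 0.5)$adherence))
  # the fitting engine integrates on a fixed grid while the reference
  # integrator adds exact event nodes; they agree to quadrature accuracy
  expect_equal(A_eng, A_pub, tolerance = 2e-3)
})

test_that("a null cohort yields a near-zero adherence slope", {
  om <- outcome_model(gamma1 = 0, gamma0 = -0.6)
  coh <- generate_cohort(150, months = 3, outcome = om, seed = 23, pefr = FALSE)
  ll <- exacerbation_log_likelihood(coh, true_p)
  g1 <- attr(ll, "coefficients")[["gamma1"]]
  expect_lt(abs(g1), 0.75)  # ~2 SE under the null at n = 450
  # likelihood close to the intercept-only model
  y <- unlist(lapply(coh, `[[`, "exacerbations"))
  p0 <- mean(y)
  ll0 <- sum(y * log(p0) + (1 - y) * log(1 - p0))
  expect_lt(as.numeric(ll) - ll0, stats::qchisq(0.999, 1) / 2)
})

test_that("the likelihood prefers the generating threshold over distant ones", {
  coh <- generate_cohort(300, months = 3, seed = 31, pefr = FALSE)
  at <- function(th) exacerbation_log_likelihood(
    coh, tat_params(alpha = log(2) / 12, beta = 73, theta = th))
  expect_gt(at(0.6), at(0.2))
  expect_gt(at(0.6), at(1.0))
})

test_that("degenerate outcomes raise a non-identifiability error", {
  coh <- generate_cohort(5, months = 2, seed = 3, pefr = FALSE)
  for (i in seq_along(coh)) coh[[i]]$exacerbations <- c(1L, 1L)
  expect_error(exacerbation_log_likelihood(coh, true_p), "identifiable")
  expect_error(fit_exacerbation_model(coh), "identifiable")
})

test_that("refinement never falls below the coarse grid", {
  coh <- generate_cohort(60, months = 3, seed = 47, pefr = FALSE)
  space <- tat_search_space(half_life = c(8, 12, 16), beta = c(50, 73, 100),
                            theta = seq(0.2, 1, by = 0.1))
  fit <- fit_exacerbation_model(coh, search_space = space)
  expect_gte(fit$log_likelihood, max(fit$grid$log_likelihood))
  # fitted parameters respect the declared bounds
  expect_true(fit$params$beta >= 50 && fit$params$beta <= 100)
  hl <- log(2) / fit$params$alpha
  expect_true(hl >= 8 && hl <= 16)
  # profile CI brackets the point estimate
  expect_true(fit$ci$lower <= fit$params$theta + 1e-9 &&
              fit$ci$upper >= fit$params$theta - 1e-9)
})

test_that("predictive power depends only weakly on threshold sharpness", {
  coh <- generate_cohort(150, months = 3, seed = 53, pefr = FALSE)
  space <- tat_search_space(half_life = 12, beta = c(50, 73, 100),
                            theta = seq(0.3, 0.9, by = 0.05))
  fit <- fit_exacerbation_model(coh, search_space = space, refine = FALSE)
  by_beta <- tapply(fit$grid$log_likelihood, fit$grid$beta, max)
  expect_lt(max(by_beta) - min(by_beta), 2)
})

test_that("reverse correlation recovers a constructed lag", {
  set.seed(61)
  daily <- runif(90)
  grid <- seq(0, 48, by = 6)
  # noiseless linear response to adherence smoothed at 18 h
  pefr <- 300 + 50 * tatadherence:::ewma_lag(daily, 18)
  got <- reverse_correlation_lag(daily, pefr, grid)
  expect_lte(abs(got - 18), 6)
  expect_false(attr(got, "low_confidence"))
  # instantaneous response: smallest grid lag wins the tie-break
  pefr0 <- 300 + 50 * daily
  expect_equal(as.numeric(reverse_correlation_lag(daily, pefr0, grid)), 0)
  # pure noise: flagged
  noise <- rnorm(90)
  expect_true(attr(reverse_correlation_lag(daily, noise, grid),
                   "low_confidence"))
  expect_error(reverse_correlation_lag(daily[1:5], pefr[1:5], grid), "14")
})

test_that("peak-flow fitting recovers threshold and lag from simulation", {
  om <- outcome_model(true_params = tat_params(half_life = 12, beta = 73,
                                               theta = 0.56, tau = 18),
                      pefr_slope = 60, pefr_noise_sd = 25)
  coh <- generate_cohort(60, months = 3, outcome = om, seed = 71)
  fit <- fit_pefr_model(coh)
  expect_s3_class(fit, "tat_fit")
  expect_lt(abs(fit$params$theta - 0.56), 0.1)
  expect_lt(abs(fit$params$tau - 18), 6)
  expect_gt(fit$coefficients[["gamma1"]], 0)  # more adherence, more peak flow
  expect_true(fit$identifiable)
  expect_gte(fit$log_likelihood, max(fit$grid$log_likelihood))
})

test_that("a flat peak-flow response is flagged unidentifiable", {
  om <- outcome_model(pefr_slope = 0, pefr_noise_sd = 25)
  coh <- generate_cohort(25, months = 2, outcome = om, seed = 73)
  space <- tat_search_space(half_life = c(9, 12, 18), beta = c(50, 100),
                            theta = seq(0.2, 1, by = 0.1), tau = c(0, 18, 36))
  fit <- fit_pefr_model(coh, search_space = space)
  expect_lt(abs(fit$coefficients[["gamma1"]]), 10)  # slope ~ 0 given PEFR scale
  expect_false(fit$identifiable)
})
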