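test_that("chi-squared is zero at a perfect fit and counts sd-of-mean units", {
  m <- toy_constant_model()
  prof <- exact_profile(m, sd = 0.3)
  expect_lt(chi_squared(m, prof), 1e-8)

  # one species one point off by exactly one sd of the mean gives 1.0
  one <- expression_profile(
    tibble::tibble(
      time = 0,
      species = c("premature", "mature", "synthesis"),
      mean = c(3, 4, 2), # P observed at 3, model predicts 2, sd = 1, n = 1
      sd = c(1, 1, 1)
    ),
    n_replicates = 1
  )
  expect_equal(chi_squared(m, one), 1, tolerance = 1e-10)
})

test_that("chi-squared equals a hand-summed weighted residual table", {
  m <- kinetic_model(rate_sigmoid(2, 4, 3, 1), 1.2, 0.5)
  times <- c(0, 2, 5)
  traj <- solve_kinetics(m, times)
  prof <- expression_profile(
    tibble::tibble(
      time = rep(times, 2),
      species = rep(c("premature", "mature"), each = 3),
      mean = c(traj$premature + c(0.1, -0.2, 0.05), traj$mature + c(-0.3, 0.4, 0)),
      sd = c(0.2, 0.3, 0.25, 0.5, 0.4, 0.6)
    ),
    n_replicates = 3
  )
  hand <- sum(c(0.1, -0.2, 0.05)^2 / (c(0.2, 0.3, 0.25)^2 / 3)) +
    sum(c(-0.3, 0.4, 0)^2 / (c(0.5, 0.4, 0.6)^2 / 3))
  expect_equal(chi_squared(m, prof), hand, tolerance = 1e-6)
})

test_that("chi-squared is invariant under joint rescaling of data and model", {
  m <- kinetic_model(rate_sigmoid(2, 4, 3, 1), 1.2, 0.5)
  prof <- simulate_profile(m, seed = 5, noise = noise_model(level = 0.1))
  base <- chi_squared(m, prof)
  cfac <- 3.7
  m_scaled <- kinetic_model(
    rate_sigmoid(2 * cfac, 4 * cfac, 3, 1), 1.2, 0.5
  )
  prof_scaled <- expression_profile(
    dplyr::mutate(tibble::as_tibble(prof),
      mean = mean * cfac, sd = sd * cfac
    ),
    n_replicates = 3
  )
  expect_equal(chi_squared(m_scaled, prof_scaled), base, tolerance = 1e-8)
})

test_that("goodness of fit gives a two-tailed p-value and AIC = chi2 + 2k", {
  # chi-squared median for dof = 10 is near 9.34: p should be large
  g <- goodness_of_fit(9.34, dof = 10, n_free_params = 3)
  expect_gt(g$p_value, 0.5)
  # independent CDF check by numerical integration of the density
  Fx <- integrate(function(x) x^4 * exp(-x / 2), 0, 9.34)$value /
    (2^5 * gamma(5))
  expect_equal(g$p_value, 2 * min(Fx, 1 - Fx), tolerance = 1e-6)
  # a perfect fit is suspicious under the two-tailed test
  expect_equal(goodness_of_fit(0, 5, 3)$p_value, 0)
  # nested fits with equal chi2: AIC difference is twice the parameter gap
  a_const <- goodness_of_fit(12, 20, 3)$aic
  a_sig <- goodness_of_fit(12, 17, 6)$aic
  expect_equal(a_sig - a_const, 2 * 3)
  expect_error(goodness_of_fit(5, 0, 3), class = "rnakinetics_domain_error")
})

test_that("noise-free constant data is recovered to 4 significant digits", {
  m <- toy_constant_model()
  prof <- exact_profile(m, sd = 0.05)
  fit <- fit_kinetics(prof, "no-reg", seed = 1)
  est <- c(fit$model$k1$params, fit$model$k2$params, fit$model$k3$params)
  expect_equal(unname(est), c(2, 1, 0.5), tolerance = 1e-4)
  expect_lt(fit$objective, 1e-6)
  expect_true(fit$converged)
  expect_identical(fit$dof, fit$n_obs - 3L)
})

test_that("an 'sp' model with 5% noise recovers sigmoid levels within 15%", {
  truth <- kinetic_model(
    rate_sigmoid(2, 6, 5, 1),
    rate_sigmoid(3, 1.2, 6, 1),
    rate_constant(0.6)
  )
  prof <- simulate_profile(truth,
    n_replicates = 3,
    noise = noise_model(level = 0.05), seed = 11
  )
  fit <- fit_kinetics(prof, "sp", seed = 12)
  rel <- function(est, tru) abs(est - tru) / tru
  expect_lt(rel(fit$model$k1$params[["h0"]], 2), 0.15)
  expect_lt(rel(fit$model$k1$params[["h1"]], 6), 0.15)
  expect_lt(rel(fit$model$k2$params[["h0"]], 3), 0.15)
  expect_lt(rel(fit$model$k2$params[["h1"]], 1.2), 0.15)
  expect_lt(rel(fit$model$k3$params[["h0"]], 0.6), 0.15)
})

test_that("single steady-state observation with synthesis inverts exactly", {
  prof <- expression_profile(
    tibble::tibble(
      time = 0,
      species = c("premature", "mature", "synthesis"),
      mean = c(9.25, 3.7 / 1.1, 3.7),
      sd = c(0.5, 0.2, 0.1)
    ),
    n_replicates = 4
  )
  fit <- fit_kinetics(prof, "no-reg")
  expect_identical(fit$model$k1$params[["h0"]], 3.7)
  expect_equal(fit$model$k2$params[["h0"]], 0.4, tolerance = 1e-12)
  expect_equal(fit$model$k3$params[["h0"]], 1.1, tolerance = 1e-12)
  expect_identical(fit$objective, 0)
  expect_true(fit$converged)
})

test_that("fitting is deterministic given a seed", {
  truth <- kinetic_model(rate_sigmoid(2, 5, 6, 1), 1.5, 0.5)
  prof <- simulate_profile(truth, seed = 3)
  f1 <- fit_kinetics(prof, "s", seed = 9)
  f2 <- fit_kinetics(prof, "s", seed = 9)
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$objective, f2$objective)
})

test_that("refine never worsens the objective and is a no-op when converged", {
  truth <- kinetic_model(rate_sigmoid(2, 5, 6, 1), 1.5, 0.5)
  prof <- simulate_profile(truth, seed = 4)
  full <- fit_kinetics(prof, "s", seed = 5)
  again <- refine_fit(full, extra_iter = 500)
  expect_lte(again$objective, full$objective)
  expect_equal(again$objective, full$objective, tolerance = 1e-8)
  expect_identical(refine_fit(full, extra_iter = 0), full)
  # a starved fit improves with more iterations
  starved <- fit_kinetics(prof, "s", max_iter = 5, n_starts = 1, seed = 5)
  recovered <- refine_fit(starved, extra_iter = 2000)
  expect_lt(recovered$objective, starved$objective)
  expect_error(
    refine_fit(full, class = "sd"),
    class = "rnakinetics_config_error"
  )
})

test_that("model selection ranks the generating class first on clean data", {
  truth <- kinetic_model(
    rate_sigmoid(2, 6, 5, 1),
    rate_constant(1.5),
    rate_sigmoid(0.4, 1.2, 7, 1)
  )
  prof <- exact_profile(truth, sd = 0.02)
  sel <- select_model(prof, seed = 21)
  expect_s3_class(sel, "model_selection")
  expect_identical(sel$class[1], "sd")
  expect_identical(sel$rank, seq_len(nrow(sel)))
  # richer classes never fit worse than classes nested within them
  obj <- setNames(sel$objective, sel$class)
  expect_lte(obj[["spd"]], obj[["sd"]] + 1e-6)
  expect_lte(obj[["sd"]], obj[["d"]] + 1e-6)
  expect_lte(obj[["s"]], obj[["no-reg"]] + 1e-6)
})

test_that("duplicate candidate classes tie and order deterministically", {
  prof <- simulate_profile(toy_constant_model(), seed = 6)
  sel <- select_model(prof, classes = c("s", "s"), seed = 7)
  expect_identical(sel$class, c("s", "s"))
  expect_lt(abs(sel$aic[1] - sel$aic[2]), 1e-6)
})

test_that("over-parameterized requests fail with a clear error", {
  prof <- simulate_profile(toy_constant_model(),
    times = c(0, 2, 4, 6, 8), seed = 8,
    include_synthesis = FALSE
  )
  # 3 x impulse = 18 free parameters > 10 observations
  expect_error(
    fit_kinetics(prof, "spd", variable_form = "impulse"),
    class = "rnakinetics_config_error"
  )
})

test_that("profile-likelihood intervals behave at the point estimate and refuse bad fits", {
  m <- toy_constant_model()
  prof <- exact_profile(m, sd = 0.01)
  fit <- fit_kinetics(prof, "no-reg", seed = 2)
  ci <- confidence_intervals(fit, parameters = c("k1.h0", "k3.h0"))
  expect_identical(ci$term, c("k1.h0", "k3.h0"))
  expect_true(all(ci$lower <= ci$estimate & ci$estimate <= ci$upper))
  # near noise-free data: intervals collapse onto the estimate
  expect_lt(max((ci$upper - ci$lower) / ci$estimate), 1e-2)
  broken <- fit
  broken$converged <- FALSE
  expect_error(confidence_intervals(broken), class = "rnakinetics_config_error")
})

test_that("intervals from a noisy constant fixture cover the truth", {
  prof <- simulate_profile(toy_constant_model(),
    seed = 31,
    noise = noise_model(level = 0.1), sd_mode = "theoretical"
  )
  fit <- fit_kinetics(prof, "no-reg", seed = 32)
  ci <- confidence_intervals(fit, parameters = "k1.h0")
  expect_gt(ci$upper, ci$lower)
  expect_false(ci$lower_at_bound)
  expect_false(ci$upper_at_bound)
  # the interval is a plausible neighbourhood of the true level 2
  expect_lt(ci$lower, 2.5)
  expect_gt(ci$upper, 1.6)
})
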