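test_that("steady state inverts to P = k1/k2, M = k1/k3", {
  expect_equal(steady_state(2, 1, 0.5), tibble::tibble(premature = 2, mature = 4))
  for (k in c(0.3, 1, 7)) {
    ss <- steady_state(k, k, k)
    expect_equal(c(ss$premature, ss$mature), c(1, 1))
  }
  ss <- steady_state(3.7, 0.4, 1.1)
  expect_equal(ss$premature, 9.25)
  expect_equal(ss$mature, 3.7 / 1.1, tolerance = 1e-15)
  expect_error(steady_state(0, 1, 1), class = "rnakinetics_domain_error")
  expect_error(steady_state(1, -2, 1), class = "rnakinetics_domain_error")
})

test_that("initial conditions are the equilibrium of the rates at t0", {
  m <- toy_constant_model()
  expect_equal(
    initial_conditions(m, -3),
    tibble::tibble(premature = 2, mature = 4)
  )
  # sigmoid k2 rising 1 -> 4 around t1 = 10: far before, equilibrium uses h0
  m2 <- kinetic_model(rate_constant(2), rate_sigmoid(1, 4, 10, 2), rate_constant(0.5))
  ic <- initial_conditions(m2, -20)
  expect_equal(c(ic$premature, ic$mature), c(2, 4), tolerance = 1e-6)
  # impulse k1 starting at its h0 asymptote
  m3 <- kinetic_model(rate_impulse(1, 5, 2, 4, 9, 1), rate_constant(1), rate_constant(1))
  ic3 <- initial_conditions(m3, -1e6)
  expect_equal(c(ic3$premature, ic3$mature), c(1, 1), tolerance = 1e-9)
})

test_that("closed-form constant-rate solution matches hand values and an RK4 oracle", {
  # equilibrium start stays flat
  tr <- closed_form_constant(2, 1, 0.5, P0 = 2, M0 = 4, times = 0:10)
  expect_equal(tr$premature, rep(2, 11), tolerance = 1e-12)
  expect_equal(tr$mature, rep(4, 11), tolerance = 1e-12)
  # relaxation from empty state: P(1) = 1 - exp(-1), M(1) by two exponentials
  tr2 <- closed_form_constant(1, 1, 2, P0 = 0, M0 = 0, times = c(0, 1, 50))
  expect_equal(tr2$premature[2], 1 - exp(-1), tolerance = 1e-12)
  expect_equal(tr2$mature[2], 0.5 + 0.5 * exp(-2) - exp(-1), tolerance = 1e-12)
  expect_equal(tr2$premature[3], 1, tolerance = 1e-8)
  expect_equal(tr2$mature[3], 0.5, tolerance = 1e-8)
  # generic and degenerate (k2 = k3) branches against fine-step RK4
  cases <- list(
    c(k1 = 1, k2 = 1, k3 = 2, P0 = 0, M0 = 0),
    c(k1 = 3, k2 = 0.7, k3 = 0.7, P0 = 1, M0 = 1),
    c(k1 = 5, k2 = 2, k3 = 0.3, P0 = 4, M0 = 0.5)
  )
  for (cs in cases) {
    y <- rk4_constant(cs["k1"], cs["k2"], cs["k3"], cs["P0"], cs["M0"], t_end = 2)
    tr3 <- closed_form_constant(cs["k1"], cs["k2"], cs["k3"], cs["P0"], cs["M0"], c(0, 2))
    expect_equal(unname(c(tr3$premature[2], tr3$mature[2])), unname(y), tolerance = 1e-8)
  }
})

test_that("the numerical solver reproduces the closed form for constant rates", {
  set.seed(42)
  errs <- replicate(20, {
    k1 <- exp(runif(1, log(0.1), log(30)))
    k2 <- exp(runif(1, log(0.1), log(10)))
    k3 <- if (runif(1) < 0.2) k2 else exp(runif(1, log(0.05), log(5)))
    P0 <- runif(1, 0, 3) * k1 / k2
    M0 <- runif(1, 0, 3) * k1 / k3
    times <- sort(c(0, runif(8, 0, 16)))
    ref <- closed_form_constant(k1, k2, k3, P0, M0, times)
    sol <- solve_kinetics(kinetic_model(k1, k2, k3), times,
      initial = c(premature = P0, mature = M0)
    )
    max(
      max_rel_err(sol$premature, ref$premature),
      max_rel_err(sol$mature, ref$mature)
    )
  })
  expect_lt(max(errs), 1e-5)
})

test_that("solver agrees with an independent deSolve integration for variable rates", {
  skip_if_not_installed("deSolve")
  m <- kinetic_model(
    rate_impulse(2, 8, 3, 3, 9, 1.5),
    rate_sigmoid(1, 4, 6, 0.8),
    rate_constant(0.6)
  )
  times <- seq(0, 16, by = 0.5)
  sol <- solve_kinetics(m, times, rtol = 1e-8, atol = 1e-10)
  ic <- initial_conditions(m, 0)
  dsol <- deSolve::ode(
    y = c(P = ic$premature, M = ic$mature),
    times = times,
    func = function(t, y, parms) {
      k1 <- rate_eval(m$k1, t); k2 <- rate_eval(m$k2, t); k3 <- rate_eval(m$k3, t)
      list(c(k1 - k2 * y[1], k2 * y[1] - k3 * y[2]))
    },
    rtol = 1e-8, atol = 1e-10
  )
  expect_lt(max_rel_err(sol$premature, dsol[, "P"]), 1e-5)
  expect_lt(max_rel_err(sol$mature, dsol[, "M"]), 1e-5)
})

test_that("trajectories converge to the steady state of the final rate asymptotes", {
  m <- kinetic_model(
    rate_sigmoid(2, 6, 4, 1),
    rate_sigmoid(3, 1.5, 5, 1),
    rate_constant(0.5)
  )
  t_far <- 5 + 20 / 0.5
  sol <- solve_kinetics(m, c(0, t_far))
  expect_equal(sol$premature[2], 6 / 1.5, tolerance = 1e-3)
  expect_equal(sol$mature[2], 6 / 0.5, tolerance = 1e-3)
})

test_that("trajectories stay non-negative", {
  # sharply dropping synthesis pushes abundances toward zero
  m <- kinetic_model(
    rate_sigmoid(10, 0.001, 2, 8),
    rate_constant(5),
    rate_constant(3)
  )
  sol <- solve_kinetics(m, seq(0, 20, by = 0.1))
  expect_true(all(sol$premature >= 0))
  expect_true(all(sol$mature >= 0))
})

test_that("rate scenarios shape the trajectories as expected", {
  # constant rates: flat profiles at the steady state
  solA <- solve_kinetics(toy_constant_model(), seq(0, 16, by = 1))
  expect_equal(solA$premature, rep(2, 17), tolerance = 1e-6)
  expect_equal(solA$mature, rep(4, 17), tolerance = 1e-6)
  # rising processing: premature permanently reduced, mature only transiently
  mB <- kinetic_model(rate_constant(2), rate_sigmoid(1, 3, 4, 1), rate_constant(0.5))
  tB <- 4 + 20 / 0.5
  solB <- solve_kinetics(mB, c(0, 2, 4, 8, tB))
  expect_lt(solB$premature[5], solB$premature[1])
  expect_lt(abs(solB$mature[5] - solB$mature[1]) / solB$mature[1], 1e-3)
  # rising synthesis: both species rise toward the doubled steady state
  mC <- kinetic_model(rate_sigmoid(2, 4, 4, 1), rate_constant(1), rate_constant(0.5))
  solC <- solve_kinetics(mC, c(0, tB))
  expect_gt(solC$premature[2], solC$premature[1])
  expect_gt(solC$mature[2], solC$mature[1])
  # final values reach the steady state of the final rate levels (4, 1, 0.5)
  expect_equal(solC$premature[2], 4, tolerance = 1e-3)
  expect_equal(solC$mature[2], 8, tolerance = 1e-3)
})

test_that("solver rejects invalid input", {
  m <- toy_constant_model()
  expect_error(solve_kinetics(m, c(2, 1)), class = "rnakinetics_domain_error")
  expect_error(solve_kinetics(m, c(1, 1)), class = "rnakinetics_domain_error")
  expect_error(solve_kinetics(m, numeric(0)), class = "rnakinetics_domain_error")
  expect_error(solve_kinetics(m, c(0, 1), rtol = -1), class = "rnakinetics_domain_error")
  expect_error(
    solve_kinetics(m, c(0, 1), initial = c(-1, 2)),
    class = "rnakinetics_domain_error"
  )
})

test_that("trajectory TSV round-trips to 12 significant digits", {
  m <- kinetic_model(rate_sigmoid(2, 4, 6, 1), 1.3, 0.7)
  sol <- solve_kinetics(m, default_time_grid())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectory_tsv(sol, path, command = "test", seed = 1)
  back <- read_trajectory_tsv(path)
  for (col in c("time", "premature", "mature", "synthesis")) {
    expect_equal(back[[col]], sol[[col]], tolerance = 1e-12)
  }
  hdr <- readLines(path, n = 3)
  expect_match(hdr[1], "^# rnakinetics ")
  expect_match(hdr[2], "^# command: test")
  expect_match(hdr[3], "^# seed: 1")
})
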