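test_that("constant and sigmoid forms evaluate to their defining values", {
  expect_identical(rate_eval(rate_constant(2), 17.3), 2)
  expect_identical(rate_eval(rate_constant(2), c(-5, 0, 100)), c(2, 2, 2))
  # at the transition time the sigmoid sits at the midpoint of its levels
  expect_equal(rate_eval(rate_sigmoid(1, 3, 4, 2), 4), 2)
  # far before/after the transition it approaches the levels
  expect_equal(rate_eval(rate_sigmoid(1, 3, 4, 2), -100), 1, tolerance = 1e-12)
  expect_equal(rate_eval(rate_sigmoid(1, 3, 4, 2), 100), 3, tolerance = 1e-12)
})

test_that("a steep impulse plateaus at the intermediate level between transitions", {
  rf <- rate_impulse(h0 = 1, h1 = 5, h2 = 1, t1 = 2, t2 = 6, beta = 50)
  # with beta = 50 both sigmoidal factors saturate at t = 4:
  # (h0 + (h1-h0)*1) * (h2 + (h1-h2)*1) / h1 = h1
  expect_equal(rate_eval(rf, 4), 5, tolerance = 1e-6)
})

test_that("parameter counts per form are 1, 4, 6", {
  expect_identical(n_params("constant"), 1L)
  expect_identical(n_params("sigmoid"), 4L)
  expect_identical(n_params("impulse"), 6L)
  expect_identical(n_params(c("constant", "impulse")), c(1L, 6L))
  expect_error(n_params("spline"), class = "rnakinetics_config_error")
})

test_that("asymptotes are the form's limits at t -> -Inf and +Inf", {
  expect_equal(rate_asymptotes(rate_constant(7)), c(initial = 7, final = 7))
  expect_equal(
    rate_asymptotes(rate_sigmoid(1, 3, 4, 2)),
    c(initial = 1, final = 3)
  )
  rf <- rate_impulse(1, 5, 2, t1 = 3, t2 = 8, beta = 1.5)
  expect_equal(rate_asymptotes(rf), c(initial = 1, final = 2))
  # cross-check numerically far outside the transition region
  expect_equal(rate_eval(rf, -1e6), 1, tolerance = 1e-9)
  expect_equal(rate_eval(rf, 1e6), 2, tolerance = 1e-9)
})

test_that("degenerate parameter settings collapse to simpler forms", {
  tt <- seq(-10, 30, length.out = 113)
  # sigmoid with equal levels is the constant function
  expect_equal(
    rate_eval(rate_sigmoid(2.5, 2.5, 4, 1.3), tt),
    rate_eval(rate_constant(2.5), tt),
    tolerance = 1e-12
  )
  # impulse with h2 = h1 reduces to the sigmoid before the second transition
  imp <- rate_impulse(1, 4, 4, t1 = 3, t2 = 20, beta = 2)
  sig <- rate_sigmoid(1, 4, 3, 2)
  tt2 <- seq(3 - 10, 20 - 1, length.out = 71)
  expect_equal(rate_eval(imp, tt2), rate_eval(sig, tt2), tolerance = 1e-6)
})

test_that("rising sigmoids are strictly increasing and evaluation vectorizes", {
  rf <- rate_sigmoid(0.5, 6, 8, 0.7)
  tt <- seq(-5, 25, length.out = 200)
  vals <- rate_eval(rf, tt)
  expect_true(all(diff(vals) > 0))
  expect_equal(vals, vapply(tt, function(t) rate_eval(rf, t), numeric(1)))
  expect_true(all(is.finite(vals) & vals > 0))
})

test_that("invalid rate parameters are rejected at construction", {
  expect_error(rate_constant(-1), class = "rnakinetics_config_error")
  expect_error(rate_constant(0), class = "rnakinetics_config_error")
  expect_error(rate_sigmoid(1, 2, 3, beta = 0), class = "rnakinetics_config_error")
  expect_error(rate_sigmoid(1, 2, 3, beta = -1), class = "rnakinetics_config_error")
  expect_error(
    rate_impulse(1, 2, 1, t1 = 5, t2 = 5, beta = 1),
    class = "rnakinetics_config_error"
  )
  expect_error(rate_fn("spline", c(h0 = 1)), class = "rnakinetics_config_error")
  expect_error(
    rate_fn("sigmoid", c(h0 = 1, h1 = 2, t1 = 3, beta = 1, junk = 9)),
    class = "rnakinetics_config_error"
  )
  expect_error(rate_fn("constant", c(h0 = NaN)), class = "rnakinetics_config_error")
  expect_error(rate_eval(rate_constant(1), Inf), class = "rnakinetics_domain_error")
  expect_error(rate_eval(rate_constant(1), NA_real_), class = "rnakinetics_domain_error")
})

test_that("model configuration files round-trip in YAML and JSON and reject unknown keys", {
  m <- kinetic_model(
    rate_sigmoid(2, 4, 6, 1),
    rate_constant(1.5),
    rate_impulse(0.5, 2, 0.8, 3, 9, 1.2)
  )
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_model_config(m, path)
    m2 <- read_model_config(path)
    expect_equal(
      c(m2$k1$form, m2$k2$form, m2$k3$form),
      c(m$k1$form, m$k2$form, m$k3$form)
    )
    expect_equal(m2$k1$params, m$k1$params, tolerance = 1e-12)
    expect_equal(m2$k3$params, m$k3$params, tolerance = 1e-12)
  }
  bad <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    k1 = list(form = "constant", params = list(h0 = 1)),
    k2 = list(form = "constant", params = list(h0 = 1)),
    k3 = list(form = "constant", params = list(h0 = 1)),
    k4 = list(form = "constant", params = list(h0 = 1))
  ), bad)
  expect_error(read_model_config(bad), class = "rnakinetics_config_error")
  bad2 <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    k1 = list(form = "constant", params = list(h0 = 1), colour = "red"),
    k2 = list(form = "constant", params = list(h0 = 1)),
    k3 = list(form = "constant", params = list(h0 = 1))
  ), bad2)
  expect_error(read_model_config(bad2), class = "rnakinetics_config_error")
})
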