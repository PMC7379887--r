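#' Replicate noise model for simulated profiles
#'
#' Gaussian replicate noise, either with a standard deviation proportional
#' to the true mean (`gaussian_cv`, the default; `sd = level * |mean|`) or
#' an absolute per-species standard deviation (`gaussian_sd`). Negative
#' draws are clipped to zero (and counted), since abundances are physical.
#'
#' @param kind `"gaussian_cv"` or `"gaussian_sd"`.
#' @param level Positive noise level: coefficient of variation for
#'   `gaussian_cv`, absolute sd for `gaussian_sd`. Default 0.1.
#' @param per_species Optional named list of per-species level overrides,
#'   e.g. `list(synthesis = 0.05)`.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(kind = c("gaussian_cv", "gaussian_sd"), level = 0.1,
                        per_species = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(level) || length(level) != 1 || !is.finite(level) || level <= 0) {
    abort_config("noise level must be a single positive number")
  }
  if (!is.null(per_species)) {
    if (is.null(names(per_species)) ||
        !all(names(per_species) %in% c("premature", "mature", "synthesis")) ||
        any(unlist(per_species) <= 0)) {
      abort_config("per_species overrides must be positive and named by species")
    }
  }
  structure(
    list(kind = kind, level = level, per_species = per_species),
    class = "noise_model"
  )
}

noise_sd <- function(noise, species, true_mean) {
  level <- noise$per_species[[species]] %||% noise$level
  if (noise$kind == "gaussian_cv") level * abs(true_mean) else rep(level, length(true_mean))
}

#' Default sampling grid for simulated time courses
#'
#' Twelve time points over 16 hours, denser early, mimicking typical
#' perturbation time-course designs.
#' @return Numeric vector of times (hours).
#' @export
default_time_grid <- function() {
  c(0, 0.5, 1, 2, 3, 4, 6, 8, 10, 12, 14, 16)
}

#' Draw a random ground-truth kinetic model
#'
#' Level parameters are drawn log-uniformly within plausible mammalian
#' ranges (defaults: synthesis 0.5–50 units/h, processing 0.5–20 /h,
#' degradation 0.05–5 /h). For variable rates the second level is tied to
#' the starting level by a log-uniform fold change (default 2–8x, random
#' direction, clamped to the range) so that a variable rate is genuinely
#' regulated; transition times fall inside the central part of the time
#' window and slopes are log-uniform in `beta_range`.
#'
#' @param cls A regulatory class (code or [regulatory_class()] object).
#' @param seed Integer seed; the draw is a pure function of seed + arguments.
#' @param ranges Named list of length-2 positive ranges for `k1`, `k2`, `k3`.
#' @param time_window Length-2 window (hours) containing the transitions.
#' @param fold_range Length-2 range of fold changes for variable rates.
#' @param beta_range Length-2 range of slopes (1/h).
#' @param variable_form Form used for variable rates when `cls` is a code.
#' @return A [kinetic_model()].
#' @export
random_model <- function(cls, seed,
                         ranges = list(k1 = c(0.5, 50), k2 = c(0.5, 20), k3 = c(0.05, 5)),
                         time_window = c(0, 16),
                         fold_range = c(2, 8),
                         beta_range = c(0.5, 4),
                         variable_form = c("sigmoid", "impulse")) {
  variable_form <- match.arg(variable_form)
  cls <- regulatory_class(cls, variable_form)
  for (nm in c("k1", "k2", "k3")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || any(r <= 0) || r[1] >= r[2]) {
      abort_config(sprintf("invalid parameter range for %s", nm))
    }
  }
  span <- diff(range(time_window))
  if (span <= 0) abort_config("time_window must have positive length")
  withr::with_seed(seed, {
    draw_rate <- function(form, range) {
      lo <- range[1]; hi <- range[2]
      h0 <- exp(runif(1, log(lo), log(hi)))
      if (form == "constant") return(rate_constant(h0))
      fold <- exp(runif(1, log(fold_range[1]), log(fold_range[2])))
      up_ok <- h0 * fold <= hi
      down_ok <- h0 / fold >= lo
      up <- if (up_ok && down_ok) runif(1) < 0.5 else up_ok
      h1 <- if (up) min(h0 * fold, hi) else max(h0 / fold, lo)
      beta <- exp(runif(1, log(beta_range[1]), log(beta_range[2])))
      if (form == "sigmoid") {
        t1 <- time_window[1] + runif(1, 0.1, 0.9) * span
        rate_sigmoid(h0, h1, t1, beta)
      } else {
        h2 <- min(max(h0 * exp(runif(1, log(0.5), log(2))), lo), hi)
        t1 <- time_window[1] + runif(1, 0.1, 0.5) * span
        t2 <- t1 + runif(1, 0.15, 0.4) * span
        rate_impulse(h0, h1, h2, t1, t2, beta)
      }
    }
    kinetic_model(
      draw_rate(cls$k1_form, ranges$k1),
      draw_rate(cls$k2_form, ranges$k2),
      draw_rate(cls$k3_form, ranges$k3)
    )
  })
}

#' Simulate a noisy replicated expression profile
#'
#' Solves the ODE system on `times`, then draws `n_replicates` Gaussian
#' observations per species and time point under the given [noise_model()]
#' (negative draws clipped to zero and counted in the `n_truncated`
#' attribute). Returns the aggregated profile alongside the clean
#' trajectory (attribute `trajectory`).
#'
#' @param model A [kinetic_model()] (the ground truth).
#' @param times Strictly increasing times (hours); default
#'   [default_time_grid()].
#' @param n_replicates Number of replicates (>= 2 so an sd can be estimated).
#' @param noise A [noise_model()].
#' @param seed Integer seed; identical seed and arguments give identical
#'   output.
#' @param include_synthesis If `TRUE` (nascent-RNA mode) the observed
#'   synthesis rate `k1(t)` is measured alongside the abundances.
#' @param sd_mode `"empirical"` reports the replicate sample sd;
#'   `"theoretical"` reports the exact noise-law sd of a single replicate
#'   (useful for calibration studies where the error variance is known by
#'   construction).
#' @return An [expression_profile()] with attributes `trajectory` (the
#'   noise-free `kinetic_trajectory`), `truth` (the generating model) and
#'   `n_truncated`.
#' @export
simulate_profile <- function(model, times = default_time_grid(),
                             n_replicates = 3, noise = noise_model(),
                             seed = 1, include_synthesis = TRUE,
                             sd_mode = c("empirical", "theoretical")) {
  sd_mode <- match.arg(sd_mode)
  stopifnot(inherits(model, "kinetic_model"), inherits(noise, "noise_model"))
  if (n_replicates < 2) abort_config("n_replicates must be at least 2")
  traj <- solve_kinetics(model, times)
  species <- c("premature", "mature", if (include_synthesis) "synthesis")
  n_truncated <- 0L
  rows <- withr::with_seed(seed, {
    purrr::map(species, function(sp) {
      truth <- traj[[sp]]
      sds <- noise_sd(noise, sp, truth)
      draws <- matrix(
        rnorm(n_replicates * length(truth), mean = rep(truth, each = n_replicates),
              sd = rep(sds, each = n_replicates)),
        nrow = n_replicates
      )
      n_truncated <<- n_truncated + sum(draws < 0)
      draws[draws < 0] <- 0
      tibble(
        time = times,
        species = sp,
        mean = colMeans(draws),
        sd = if (sd_mode == "empirical") apply(draws, 2, stats::sd) else sds
      )
    })
  })
  prof <- expression_profile(dplyr::bind_rows(rows), n_replicates = n_replicates)
  attr(prof, "trajectory") <- traj
  attr(prof, "truth") <- model
  attr(prof, "n_truncated") <- n_truncated
  prof
}
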