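#' Steady-state abundance of premature and mature RNA
#'
#' With constant rates the life-cycle system `dP/dt = k1 - k2 P`,
#' `dM/dt = k2 P - k3 M` settles at `P = k1 / k2`, `M = k1 / k3`.
#'
#' @param k1,k2,k3 Strictly positive rate values (vectors are recycled to a
#'   common length).
#' @return A tibble with columns `premature` and `mature`, one row per input.
#' @examples
#' steady_state(2, 1, 0.5) # P = 2, M = 4
#' @export
steady_state <- function(k1, k2, k3) {
  n <- max(length(k1), length(k2), length(k3))
  k1 <- rep_len(k1, n); k2 <- rep_len(k2, n); k3 <- rep_len(k3, n)
  if (any(!is.finite(c(k1, k2, k3))) || any(c(k1, k2, k3) <= 0)) {
    abort_domain("steady state undefined: all rates must be finite and strictly positive")
  }
  tibble(premature = k1 / k2, mature = k1 / k3)
}

#' Equilibrium initial conditions of a kinetic model
#'
#' The system is assumed at the steady state implied by the rate values at
#' the first time point (the pre-perturbation state): transitions placed
#' after `t0` start from a flat plateau.
#'
#' @param model A [kinetic_model()].
#' @param t0 Time (hours) at which to evaluate the rates.
#' @return A one-row tibble with columns `premature` and `mature`.
#' @export
initial_conditions <- function(model, t0) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.numeric(t0) || length(t0) != 1 || !is.finite(t0)) {
    abort_domain("t0 must be a single finite time")
  }
  steady_state(
    rate_eval(model$k1, t0),
    rate_eval(model$k2, t0),
    rate_eval(model$k3, t0)
  )
}

new_kinetic_trajectory <- function(time, premature, mature, synthesis) {
  out <- tibble(
    time = as.numeric(time),
    premature = as.numeric(premature),
    mature = as.numeric(mature),
    synthesis = as.numeric(synthesis)
  )
  class(out) <- c("kinetic_trajectory", class(out))
  out
}

#' Solve the RNA life-cycle ODE system
#'
#' Integrates `dP/dt = k1(t) - k2(t) P` and `dM/dt = k2(t) P - k3(t) M` with
#' an adaptive Cash-Karp Runge-Kutta (4,5) method, starting from the
#' equilibrium implied by the rates at `times[1]` (see
#' [initial_conditions()]) unless an explicit `initial` state is given.
#' Solutions are evaluated exactly at the requested times.
#'
#' @param model A [kinetic_model()].
#' @param times Strictly increasing numeric vector of output times (hours).
#' @param rtol,atol Relative and absolute integration tolerances.
#' @param initial Optional explicit initial state, a numeric vector
#'   `c(premature = P0, mature = M0)` (non-default; mainly for studying
#'   relaxation from out-of-equilibrium states).
#' @return A `kinetic_trajectory` tibble with columns `time`, `premature`,
#'   `mature` and `synthesis` (the synthesis rate `k1(t)`).
#' @examples
#' m <- kinetic_model(2, 1, 0.5)
#' solve_kinetics(m, seq(0, 16, by = 2))
#' @export
solve_kinetics <- function(model, times, rtol = 1e-6, atol = 1e-9,
                           initial = NULL) {
  stopifnot(inherits(model, "kinetic_model"))
  if (!is.numeric(times) || length(times) == 0 || any(!is.finite(times))) {
    abort_domain("times must be a nonempty vector of finite values")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort_domain("times must be strictly increasing")
  }
  if (!is.numeric(rtol) || !is.numeric(atol) || rtol <= 0 || atol <= 0) {
    abort_domain("rtol and atol must be positive")
  }
  if (is.null(initial)) {
    ic <- initial_conditions(model, times[1])
    P0 <- ic$premature
    M0 <- ic$mature
  } else {
    initial <- unlist(initial)
    if (length(initial) != 2 || any(!is.finite(initial)) || any(initial < 0)) {
      abort_domain("initial must be two finite non-negative values (premature, mature)")
    }
    if (!is.null(names(initial)) && all(c("premature", "mature") %in% names(initial))) {
      initial <- initial[c("premature", "mature")]
    }
    P0 <- initial[[1]]
    M0 <- initial[[2]]
  }
  forms <- form_code(model_forms(model))
  params <- list(
    unname(model$k1$params), unname(model$k2$params), unname(model$k3$params)
  )
  mat <- tryCatch(
    cpp_solve_kinetics(forms, params, times, P0, M0, rtol, atol),
    error = function(e) abort_numerical(conditionMessage(e))
  )
  if (min(mat) < -max(1e-6, 100 * atol)) {
    abort_numerical("integration produced substantially negative abundances")
  }
  mat[mat < 0] <- 0
  new_kinetic_trajectory(times, mat[, 1], mat[, 2], rate_eval(model$k1, times))
}

#' Closed-form trajectory for constant rates
#'
#' Exact analytic solution of the life-cycle system when all three rates are
#' constant, from arbitrary initial conditions at `times[1]`:
#' `P(t) = k1/k2 + (P0 - k1/k2) exp(-k2 tau)` with `tau = t - times[1]`, and
#' `M(t)` the matching two-exponential expression. When `k2` and `k3`
#' coincide (relative difference below `1e-7`) the degenerate-eigenvalue
#' branch with a `tau * exp(-k tau)` term is used. This is an independent
#' reference solution, implemented without the numerical integrator; the
#' test suite uses it as the oracle for [solve_kinetics()].
#'
#' @param k1,k2,k3 Positive constant rate values.
#' @param P0,M0 Initial premature and mature abundance at `times[1]`.
#' @param times Strictly increasing numeric vector (hours).
#' @return A `kinetic_trajectory` tibble.
#' @export
closed_form_constant <- function(k1, k2, k3, P0, M0, times) {
  vals <- c(k1, k2, k3)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    abort_domain("rates must be finite and strictly positive")
  }
  if (!is.numeric(times) || is.unsorted(times, strictly = TRUE)) {
    abort_domain("times must be strictly increasing")
  }
  tau <- times - times[1]
  Pss <- k1 / k2
  Mss <- k1 / k3
  A <- P0 - Pss
  P <- Pss + A * exp(-k2 * tau)
  if (abs(k2 - k3) < 1e-7 * max(k2, k3)) {
    k <- (k2 + k3) / 2
    M <- k1 / k + (M0 - k1 / k) * exp(-k * tau) + k * A * tau * exp(-k * tau)
  } else {
    B <- k2 * A / (k3 - k2)
    M <- Mss + (M0 - Mss - B) * exp(-k3 * tau) + B * exp(-k2 * tau)
  }
  new_kinetic_trajectory(times, P, M, rep(k1, length(times)))
}
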