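# Parameter transform ------------------------------------------------------
#
# Optimization runs in an unconstrained transformed space:
#   * level parameters (h0, h1, h2) and the slope beta: log scale
#     (positivity by construction);
#   * first transition time t1: untransformed hours, softly penalized
#     outside [t_first - span, t_last + span];
#   * impulse second transition: log(t2 - t1), enforcing t1 < t2.

theta_info <- function(forms, window) {
  span <- max(diff(range(window)), 1e-6)
  coords <- list()
  for (r in 1:3) {
    rate_nm <- c("k1", "k2", "k3")[r]
    form <- forms[r]
    pn <- RATE_PARAM_NAMES[[form]]
    for (p in pn) {
      kind <- if (grepl("^h", p) || p == "beta") "log" else if (p == "t1") "time" else "logdt"
      coords[[length(coords) + 1]] <- list(
        rate = r, rate_nm = rate_nm, param = p, kind = kind,
        term = paste0(rate_nm, ".", p)
      )
    }
  }
  list(
    forms = forms,
    forms_int = form_code(forms),
    coords = coords,
    terms = vapply(coords, function(c) c$term, character(1)),
    kinds = vapply(coords, function(c) c$kind, character(1)),
    rates = vapply(coords, function(c) c$rate, integer(1)),
    window = range(window),
    span = span
  )
}

pack_theta <- function(model, info) {
  theta <- numeric(length(info$coords))
  rates <- list(model$k1, model$k2, model$k3)
  for (i in seq_along(info$coords)) {
    cc <- info$coords[[i]]
    p <- rates[[cc$rate]]$params
    theta[i] <- switch(cc$kind,
      log = log(p[[cc$param]]),
      time = p[["t1"]],
      logdt = log(p[["t2"]] - p[["t1"]])
    )
  }
  names(theta) <- info$terms
  theta
}

# fast path: list of three bare numeric parameter vectors for the C++ kernel
unpack_params <- function(theta, info) {
  pars <- vector("list", 3)
  idx <- 1L
  for (r in 1:3) {
    form <- info$forms[r]
    pn <- RATE_PARAM_NAMES[[form]]
    v <- numeric(length(pn))
    for (j in seq_along(pn)) {
      kind <- info$kinds[idx]
      v[j] <- switch(kind,
        log = exp(theta[idx]),
        time = theta[idx],
        logdt = v[j - 1L] + exp(theta[idx]) # t2 follows t1 in canonical order
      )
      idx <- idx + 1L
    }
    pars[[r]] <- v
  }
  pars
}

unpack_model <- function(theta, info) {
  pars <- unpack_params(theta, info)
  mk <- function(r) {
    rate_fn(info$forms[r], stats::setNames(pars[[r]], RATE_PARAM_NAMES[[info$forms[r]]]))
  }
  kinetic_model(mk(1), mk(2), mk(3))
}

# quadratic penalty keeping transition times near the observation window
time_penalty <- function(pars, info) {
  lo <- info$window[1] - info$span
  hi <- info$window[2] + info$span
  pen <- 0
  for (r in 1:3) {
    form <- info$forms[r]
    tt <- if (form == "sigmoid") pars[[r]][3] else if (form == "impulse") pars[[r]][4:5] else NULL
    if (!is.null(tt)) {
      ex <- pmax(0, lo - tt, tt - hi) / info$span
      pen <- pen + 1e4 * sum(ex^2)
    }
  }
  pen
}

make_objective <- function(mats, info, rtol = 1e-6, atol = 1e-9) {
  forms_int <- info$forms_int
  force(mats)
  function(theta) {
    if (any(!is.finite(theta)) || any(abs(theta) > 50)) return(1e12)
    pars <- unpack_params(theta, info)
    val <- cpp_chi2(
      forms_int, pars, mats$times, mats$obs, mats$w, mats$has_syn, rtol, atol
    )
    if (!is.finite(val)) return(1e12)
    val + time_penalty(pars, info)
  }
}

# Chi-squared objective -----------------------------------------------------

#' Weighted chi-squared discrepancy between a model and a profile
#'
#' The objective minimized by [fit_kinetics()]: the model is solved at the
#' profile's time points (starting from the equilibrium implied by the rates
#' at the first time), and squared residuals of premature, mature and — when
#' observed — synthesis (predicted by `k1(t)`) are weighted by the inverse
#' variance of the replicate mean, `sd^2 / n_replicates`. Standard
#' deviations are floored at `max(1e-6, 0.01 |mean|)` before weighting.
#' Under Gaussian replicate error the minimized value is a chi-squared
#' statistic, which justifies the chi-squared goodness-of-fit test.
#'
#' @param model A [kinetic_model()].
#' @param data An [expression_profile()] (or data frame coercible to one).
#' @return The chi-squared value (non-negative scalar).
#' @export
chi_squared <- function(model, data) {
  stopifnot(inherits(model, "kinetic_model"))
  mats <- profile_matrices(data)
  if (mats$n_floored > 0) {
    rlang::inform(sprintf(
      "floored %d degenerate standard deviation(s) at max(1e-6, 0.01|mean|)",
      mats$n_floored
    ), class = "rnakinetics_floor_note")
  }
  val <- cpp_chi2(
    form_code(model_forms(model)),
    list(unname(model$k1$params), unname(model$k2$params), unname(model$k3$params)),
    mats$times, mats$obs, mats$w, mats$has_syn, 1e-6, 1e-9
  )
  if (!is.finite(val)) abort_numerical("chi-squared evaluation failed (integration error)")
  val
}

#' Goodness-of-fit statistics
#'
#' Two-tailed chi-squared test p-value and Akaike information criterion for
#' a minimized chi-squared objective. The p-value is
#' `p = min(1, 2 * min(F(chi2; dof), 1 - F(chi2; dof)))` with `F` the
#' chi-squared CDF — two-tailed, so that implausibly good fits (suggesting
#' overestimated variances or overfitting) are flagged as well as poor
#' ones. The AIC is `chi2 + 2 * n_free_params`, treating the chi-squared as
#' minus twice the Gaussian log-likelihood up to a data-only constant that
#' cancels when comparing regulatory models on the same data.
#'
#' @param objective Minimized chi-squared value.
#' @param dof Degrees of freedom (observations minus free parameters); must
#'   be >= 1.
#' @param n_free_params Total number of free parameters of the model.
#' @return A list with elements `p_value` and `aic`.
#' @export
goodness_of_fit <- function(objective, dof, n_free_params) {
  if (!is.numeric(objective) || objective < 0 || !is.finite(objective)) {
    abort_domain("objective must be a non-negative finite number")
  }
  if (dof < 1) {
    abort_domain("goodness-of-fit statistics undefined for dof < 1")
  }
  Fc <- pchisq(objective, df = dof)
  p <- min(1, 2 * min(Fc, 1 - Fc))
  list(p_value = p, aic = objective + 2 * n_free_params)
}

# Fitting --------------------------------------------------------------------

# Data-driven initial guess: invert the steady-state relations at the first
# and last observations to get level guesses, place the transition at the
# steepest observed change. Without observed synthesis the overall scale of
# the rates is not identified by a single point, so a unit degradation rate
# anchors the guess; multi-start jitter explores alternatives.
init_guess <- function(mats, info) {
  n <- length(mats$times)
  P <- mats$obs[, 1]; M <- mats$obs[, 2]
  eps <- 1e-6
  if (mats$has_syn) {
    k1f <- max(mats$obs[1, 3], eps); k1l <- max(mats$obs[n, 3], eps)
  } else {
    k1f <- max(M[1], eps); k1l <- max(M[n], eps)
  }
  first <- c(k1f, k1f / max(P[1], eps), k1f / max(M[1], eps))
  last <- c(k1l, k1l / max(P[n], eps), k1l / max(M[n], eps))
  first <- pmax(first, eps); last <- pmax(last, eps)
  t_star <- if (n >= 2) {
    rel <- abs(diff(P)) / max(max(abs(P)), eps) + abs(diff(M)) / max(max(abs(M)), eps)
    i <- which.max(rel)
    (mats$times[i] + mats$times[i + 1]) / 2
  } else {
    mean(info$window)
  }
  span <- info$span
  mk <- function(r) {
    switch(info$forms[r],
      constant = rate_constant(sqrt(first[r] * last[r])),
      sigmoid = rate_sigmoid(first[r], last[r], t_star, 1),
      impulse = rate_impulse(
        first[r], sqrt(first[r] * last[r]) * 2, last[r],
        t_star, min(t_star + span / 4, info$window[2]), 1
      )
    )
  }
  kinetic_model(mk(1), mk(2), mk(3))
}

run_optim <- function(theta0, objective, optimizer, max_iter) {
  method <- switch(optimizer, "nelder-mead" = "Nelder-Mead", "bfgs" = "BFGS")
  if (length(theta0) == 1) {
    # one-dimensional models: golden-section over a generous bracket
    opt <- optimise(function(v) objective(c(v)), interval = theta0 + c(-20, 20), tol = 1e-10)
    return(list(
      par = stats::setNames(opt$minimum, names(theta0)),
      value = opt$objective, counts = c(`function` = NA_integer_),
      convergence = 0L
    ))
  }
  stats::optim(
    theta0, objective,
    method = method,
    control = list(maxit = max_iter, reltol = 1e-10)
  )
}

new_kinetic_fit <- function(model, cls, objective, mats, info, converged,
                            n_iterations, optimizer, seed, data) {
  n_free <- sum(n_params(info$forms))
  dof <- mats$n_obs - n_free
  gof <- if (dof >= 1) goodness_of_fit(objective, dof, n_free) else list(p_value = NA_real_, aic = objective + 2 * n_free)
  structure(
    list(
      model = model,
      class = cls,
      objective = objective,
      dof = dof,
      n_obs = mats$n_obs,
      p_value = gof$p_value,
      aic = gof$aic,
      n_free_params = n_free,
      converged = converged,
      n_iterations = n_iterations,
      optimizer = optimizer,
      seed = seed,
      theta = pack_theta(model, info),
      info = info,
      data = data,
      ci = NULL
    ),
    class = "kinetic_fit"
  )
}

#' Fit rate-function parameters to an expression profile
#'
#' Estimates the parameters of the functional forms assigned to the three
#' kinetic rates by minimizing the weighted chi-squared objective (see
#' [chi_squared()]) with multi-start derivative-free or quasi-Newton
#' optimization. Level and slope parameters are optimized on the log scale
#' (positivity by construction); transition times are softly confined to
#' the observation window; the impulse ordering `t1 < t2` is enforced by
#' optimizing `log(t2 - t1)`.
#'
#' The first start is data-driven (steady-state inversion of the first and
#' last observations, transition at the steepest observed change); the
#' remaining starts perturb it with seeded log-normal jitter (sd 0.5 in the
#' transformed space). With identical seed and inputs the result is
#' reproducible exactly.
#'
#' Special case: single-time-point data with observed synthesis and the
#' all-constant class is solved exactly by inverting the steady-state
#' relations (`k1` = observed synthesis, `k2 = k1/P`, `k3 = k1/M`).
#'
#' @param data An [expression_profile()] (or data frame coercible to one,
#'   via `n_replicates` attribute handling in [expression_profile()]).
#' @param class Regulatory class: a code such as `"sd"` or a
#'   [regulatory_class()] object.
#' @param variable_form Functional form for the variable rates when `class`
#'   is a code: `"sigmoid"` (default) or `"impulse"`.
#' @param optimizer `"nelder-mead"` (default) or `"bfgs"`.
#' @param max_iter Iteration budget per start.
#' @param n_starts Number of multi-start optimizations.
#' @param seed Integer seed for the start jitter.
#' @param extra_starts Optional list of [kinetic_model()] objects (matching
#'   the class's forms, or nested within them) used as additional starts.
#' @return A `kinetic_fit` object; see [tidy.kinetic_fit()] and
#'   [glance.kinetic_fit()] for tabular views.
#' @export
fit_kinetics <- function(data, class, variable_form = c("sigmoid", "impulse"),
                         optimizer = c("nelder-mead", "bfgs"),
                         max_iter = 2000, n_starts = 5, seed = 1,
                         extra_starts = list()) {
  variable_form <- match.arg(variable_form)
  optimizer <- match.arg(optimizer)
  cls <- regulatory_class(class, variable_form)
  prof <- as_expression_profile(data)
  mats <- profile_matrices(prof)
  forms <- class_forms(cls)
  n_free <- sum(n_params(forms))
  dof <- mats$n_obs - n_free
  any_variable <- any(forms != "constant")

  # exact steady-state inversion: one time point, constants, observed synthesis
  if (!any_variable && length(mats$times) == 1 && mats$has_syn) {
    k1v <- unname(mats$obs[1, 3])
    P <- unname(mats$obs[1, 1]); M <- unname(mats$obs[1, 2])
    if (k1v <= 0 || P <= 0 || M <= 0) {
      abort_domain("steady-state inversion needs positive observations")
    }
    model <- kinetic_model(k1v, k1v / P, k1v / M)
    info <- theta_info(forms, range(mats$times) + c(-1, 1))
    return(new_kinetic_fit(
      model, cls, 0, mats, info,
      converged = TRUE, n_iterations = 0L, optimizer = optimizer,
      seed = seed, data = prof
    ))
  }
  if (any_variable && length(mats$times) < 2) {
    abort_domain("variable-rate fitting needs at least 2 time points")
  }
  if (dof < 1) {
    abort_config(sprintf(
      "model too complex for data: %d free parameters, %d observations",
      n_free, mats$n_obs
    ))
  }

  info <- theta_info(forms, range(mats$times))
  objective <- make_objective(mats, info)
  base_theta <- pack_theta(init_guess(mats, info), info)
  starts <- list(base_theta)
  for (m in extra_starts) {
    emb <- embed_model(m, forms, info$window)
    starts[[length(starts) + 1]] <- pack_theta(emb, info)
  }
  n_jitter <- max(0, n_starts - 1)
  if (n_jitter > 0) {
    jit_sd <- ifelse(info$kinds == "time", 0.125 * info$span, 0.5)
    jits <- withr::with_seed(seed, {
      purrr::map(seq_len(n_jitter), function(i) rnorm(length(base_theta), 0, jit_sd))
    })
    for (j in jits) starts[[length(starts) + 1]] <- base_theta + j
  }

  best <- NULL
  n_iter_total <- 0L
  for (th in starts) {
    res <- tryCatch(
      run_optim(th, objective, optimizer, max_iter),
      error = function(e) NULL
    )
    if (is.null(res)) next
    cnt <- res$counts[[1]]
    n_iter_total <- n_iter_total + (if (is.na(cnt)) 0L else as.integer(cnt))
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    abort_numerical("optimization failed on every start")
  }
  # continuation run from the best start firms up convergence
  res2 <- tryCatch(
    run_optim(best$par, objective, optimizer, max_iter),
    error = function(e) NULL
  )
  if (!is.null(res2) && res2$value <= best$value) {
    cnt <- res2$counts[[1]]
    n_iter_total <- n_iter_total + (if (is.na(cnt)) 0L else as.integer(cnt))
    best <- res2
  }
  model <- unpack_model(best$par, info)
  pure <- cpp_chi2(
    info$forms_int, unpack_params(best$par, info),
    mats$times, mats$obs, mats$w, mats$has_syn, 1e-6, 1e-9
  )
  if (!is.finite(pure)) pure <- best$value
  new_kinetic_fit(
    model, cls, pure, mats, info,
    converged = identical(best$convergence, 0L) || identical(best$convergence, 0),
    n_iterations = n_iter_total, optimizer = optimizer, seed = seed, data = prof
  )
}

#' Refine a fit with additional optimization iterations
#'
#' Continues the minimization from a previous fit's parameters; the refined
#' objective is guaranteed not to exceed the previous one (the previous fit
#' is kept when no improvement is found).
#'
#' @param prev A `kinetic_fit` from [fit_kinetics()].
#' @param data The profile the fit was computed on (defaults to the one
#'   stored in `prev`).
#' @param extra_iter Additional iteration budget; `0` returns `prev`
#'   unchanged.
#' @param optimizer Optionally switch optimizer (`"nelder-mead"`/`"bfgs"`).
#' @param class Optional regulatory class; must match `prev`'s forms.
#' @return A `kinetic_fit`.
#' @export
refine_fit <- function(prev, data = NULL, extra_iter = 1000, optimizer = NULL,
                       class = NULL) {
  stopifnot(inherits(prev, "kinetic_fit"))
  if (!is.null(class)) {
    cls <- regulatory_class(class)
    if (!identical(class_forms(cls), prev$info$forms)) {
      abort_config("requested regulatory class does not match the previous fit's forms")
    }
  }
  if (extra_iter == 0) return(prev)
  optimizer <- optimizer %||% prev$optimizer
  prof <- if (is.null(data)) prev$data else as_expression_profile(data)
  mats <- profile_matrices(prof)
  info <- prev$info
  objective <- make_objective(mats, info)
  res <- tryCatch(
    run_optim(prev$theta, objective, optimizer, extra_iter),
    error = function(e) NULL
  )
  if (is.null(res)) return(prev)
  pure <- cpp_chi2(
    info$forms_int, unpack_params(res$par, info),
    mats$times, mats$obs, mats$w, mats$has_syn, 1e-6, 1e-9
  )
  if (!is.finite(pure) || pure >= prev$objective) return(prev)
  out <- new_kinetic_fit(
    unpack_model(res$par, info), prev$class, pure, mats, info,
    converged = identical(res$convergence, 0L) || identical(res$convergence, 0),
    n_iterations = prev$n_iterations +
      (if (is.na(res$counts[[1]])) 0L else as.integer(res$counts[[1]])),
    optimizer = optimizer, seed = prev$seed, data = prof
  )
  out
}

#' Compare alternative regulatory models on one profile
#'
#' Fits every candidate regulatory class and ranks the fits by ascending
#' AIC (ties broken by fewer free parameters, then class code). Classes are
#' fitted in order of increasing complexity, and each fit is warm-started
#' from the embeddings of already-fitted nested simpler classes, so a
#' richer class can never end with a larger minimized chi-squared than a
#' class nested within it.
#'
#' @inheritParams fit_kinetics
#' @param classes Character vector of class codes (or list of
#'   [regulatory_class()] objects); at least two.
#' @return A tibble of class `model_selection`, one row per candidate,
#'   sorted by rank, with columns `class`, `n_free_params`, `objective`,
#'   `dof`, `p_value`, `aic`, `converged`, `rank` and a list-column `fit`.
#' @export
select_model <- function(data, classes = c("no-reg", "s", "p", "d", "sp", "sd", "pd", "spd"),
                         variable_form = c("sigmoid", "impulse"),
                         optimizer = c("nelder-mead", "bfgs"),
                         max_iter = 2000, n_starts = 5, seed = 1) {
  variable_form <- match.arg(variable_form)
  optimizer <- match.arg(optimizer)
  if (length(classes) < 2) abort_config("model selection needs at least 2 candidate classes")
  prof <- as_expression_profile(data)
  cls_list <- purrr::map(classes, regulatory_class, variable_form = variable_form)
  codes <- vapply(cls_list, function(c) c$code, character(1))
  ord <- order(vapply(cls_list, function(c) sum(n_params(class_forms(c))), numeric(1)), codes)
  fits <- stats::setNames(vector("list", length(cls_list)), NULL)
  errors <- character(0)
  for (pos in seq_along(ord)) {
    i <- ord[pos]
    cls <- cls_list[[i]]
    warm <- list()
    for (j in ord[seq_len(pos - 1)]) {
      fj <- fits[[j]]
      if (!is.null(fj) && fj$class$code != cls$code &&
          class_nested_in(fj$class, cls)) {
        warm[[length(warm) + 1]] <- fj$model
      }
    }
    # per-class seed derived from the class code so identical candidates
    # yield identical fits (exact ties, deterministic ordering)
    class_seed <- seed + 131L * (sum(utf8ToInt(cls$code)) %% 997L)
    fits[[i]] <- tryCatch(
      fit_kinetics(prof, cls,
        optimizer = optimizer, max_iter = max_iter,
        n_starts = n_starts, seed = class_seed, extra_starts = warm
      ),
      error = function(e) {
        errors <<- c(errors, paste0(cls$code, ": ", conditionMessage(e)))
        NULL
      }
    )
  }
  keep <- !vapply(fits, is.null, logical(1))
  if (!any(keep)) {
    abort_config(paste0(
      "no candidate class could be fitted:\n  ",
      paste(errors, collapse = "\n  ")
    ))
  }
  out <- purrr::map_dfr(which(keep), function(i) {
    f <- fits[[i]]
    tibble(
      class = f$class$code,
      n_free_params = f$n_free_params,
      objective = f$objective,
      dof = f$dof,
      p_value = f$p_value,
      aic = f$aic,
      converged = f$converged,
      fit = list(f)
    )
  })
  out <- out |>
    dplyr::arrange(.data$aic, .data$n_free_params, .data$class) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  if (length(errors)) attr(out, "failed_classes") <- errors
  class(out) <- unique(c("model_selection", class(out)))
  out
}

# Profile-likelihood confidence intervals ------------------------------------

#' Profile-likelihood confidence intervals for fitted parameters
#'
#' For each parameter the interval contains the values at which the
#' re-minimized chi-squared (all other parameters free) stays within the
#' chi-squared quantile with 1 degree of freedom at the requested level
#' (3.84 for 95%) of the fit's minimum. Search and re-optimization happen
#' in the transformed parameter space of [fit_kinetics()]; bounds that hit
#' the search window are flagged unbounded. For the impulse second
#' transition time the interval is computed on the profiled gap `t2 - t1`
#' and reported as `t1 + gap` at the inner optimum.
#'
#' @param fit A converged `kinetic_fit`.
#' @param data Profile to evaluate against (defaults to the fit's stored
#'   data).
#' @param level Confidence level, default 0.95.
#' @param parameters Optional character vector of term names (e.g.
#'   `"k1.h0"`) to restrict the computation to.
#' @return A tibble with columns `term`, `estimate`, `lower`, `upper`,
#'   `level`, `lower_at_bound`, `upper_at_bound`.
#' @export
confidence_intervals <- function(fit, data = NULL, level = 0.95,
                                 parameters = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (!isTRUE(fit$converged)) {
    abort_config("confidence intervals require a converged fit; refine it first")
  }
  if (fit$dof < 1) {
    abort_config("confidence intervals undefined for dof < 1")
  }
  prof <- if (is.null(data)) fit$data else as_expression_profile(data)
  mats <- profile_matrices(prof)
  info <- fit$info
  objective <- make_objective(mats, info)
  theta_hat <- fit$theta
  obj_min <- objective(theta_hat)
  thr <- obj_min + qchisq(level, df = 1)
  terms <- parameters %||% info$terms
  bad <- setdiff(terms, info$terms)
  if (length(bad)) {
    abort_config(paste0("unknown parameter(s): ", paste(bad, collapse = ", ")))
  }

  # minimize over all coordinates except j, with coordinate j fixed at v
  inner_min <- function(j, v, warm) {
    full <- function(sub) {
      th <- warm
      th[-j] <- sub
      th[j] <- v
      objective(th)
    }
    if (length(theta_hat) == 1) {
      th <- theta_hat; th[j] <- v
      return(list(value = objective(th), theta = th))
    }
    if (length(theta_hat) == 2) {
      opt <- optimise(function(s) full(s), interval = warm[-j] + c(-15, 15), tol = 1e-8)
      th <- warm; th[j] <- v; th[-j] <- opt$minimum
      return(list(value = opt$objective, theta = th))
    }
    res <- stats::optim(warm[-j], full,
      method = "Nelder-Mead",
      control = list(maxit = 400, reltol = 1e-9)
    )
    th <- warm; th[j] <- v; th[-j] <- res$par
    list(value = res$value, theta = th)
  }

  coord_limits <- function(j) {
    switch(info$kinds[j],
      log = theta_hat[j] + c(-20, 20),
      time = c(info$window[1] - 2 * info$span, info$window[2] + 2 * info$span),
      logdt = theta_hat[j] + c(-20, 20)
    )
  }

  natural_value <- function(j, v, th_inner) {
    cc <- info$coords[[j]]
    switch(info$kinds[j],
      log = exp(v),
      time = v,
      logdt = {
        t1_idx <- which(info$terms == paste0(cc$rate_nm, ".t1"))
        th_inner[t1_idx] + exp(v)
      }
    )
  }

  one_side <- function(j, dir) { # dir = -1 lower, +1 upper
    lim <- coord_limits(j)
    bound <- if (dir < 0) lim[1] else lim[2]
    step <- 0.05 * (if (info$kinds[j] == "time") info$span else 1)
    v_prev <- theta_hat[j]
    g_prev <- obj_min
    warm <- theta_hat
    repeat {
      v <- v_prev + dir * step
      hit_bound <- (dir < 0 && v <= bound) || (dir > 0 && v >= bound)
      if (hit_bound) v <- bound
      r <- inner_min(j, v, warm)
      warm <- r$theta
      if (r$value > thr) {
        # bracket between v_prev and v
        root <- tryCatch(
          uniroot(
            function(u) inner_min(j, u, warm)$value - thr,
            interval = sort(c(v_prev, v)), tol = 1e-4 * max(abs(step), 1e-3)
          )$root,
          error = function(e) v
        )
        ri <- inner_min(j, root, warm)
        return(list(value = natural_value(j, root, ri$theta), at_bound = FALSE))
      }
      if (hit_bound) {
        return(list(value = natural_value(j, v, r$theta), at_bound = TRUE))
      }
      v_prev <- v
      g_prev <- r$value
      step <- step * 1.7
    }
  }

  rows <- purrr::map(terms, function(tm) {
    j <- match(tm, info$terms)
    lo <- one_side(j, -1)
    hi <- one_side(j, +1)
    est <- natural_value(j, theta_hat[j], theta_hat)
    tibble(
      term = tm,
      estimate = est,
      lower = lo$value,
      upper = hi$value,
      level = level,
      lower_at_bound = lo$at_bound,
      upper_at_bound = hi$at_bound
    )
  })
  dplyr::bind_rows(rows)
}
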