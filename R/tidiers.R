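#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the parameters of a fitted kinetic model
#'
#' @param x A `kinetic_fit` from [fit_kinetics()].
#' @param ... Unused.
#' @return A tibble with one row per parameter: `rate`, `form`, `term`,
#'   `estimate`, and — when [confidence_intervals()] results are attached to
#'   the fit (`x$ci`) — `lower` and `upper`.
#' @export
tidy.kinetic_fit <- function(x, ...) {
  rates <- list(k1 = x$model$k1, k2 = x$model$k2, k3 = x$model$k3)
  out <- purrr::map_dfr(names(rates), function(nm) {
    rf <- rates[[nm]]
    tibble(
      rate = nm,
      form = rf$form,
      term = paste0(nm, ".", names(rf$params)),
      estimate = unname(rf$params)
    )
  })
  if (!is.null(x$ci)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(x$ci, "term", "lower", "upper"),
      by = "term"
    )
  }
  out
}

#' One-row summary of a kinetic fit
#'
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @return A one-row tibble: regulatory class, chi-squared objective,
#'   degrees of freedom, two-tailed p-value, AIC, free-parameter count,
#'   convergence flag, iteration count, optimizer and seed.
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(
    class = x$class$code,
    objective = x$objective,
    dof = x$dof,
    p_value = x$p_value,
    aic = x$aic,
    n_free_params = x$n_free_params,
    converged = x$converged,
    n_iterations = x$n_iterations,
    optimizer = x$optimizer,
    seed = x$seed
  )
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> class ", x$class$code,
    " | chi-squared = ", signif(x$objective, 6),
    " on ", x$dof, " dof",
    " | p = ", signif(x$p_value, 4),
    " | AIC = ", signif(x$aic, 6),
    if (x$converged) " | converged" else " | NOT converged",
    "\n",
    sep = ""
  )
  print(x$model)
  invisible(x)
}

#' Predicted and observed values of a fit, plot-ready
#'
#' Long-format table matching the observed profile with the fitted model's
#' predictions: one row per time point and species with the observed mean
#' and sd, the fitted value, and — when confidence intervals have been
#' attached to the fit — a sensitivity band obtained by re-evaluating the
#' model at each parameter's interval bounds one at a time and taking the
#' envelope.
#'
#' @param fit A `kinetic_fit`.
#' @param times Optional evaluation grid; defaults to the observed times.
#' @return A tibble with columns `time`, `species`, `observed_mean`,
#'   `observed_sd`, `fitted_value`, `ci_lo`, `ci_hi`.
#' @export
fitted_table <- function(fit, times = NULL) {
  stopifnot(inherits(fit, "kinetic_fit"))
  prof <- fit$data
  obs_times <- sort(unique(prof$time))
  times <- times %||% obs_times
  traj <- solve_kinetics(fit$model, times)
  pred <- traj |>
    tidyr::pivot_longer(c("premature", "mature", "synthesis"),
      names_to = "species", values_to = "fitted_value"
    )
  species_obs <- unique(prof$species)
  pred <- dplyr::filter(pred, .data$species %in% species_obs)
  out <- pred |>
    dplyr::left_join(
      prof |>
        dplyr::rename(observed_mean = "mean", observed_sd = "sd") |>
        as_tibble(),
      by = c("time", "species")
    ) |>
    dplyr::select(
      "time", "species", "observed_mean", "observed_sd", "fitted_value"
    )
  if (!is.null(fit$ci)) {
    envelope <- band_envelope(fit, times)
    out <- dplyr::left_join(out, envelope, by = c("time", "species"))
  } else {
    out$ci_lo <- NA_real_
    out$ci_hi <- NA_real_
  }
  out
}

# one-at-a-time parameter-bound envelope of the fitted curves
band_envelope <- function(fit, times) {
  info <- fit$info
  base <- fit$theta
  curves <- list()
  for (i in seq_len(nrow(fit$ci))) {
    tm <- fit$ci$term[i]
    j <- match(tm, info$terms)
    for (bound in c(fit$ci$lower[i], fit$ci$upper[i])) {
      th <- base
      th[j] <- switch(info$kinds[j],
        log = log(max(bound, 1e-12)),
        time = bound,
        logdt = log(max(bound - 1e-12, 1e-6))
      )
      traj <- tryCatch(
        solve_kinetics(unpack_model(th, info), times),
        error = function(e) NULL
      )
      if (!is.null(traj)) curves[[length(curves) + 1]] <- traj
    }
  }
  if (!length(curves)) {
    return(tibble(
      time = rep(times, 3),
      species = rep(c("premature", "mature", "synthesis"), each = length(times)),
      ci_lo = NA_real_, ci_hi = NA_real_
    ))
  }
  long <- purrr::map_dfr(curves, function(tr) {
    tidyr::pivot_longer(tr, c("premature", "mature", "synthesis"),
      names_to = "species", values_to = "value"
    )
  })
  long |>
    dplyr::group_by(.data$time, .data$species) |>
    dplyr::summarise(
      ci_lo = min(.data$value), ci_hi = max(.data$value), .groups = "drop"
    )
}
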