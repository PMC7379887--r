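#' Rate functions for the RNA life cycle
#'
#' Each kinetic rate of the RNA life cycle (synthesis `k1`, processing `k2`,
#' degradation `k3`) is modeled as a function of time with one of three
#' functional forms:
#'
#' * **constant** — a fixed level: `f(t) = h0`.
#' * **sigmoid** — an S-shaped transition between a starting level `h0` and a
#'   final level `h1`, centered at time `t1` with slope `beta`:
#'   `f(t) = h0 + (h1 - h0) * sigma(beta * (t - t1))` where
#'   `sigma(x) = 1 / (1 + exp(-x))`.
#' * **impulse** — a product of two sigmoids allowing double-sigmoid or
#'   bell-shaped responses, with a first transition from `h0` toward an
#'   intermediate/peak level `h1` at time `t1` and a second transition toward
#'   a final level `h2` at time `t2` (shared slope `beta`):
#'   `f(t) = (1/h1) * [h0 + (h1 - h0) * sigma(beta (t - t1))] *
#'   [h2 + (h1 - h2) * sigma(-beta (t - t2))]`.
#'
#' Level parameters (`h0`, `h1`, `h2`) are strictly positive rates, in RNA
#' units per hour for synthesis and per hour for processing/degradation.
#' Times are in hours; `beta` is in 1/hours and must be positive; the impulse
#' form requires `t1 < t2`.
#'
#' @param form One of `"constant"`, `"sigmoid"`, `"impulse"`.
#' @param params Named numeric vector (or list) of parameters for the chosen
#'   form: `h0` (constant); `h0, h1, t1, beta` (sigmoid);
#'   `h0, h1, h2, t1, t2, beta` (impulse). An unnamed vector in that canonical
#'   order is also accepted.
#' @return An object of class `rate_fn`.
#' @examples
#' rate_sigmoid(h0 = 1, h1 = 3, t1 = 4, beta = 2)
#' rate_eval(rate_constant(2), c(0, 5, 10))
#' @export
rate_fn <- function(form, params) {
  if (!is.character(form) || length(form) != 1 || is.na(form) ||
      !form %in% RATE_FORMS) {
    abort_config(paste0(
      "unknown rate functional form ",
      if (is.character(form) && length(form) == 1) paste0("'", form, "'") else "",
      "; must be one of: ", paste(RATE_FORMS, collapse = ", ")
    ))
  }
  params <- unlist(params)
  need <- RATE_PARAM_NAMES[[form]]
  if (!is.numeric(params)) {
    abort_config("rate parameters must be numeric")
  }
  if (is.null(names(params)) || !any(nzchar(names(params)))) {
    if (length(params) != length(need)) {
      abort_config(sprintf(
        "a %s rate takes %d parameters (%s); got %d unnamed values",
        form, length(need), paste(need, collapse = ", "), length(params)
      ))
    }
    names(params) <- need
  }
  extra <- setdiff(names(params), need)
  missing <- setdiff(need, names(params))
  if (length(extra) || length(missing)) {
    abort_config(sprintf(
      "a %s rate requires exactly the parameters {%s}%s%s",
      form, paste(need, collapse = ", "),
      if (length(missing)) paste0("; missing: ", paste(missing, collapse = ", ")) else "",
      if (length(extra)) paste0("; unknown: ", paste(extra, collapse = ", ")) else ""
    ))
  }
  params <- params[need]
  validate_rate_params(form, params)
  structure(list(form = form, params = params), class = "rate_fn")
}

RATE_FORMS <- c("constant", "sigmoid", "impulse")

RATE_PARAM_NAMES <- list(
  constant = "h0",
  sigmoid  = c("h0", "h1", "t1", "beta"),
  impulse  = c("h0", "h1", "h2", "t1", "t2", "beta")
)

# integer codes shared with the C++ kernel
form_code <- function(form) {
  match(form, RATE_FORMS) - 1L
}

validate_rate_params <- function(form, params) {
  if (any(!is.finite(params))) {
    abort_config("rate parameters must be finite")
  }
  levels <- params[grepl("^h", names(params))]
  if (any(levels <= 0)) {
    abort_config("rate level parameters (h0, h1, h2) must be strictly positive")
  }
  if ("beta" %in% names(params) && params[["beta"]] <= 0) {
    abort_config("slope parameter beta must be strictly positive")
  }
  if (form == "impulse" && params[["t1"]] >= params[["t2"]]) {
    abort_config("impulse transition times must satisfy t1 < t2")
  }
  invisible(params)
}

#' @rdname rate_fn
#' @param h0,h1,h2 Level parameters (strictly positive).
#' @param t1,t2 Transition times in hours (`t1 < t2` for the impulse).
#' @param beta Slope of the transition(s), 1/hours, strictly positive.
#' @export
rate_constant <- function(h0) rate_fn("constant", c(h0 = h0))

#' @rdname rate_fn
#' @export
rate_sigmoid <- function(h0, h1, t1, beta) {
  rate_fn("sigmoid", c(h0 = h0, h1 = h1, t1 = t1, beta = beta))
}

#' @rdname rate_fn
#' @export
rate_impulse <- function(h0, h1, h2, t1, t2, beta) {
  rate_fn("impulse", c(h0 = h0, h1 = h1, h2 = h2, t1 = t1, t2 = t2, beta = beta))
}

#' Evaluate a rate function over time
#'
#' @param rf A [rate_fn()] object.
#' @param t Numeric vector of finite times (hours).
#' @return Numeric vector of rate values, elementwise in the order of `t`.
#' @examples
#' rate_eval(rate_sigmoid(1, 3, 4, 2), 4) # midpoint (h0 + h1) / 2
#' @export
rate_eval <- function(rf, t) {
  stopifnot(inherits(rf, "rate_fn"))
  if (!is.numeric(t) || length(t) == 0 || any(!is.finite(t))) {
    abort_domain("evaluation times must be finite numbers")
  }
  p <- rf$params
  switch(rf$form,
    constant = rep(p[["h0"]], length(t)),
    sigmoid = p[["h0"]] +
      (p[["h1"]] - p[["h0"]]) * plogis(p[["beta"]] * (t - p[["t1"]])),
    impulse = {
      s1 <- plogis(p[["beta"]] * (t - p[["t1"]]))
      s2 <- plogis(-p[["beta"]] * (t - p[["t2"]]))
      (p[["h0"]] + (p[["h1"]] - p[["h0"]]) * s1) *
        (p[["h2"]] + (p[["h1"]] - p[["h2"]]) * s2) / p[["h1"]]
    }
  )
}

#' Number of free parameters of a functional form
#'
#' Constant, sigmoid and impulse forms carry 1, 4 and 6 parameters
#' respectively; used for degrees-of-freedom and AIC accounting.
#'
#' @param form Character vector of forms, or a [rate_fn()] object.
#' @return Integer vector of parameter counts.
#' @export
n_params <- function(form) {
  if (inherits(form, "rate_fn")) form <- form$form
  if (!is.character(form) || any(!form %in% RATE_FORMS)) {
    abort_config(paste0(
      "unknown functional form; must be one of: ",
      paste(RATE_FORMS, collapse = ", ")
    ))
  }
  unname(c(constant = 1L, sigmoid = 4L, impulse = 6L)[form])
}

#' Asymptotic levels of a rate function
#'
#' Limits of the rate as `t -> -Inf` and `t -> +Inf`: `(h0, h0)` for a
#' constant, `(h0, h1)` for a sigmoid, `(h0, h2)` for an impulse (the two
#' sigmoidal factors saturate to `h0 * h1 / h1` and `h1 * h2 / h1`).
#'
#' @param rf A [rate_fn()] object.
#' @return Named numeric vector `c(initial = ..., final = ...)`.
#' @export
rate_asymptotes <- function(rf) {
  stopifnot(inherits(rf, "rate_fn"))
  p <- rf$params
  out <- switch(rf$form,
    constant = c(p[["h0"]], p[["h0"]]),
    sigmoid = c(p[["h0"]], p[["h1"]]),
    impulse = c(p[["h0"]], p[["h2"]])
  )
  c(initial = out[1], final = out[2])
}

#' @export
print.rate_fn <- function(x, ...) {
  cat("<rate_fn> ", x$form, ": ",
    paste(names(x$params), signif(x$params, 6), sep = "=", collapse = ", "),
    "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
format.rate_fn <- function(x, ...) {
  paste0(x$form, "(", paste(names(x$params), signif(x$params, 6),
    sep = "=", collapse = ", "
  ), ")")
}
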