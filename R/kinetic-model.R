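#' Kinetic model of one gene's RNA life cycle
#'
#' Bundles the three kinetic rates: synthesis `k1` (RNA units/hour),
#' processing `k2` (1/hour) and degradation `k3` (1/hour), each a
#' [rate_fn()]. A bare positive number is promoted to a constant rate.
#'
#' @param k1,k2,k3 [rate_fn()] objects (or positive scalars, taken as
#'   constant rates) for synthesis, processing and degradation.
#' @return An object of class `kinetic_model`.
#' @examples
#' kinetic_model(k1 = 2, k2 = 1, k3 = 0.5)
#' kinetic_model(rate_sigmoid(2, 4, 4, 1), rate_constant(1), rate_constant(0.5))
#' @export
kinetic_model <- function(k1, k2, k3) {
  as_rate <- function(x, nm) {
    if (inherits(x, "rate_fn")) return(x)
    if (is.numeric(x) && length(x) == 1) return(rate_constant(x))
    abort_config(sprintf("%s must be a rate_fn or a positive scalar", nm))
  }
  structure(
    list(
      k1 = as_rate(k1, "k1"),
      k2 = as_rate(k2, "k2"),
      k3 = as_rate(k3, "k3")
    ),
    class = "kinetic_model"
  )
}

model_forms <- function(model) {
  c(model$k1$form, model$k2$form, model$k3$form)
}

#' @export
print.kinetic_model <- function(x, ...) {
  cls <- regulatory_class(x)
  cat("<kinetic_model> regulatory class:", cls$code, "\n")
  cat("  k1 (synthesis):  ", format(x$k1), "\n", sep = "")
  cat("  k2 (processing): ", format(x$k2), "\n", sep = "")
  cat("  k3 (degradation):", format(x$k3), "\n", sep = "")
  invisible(x)
}

#' Regulatory class of a kinetic model
#'
#' A regulatory class records, per rate, whether it is constant or variable
#' and by which functional form. Classes are coded by which rates vary:
#' `"s"` for synthesis (`k1`), `"p"` for processing (`k2`), `"d"` for
#' degradation (`k3`), concatenated in that order — e.g. `"sd"` means
#' variable synthesis, constant processing, variable degradation; `"sp"`
#' means variable synthesis and processing with constant degradation. The
#' all-constant class is coded `"no-reg"`.
#'
#' @param x A class code (character, e.g. `"sd"`), a [kinetic_model()], or an
#'   existing `regulatory_class`.
#' @param variable_form Functional form (`"sigmoid"` or `"impulse"`) assigned
#'   to the variable rates when `x` is a class code.
#' @return An object of class `regulatory_class` with fields `k1_form`,
#'   `k2_form`, `k3_form` and `code`.
#' @examples
#' regulatory_class("sd")
#' regulatory_class("sp", variable_form = "impulse")
#' @export
regulatory_class <- function(x, variable_form = c("sigmoid", "impulse")) {
  UseMethod("regulatory_class")
}

#' @export
regulatory_class.regulatory_class <- function(x, variable_form = NULL) x

#' @export
regulatory_class.kinetic_model <- function(x, variable_form = NULL) {
  new_regulatory_class(model_forms(x))
}

#' @export
regulatory_class.character <- function(x, variable_form = c("sigmoid", "impulse")) {
  variable_form <- match.arg(variable_form)
  if (length(x) != 1 || is.na(x)) {
    abort_config("a regulatory class code must be a single string")
  }
  if (x == "no-reg") {
    return(new_regulatory_class(rep("constant", 3)))
  }
  if (!grepl("^s?p?d?$", x) || !nzchar(x)) {
    abort_config(paste0(
      "invalid regulatory class code '", x, "'; expected 'no-reg' or a ",
      "subset of the letters s, p, d in that order (e.g. 's', 'sd', 'spd')"
    ))
  }
  letters_in <- strsplit(x, "")[[1]]
  forms <- ifelse(c("s", "p", "d") %in% letters_in, variable_form, "constant")
  new_regulatory_class(forms)
}

new_regulatory_class <- function(forms) {
  stopifnot(length(forms) == 3, all(forms %in% RATE_FORMS))
  vary <- forms != "constant"
  code <- if (!any(vary)) "no-reg" else paste(c("s", "p", "d")[vary], collapse = "")
  structure(
    list(k1_form = forms[1], k2_form = forms[2], k3_form = forms[3], code = code),
    class = "regulatory_class"
  )
}

class_forms <- function(cls) {
  c(cls$k1_form, cls$k2_form, cls$k3_form)
}

#' @export
print.regulatory_class <- function(x, ...) {
  cat("<regulatory_class> ", x$code, " (k1=", x$k1_form, ", k2=", x$k2_form,
    ", k3=", x$k3_form, ")\n",
    sep = ""
  )
  invisible(x)
}

# ---- nesting and embedding ------------------------------------------------

FORM_RANK <- c(constant = 0L, sigmoid = 1L, impulse = 2L)

# TRUE when every rate of `a` uses a form no richer than the same rate in `b`
class_nested_in <- function(a, b) {
  all(FORM_RANK[class_forms(a)] <= FORM_RANK[class_forms(b)])
}

# Re-express a fitted model in a richer class without changing the function
# it computes: constant -> sigmoid with h1 = h0; sigmoid -> impulse with
# h2 = h1 (the second factor is then exactly constant). Used to warm-start
# complex classes from nested simpler fits, which guarantees the minimized
# objective of a class never exceeds that of a class nested within it.
embed_model <- function(model, target_forms, window = c(0, 16)) {
  span <- max(diff(range(window)), 1e-6)
  mid <- mean(range(window))
  embed_rate <- function(rf, target) {
    cur <- rf$form
    if (cur == target) return(rf)
    if (FORM_RANK[cur] > FORM_RANK[target]) {
      abort_config("cannot embed a richer form into a simpler one")
    }
    p <- rf$params
    if (cur == "constant" && target == "sigmoid") {
      rate_sigmoid(p[["h0"]], p[["h0"]], mid, 1)
    } else if (cur == "constant" && target == "impulse") {
      rate_impulse(p[["h0"]], p[["h0"]], p[["h0"]],
        mid - span / 6, mid + span / 6, 1
      )
    } else { # sigmoid -> impulse
      rate_impulse(p[["h0"]], p[["h1"]], p[["h1"]],
        p[["t1"]], p[["t1"]] + span, p[["beta"]]
      )
    }
  }
  kinetic_model(
    embed_rate(model$k1, target_forms[1]),
    embed_rate(model$k2, target_forms[2]),
    embed_rate(model$k3, target_forms[3])
  )
}
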