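# Condition helpers. Three error classes cover the failure modes the package
# distinguishes: bad configuration (wrong forms, malformed files), bad values
# in an otherwise valid call (non-positive rates, non-finite times), and
# numerical failure (integrator breakdown, optimizer divergence).

abort_config <- function(message, ...) {
  abort(message, class = "rnakinetics_config_error", ...)
}

abort_domain <- function(message, ...) {
  abort(message, class = "rnakinetics_domain_error", ...)
}

abort_numerical <- function(message, ...) {
  abort(message, class = "rnakinetics_numerical_error", ...)
}

abort_usage <- function(message, ...) {
  abort(message, class = "rnakinetics_usage_error", ...)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# format a number for text output without losing precision (round-trips
# doubles through up to 15 significant digits)
num_chr <- function(x) sprintf("%.15g", x)
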