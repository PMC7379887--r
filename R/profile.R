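#' Replicated expression profile of one gene
#'
#' An expression profile records, per time point and RNA species, the mean
#' and standard deviation across replicates. Species are `premature` and
#' `mature` RNA abundance (RNA units) and, optionally, the observed
#' `synthesis` rate (RNA units/hour) measured from nascent RNA — the
#' nascent-RNA mode.
#'
#' Two input layouts are accepted:
#' * replicate-level: columns `time`, `species`, `replicate`, `value`; means
#'   and standard deviations are computed, and `n_replicates` inferred;
#' * pre-aggregated: columns `time`, `species`, `mean`, `sd`; then
#'   `n_replicates` must be supplied.
#'
#' @param data A data frame in one of the two layouts above.
#' @param n_replicates Number of replicates behind each mean (required for
#'   pre-aggregated input).
#' @return A tibble of class `expression_profile` with columns `time`,
#'   `species`, `mean`, `sd` and attribute `n_replicates`.
#' @export
expression_profile <- function(data, n_replicates = NULL) {
  df <- as_tibble(data)
  if (all(c("replicate", "value") %in% names(df))) {
    if (!all(c("time", "species") %in% names(df))) {
      abort_config("replicate-level input needs columns time, species, replicate, value")
    }
    counts <- df |>
      dplyr::count(.data$time, .data$species)
    if (length(unique(counts$n)) != 1) {
      abort_config("unbalanced replicates: every time/species must have the same count")
    }
    n_replicates <- counts$n[1]
    df <- df |>
      dplyr::group_by(.data$time, .data$species) |>
      dplyr::summarise(
        mean = mean(.data$value),
        sd = stats::sd(.data$value),
        .groups = "drop"
      )
  } else if (!all(c("time", "species", "mean", "sd") %in% names(df))) {
    abort_config(paste0(
      "expression profile needs columns time, species, mean, sd ",
      "(or time, species, replicate, value)"
    ))
  }
  if (is.null(n_replicates)) {
    abort_config("n_replicates is required for pre-aggregated profiles")
  }
  n_replicates <- as.integer(n_replicates)
  if (is.na(n_replicates) || n_replicates < 1) {
    abort_config("n_replicates must be a positive integer")
  }
  df <- df |>
    dplyr::select("time", "species", "mean", "sd") |>
    dplyr::arrange(.data$species, .data$time)
  validate_profile(df)
  structure_profile(df, n_replicates)
}

structure_profile <- function(df, n_replicates) {
  out <- as_tibble(df)
  attr(out, "n_replicates") <- as.integer(n_replicates)
  class(out) <- unique(c("expression_profile", class(out)))
  out
}

validate_profile <- function(df) {
  ok_species <- c("premature", "mature", "synthesis")
  if (!all(df$species %in% ok_species)) {
    abort_config(paste0(
      "unknown species '",
      paste(setdiff(unique(df$species), ok_species), collapse = "', '"),
      "'; species must be premature, mature or synthesis (lowercase)"
    ))
  }
  if (!all(c("premature", "mature") %in% df$species)) {
    abort_config("profile must contain both premature and mature species")
  }
  if (any(!is.finite(df$time)) || any(!is.finite(df$mean)) || any(!is.finite(df$sd))) {
    abort_config("profile contains non-finite values")
  }
  if (any(df$sd < 0)) {
    abort_config("standard deviations must be non-negative")
  }
  by_sp <- split(df$time, df$species)
  times <- sort(unique(df$time))
  for (sp in names(by_sp)) {
    tt <- sort(by_sp[[sp]])
    if (anyDuplicated(tt) || !identical(tt, times)) {
      abort_config("every species must be observed once at each time point")
    }
  }
  invisible(df)
}

as_expression_profile <- function(x, n_replicates = NULL) {
  if (inherits(x, "expression_profile")) return(x)
  expression_profile(x, n_replicates)
}

#' @export
print.expression_profile <- function(x, ...) {
  nrep <- attr(x, "n_replicates")
  cat(
    "<expression_profile> ", length(unique(x$time)), " time points, species: ",
    paste(sort(unique(x$species)), collapse = ", "),
    ", n_replicates = ", nrep, "\n",
    sep = ""
  )
  NextMethod()
}

n_replicates <- function(profile) {
  attr(profile, "n_replicates") %||% 1L
}

# Dense numeric view of a profile for the fitting kernel: per-time matrices
# of observed means and inverse variances of the mean. Standard deviations
# are floored at max(1e-6, 0.01 |mean|) so degenerate replicates cannot give
# infinite weight; the number of floored points is returned.
profile_matrices <- function(profile) {
  prof <- as_expression_profile(profile)
  nrep <- n_replicates(prof)
  wide_mean <- prof |>
    dplyr::select("time", "species", "mean") |>
    tidyr::pivot_wider(names_from = "species", values_from = "mean") |>
    dplyr::arrange(.data$time)
  wide_sd <- prof |>
    dplyr::select("time", "species", "sd") |>
    tidyr::pivot_wider(names_from = "species", values_from = "sd") |>
    dplyr::arrange(.data$time)
  has_syn <- "synthesis" %in% prof$species
  cols <- c("premature", "mature", if (has_syn) "synthesis")
  obs <- as.matrix(wide_mean[cols])
  sds <- as.matrix(wide_sd[cols])
  floor_val <- pmax(1e-6, 0.01 * abs(obs))
  n_floored <- sum(sds < floor_val)
  sds <- pmax(sds, floor_val)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    bad <- which(!is.finite(sds) | sds <= 0, arr.ind = TRUE)[1, ]
    abort_config(sprintf(
      "unusable standard deviation at time %g, species %s",
      wide_mean$time[bad[1]], cols[bad[2]]
    ))
  }
  list(
    times = wide_mean$time,
    obs = obs,
    w = nrep / sds^2,
    has_syn = has_syn,
    n_rep = nrep,
    n_obs = length(obs),
    n_floored = n_floored,
    species = cols
  )
}
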