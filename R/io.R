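# File formats --------------------------------------------------------------
#
# All tabular output is plain TSV with "." decimals, fixed column order, no
# quoting, and a reproducibility header of "#"-prefixed lines recording the
# package version, the generating command and the seed. Values are written
# with 15 significant digits so round-trips are exact to at least 12.

repro_header <- function(command = NA_character_, seed = NA,
                         extra = character(0)) {
  c(
    paste0("# rnakinetics ", as.character(packageVersion("rnakinetics"))),
    paste0("# command: ", ifelse(is.na(command), "(none)", command)),
    paste0("# seed: ", ifelse(is.na(seed), "(none)", seed)),
    extra
  )
}

write_tsv_with_header <- function(df, path, header_lines) {
  num <- vapply(df, is.numeric, logical(1))
  chr <- df
  for (j in which(num)) chr[[j]] <- num_chr(df[[j]])
  lines <- c(
    header_lines,
    paste(names(df), collapse = "\t"),
    do.call(paste, c(unname(as.list(chr)), sep = "\t"))
  )
  writeLines(lines, path)
}

read_tsv_checked <- function(path, required, numeric_cols) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  raw <- readLines(path)
  header_n <- 0L
  while (header_n < length(raw) && startsWith(raw[header_n + 1L], "#")) {
    header_n <- header_n + 1L
  }
  body_lines <- if (header_n > 0) raw[-seq_len(header_n)] else raw
  df <- readr::read_tsv(
    I(paste(body_lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    abort_config(paste0(
      path, ": missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  for (col in intersect(numeric_cols, names(df))) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    if (length(bad)) {
      # file line = comment block + column-name row + data row index
      abort_config(sprintf(
        "%s: line %d: '%s' is not a number in column %s",
        path, header_n + 1L + bad[1], df[[col]][bad[1]], col
      ))
    }
    if (anyNA(parsed)) {
      abort_config(sprintf("%s: empty value in column %s", path, col))
    }
    df[[col]] <- parsed
  }
  list(data = as_tibble(df), header = raw[seq_len(header_n)])
}

header_field <- function(header, key) {
  hit <- grep(paste0("^# ", key, ": "), header, value = TRUE)
  if (!length(hit)) return(NULL)
  sub(paste0("^# ", key, ": "), "", hit[1])
}

#' Read and write expression-profile TSV files
#'
#' The profile dialect has either replicate-level columns
#' `time, species, replicate, value` or pre-aggregated columns
#' `time, species, mean, sd`; species are the lowercase names `premature`,
#' `mature`, `synthesis`. Writers prepend a reproducibility header
#' (`#`-prefixed: package version, command, seed, `n_replicates`); readers
#' recover `n_replicates` from it.
#'
#' @param path File path.
#' @param profile An [expression_profile()].
#' @param command,seed Recorded in the reproducibility header.
#' @param n_replicates Fallback replicate count when the file has no header
#'   (required for pre-aggregated files without one).
#' @return `read_profile_tsv()` returns an [expression_profile()];
#'   `write_profile_tsv()` returns `path` invisibly.
#' @export
read_profile_tsv <- function(path, n_replicates = NULL) {
  parsed <- read_tsv_checked(
    path,
    required = c("time", "species"),
    numeric_cols = c("time", "mean", "sd", "value", "replicate")
  )
  df <- parsed$data
  nrep_hdr <- header_field(parsed$header, "n_replicates")
  if (all(c("replicate", "value") %in% names(df))) {
    return(expression_profile(df))
  }
  nrep <- n_replicates %||% (if (!is.null(nrep_hdr)) as.integer(nrep_hdr))
  if (is.null(nrep)) {
    abort_config(paste0(
      path, ": aggregated profile without an '# n_replicates:' header; ",
      "pass n_replicates explicitly"
    ))
  }
  expression_profile(df, n_replicates = nrep)
}

#' @rdname read_profile_tsv
#' @export
write_profile_tsv <- function(profile, path, command = NA_character_, seed = NA) {
  prof <- as_expression_profile(profile)
  write_tsv_with_header(
    as_tibble(prof)[, c("time", "species", "mean", "sd")],
    path,
    repro_header(command, seed,
      extra = paste0("# n_replicates: ", n_replicates(prof))
    )
  )
  invisible(path)
}

#' Read and write trajectory TSV files
#'
#' Long format with columns `time`, `species`
#' (`premature`/`mature`/`synthesis`) and `value`; values round-trip to at
#' least 12 significant digits.
#'
#' @param traj A `kinetic_trajectory` from [solve_kinetics()].
#' @param path File path.
#' @param command,seed Recorded in the reproducibility header.
#' @return `read_trajectory_tsv()` returns a `kinetic_trajectory`;
#'   `write_trajectory_tsv()` returns `path` invisibly.
#' @export
write_trajectory_tsv <- function(traj, path, command = NA_character_, seed = NA) {
  stopifnot(inherits(traj, "kinetic_trajectory"))
  long <- tidyr::pivot_longer(
    as_tibble(traj), c("premature", "mature", "synthesis"),
    names_to = "species", values_to = "value"
  )[, c("time", "species", "value")]
  write_tsv_with_header(long, path, repro_header(command, seed))
  invisible(path)
}

#' @rdname write_trajectory_tsv
#' @export
read_trajectory_tsv <- function(path) {
  parsed <- read_tsv_checked(
    path,
    required = c("time", "species", "value"),
    numeric_cols = c("time", "value")
  )
  wide <- tidyr::pivot_wider(
    parsed$data,
    names_from = "species", values_from = "value"
  ) |>
    dplyr::arrange(.data$time)
  for (sp in c("premature", "mature", "synthesis")) {
    if (!sp %in% names(wide)) {
      abort_config(paste0(path, ": trajectory is missing species ", sp))
    }
  }
  new_kinetic_trajectory(wide$time, wide$premature, wide$mature, wide$synthesis)
}

# Model configuration --------------------------------------------------------

#' Read and write kinetic-model configuration files
#'
#' A model configuration maps each rate (`k1`, `k2`, `k3`) to a functional
#' form and its named parameters, e.g. in YAML:
#' ```
#' k1: {form: sigmoid, params: {h0: 2, h1: 4, t1: 4, beta: 1}}
#' k2: {form: constant, params: {h0: 1}}
#' k3: {form: constant, params: {h0: 0.5}}
#' ```
#' JSON files (extension `.json`) use the equivalent structure. Unknown
#' keys are rejected.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param model A [kinetic_model()].
#' @return `read_model_config()` returns a [kinetic_model()];
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  model_from_config(cfg, where = path)
}

model_from_config <- function(cfg, where = "model configuration") {
  if (!is.list(cfg)) abort_config(paste0(where, ": expected a mapping"))
  extra <- setdiff(names(cfg), c("k1", "k2", "k3"))
  if (length(extra)) {
    abort_config(paste0(where, ": unknown key(s): ", paste(extra, collapse = ", ")))
  }
  missing <- setdiff(c("k1", "k2", "k3"), names(cfg))
  if (length(missing)) {
    abort_config(paste0(where, ": missing rate(s): ", paste(missing, collapse = ", ")))
  }
  parse_rate <- function(entry, nm) {
    if (!is.list(entry)) abort_config(paste0(where, ": ", nm, " must be a mapping"))
    extra <- setdiff(names(entry), c("form", "params"))
    if (length(extra)) {
      abort_config(paste0(
        where, ": ", nm, ": unknown key(s): ", paste(extra, collapse = ", ")
      ))
    }
    if (is.null(entry$form) || is.null(entry$params)) {
      abort_config(paste0(where, ": ", nm, " needs 'form' and 'params'"))
    }
    rate_fn(entry$form, unlist(entry$params))
  }
  kinetic_model(
    parse_rate(cfg$k1, "k1"),
    parse_rate(cfg$k2, "k2"),
    parse_rate(cfg$k3, "k3")
  )
}

model_to_config <- function(model) {
  as_entry <- function(rf) list(form = rf$form, params = as.list(rf$params))
  list(
    k1 = as_entry(model$k1),
    k2 = as_entry(model$k2),
    k3 = as_entry(model$k3)
  )
}

#' @rdname read_model_config
#' @export
write_model_config <- function(model, path) {
  stopifnot(inherits(model, "kinetic_model"))
  cfg <- model_to_config(model)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    yaml::write_yaml(cfg, path)
  }
  invisible(path)
}

# Fit serialization -----------------------------------------------------------

#' Serialize a fit to JSON
#'
#' Writes the fitted model configuration together with the fit statistics
#' (objective, dof, p-value, AIC, convergence record) and — when attached —
#' confidence intervals. `read_fit_json()` rebuilds a `kinetic_fit` usable
#' with [confidence_intervals()] and [fitted_table()] provided the matching
#' profile is supplied.
#'
#' @param fit A `kinetic_fit`.
#' @param path File path.
#' @param command Command line recorded for reproducibility.
#' @param data Expression profile the fit refers to (for
#'   `read_fit_json()`).
#' @return `write_fit_json()` returns `path` invisibly; `read_fit_json()` a
#'   `kinetic_fit`.
#' @export
write_fit_json <- function(fit, path, command = NA_character_) {
  stopifnot(inherits(fit, "kinetic_fit"))
  payload <- list(
    tool = paste0("rnakinetics ", as.character(packageVersion("rnakinetics"))),
    command = if (is.na(command)) NULL else command,
    class = fit$class$code,
    forms = stats::setNames(as.list(fit$info$forms), c("k1", "k2", "k3")),
    model = model_to_config(fit$model),
    statistics = list(
      objective = fit$objective,
      dof = fit$dof,
      n_obs = fit$n_obs,
      p_value = fit$p_value,
      aic = fit$aic,
      n_free_params = fit$n_free_params,
      converged = fit$converged,
      n_iterations = fit$n_iterations,
      optimizer = fit$optimizer,
      seed = fit$seed
    ),
    window = as.numeric(fit$info$window),
    ci = if (!is.null(fit$ci)) fit$ci else NULL
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path, data) {
  if (!file.exists(path)) abort_config(paste0("file not found: ", path))
  payload <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  model <- model_from_config(
    lapply(payload$model, function(e) list(form = e$form, params = e$params)),
    where = path
  )
  prof <- as_expression_profile(data)
  mats <- profile_matrices(prof)
  st <- payload$statistics
  info <- theta_info(model_forms(model), as.numeric(payload$window))
  fit <- new_kinetic_fit(
    model, regulatory_class(model), as.numeric(st$objective), mats, info,
    converged = isTRUE(st$converged),
    n_iterations = as.integer(st$n_iterations),
    optimizer = st$optimizer, seed = st$seed, data = prof
  )
  if (!is.null(payload$ci) && length(payload$ci)) {
    fit$ci <- as_tibble(payload$ci)
  }
  fit
}
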