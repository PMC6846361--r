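#' Write a reproducibility manifest for a run
#'
#' Records the command, a config snapshot, input paths with row counts,
#' the root seed, package version and timestamp. Re-running a
#' deterministic command with the manifest's config and seed reproduces
#' its outputs.
#'
#' @param path Output JSON path.
#' @param command Command or function name.
#' @param config Configuration list snapshot (dates are serialized as
#'   ISO 8601 strings).
#' @param inputs Named list or vector of input paths.
#' @param seed Root seed of the run.
#' @param outputs Character vector of files written.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, command, config = NULL, inputs = NULL,
                               seed = NULL, outputs = NULL) {
  input_info <- NULL
  if (length(inputs)) {
    inputs <- unlist(inputs)
    input_info <- lapply(inputs, function(p) {
      rows <- if (file.exists(p)) max(length(readLines(p, warn = FALSE)) - 1L, 0L) else NA_integer_
      list(path = p, rows = rows)
    })
  }
  manifest <- list(
    command = command,
    config = serialize_config(config),
    inputs = input_info,
    seed = seed,
    outputs = as.list(outputs),
    package = "gfreval",
    version = as.character(packageVersion("gfreval")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

serialize_config <- function(config) {
  if (is.null(config)) return(NULL)
  rapply(unclass(config), function(x) {
    if (inherits(x, "Date")) format(x, "%Y-%m-%d") else x
  }, how = "replace")
}

#' Write a generator config to YAML
#' @param config A [cohort_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- serialize_config(config)
  out$strata <- lapply(seq_len(nrow(config$strata)), function(i) as.list(config$strata[i, ]))
  yaml::write_yaml(name_safe(out), path)
  invisible(path)
}

# yaml::write_yaml drops names on atomic vectors; keep them as maps
name_safe <- function(x) {
  if (is.list(x)) {
    lapply(x, name_safe)
  } else if (is.atomic(x) && !is.null(names(x))) {
    as.list(x)
  } else {
    x
  }
}

#' Read a generator config from YAML
#' @param path YAML path written by [write_config()] (or hand-edited).
#' @return A validated [cohort_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$strata)) {
    raw$strata <- purrr::map_dfr(raw$strata, tibble::as_tibble)
  }
  if (!is.null(raw$study_window)) raw$study_window <- as.Date(unlist(raw$study_window))
  if (!is.null(raw$center_calibration)) {
    raw$center_calibration <- unlist(raw$center_calibration)
  }
  base <- cohort_config()
  config <- modifyList(unclass(base), raw)
  if (is.null(raw$strata) && !is.null(raw$n) && raw$n != nrow_sum(base$strata)) {
    config$strata <- default_strata(raw$n)
  }
  config$creatinine_bounds <- as.numeric(unlist(config$creatinine_bounds))
  config$mgfr_bounds <- as.numeric(unlist(config$mgfr_bounds))
  for (fld in c("height", "weight")) {
    for (sx in c("male", "female")) {
      config[[fld]][[sx]] <- unlist(config[[fld]][[sx]])
    }
    config[[fld]]$min <- as.numeric(config[[fld]]$min)
    config[[fld]]$max <- as.numeric(config[[fld]]$max)
  }
  config <- structure(config, class = "gfr_config")
  validate_config(config)
  config
}

nrow_sum <- function(strata) sum(strata$n)
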