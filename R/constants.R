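.gfreval <- new.env(parent = emptyenv())

MODEL_IDS <- c("camgfr", "ckd_epi", "mdrd186", "mayo", "wright", "martin",
               "cockcroft_gault", "jelliffe")

#' Model identifiers known to the registry
#'
#' @return Character vector of the eight registered model ids.
#' @export
gfr_model_ids <- function() MODEL_IDS

#' Load the model-coefficient registry
#'
#' The registry ships as a YAML file mapping each model id to its
#' coefficients, native output scale (`absolute_ml_min` or
#' `normalized_ml_min_173`), expected creatinine unit and a source
#' citation. Pass a path to an edited copy to override coefficients
#' (for example to flip the Jelliffe native scale to absolute); the
#' packaged defaults are used otherwise and cached for the session.
#'
#' @param path Optional path to a YAML constants file. `NULL` uses the
#'   packaged defaults (or the path set in `options(gfreval.constants=)`).
#' @return Named list of model constant sets.
#' @export
gfr_constants <- function(path = NULL) {
  path <- path %||% getOption("gfreval.constants")
  if (is.null(path)) {
    if (is.null(.gfreval$constants)) {
      default <- system.file("extdata", "model_constants.yaml", package = "gfreval")
      .gfreval$constants <- read_constants(default)
    }
    return(.gfreval$constants)
  }
  read_constants(path)
}

read_constants <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("constants file not found: %s", path), class = "gfreval_io")
  }
  raw <- yaml::read_yaml(path)
  models <- raw$models
  if (is.null(models)) abort("constants file has no 'models' section", class = "gfreval_schema")
  for (id in names(models)) {
    m <- models[[id]]
    missing <- setdiff(c("native_scale", "creatinine_unit", "coefficients", "source_ref"),
                       names(m))
    if (length(missing)) {
      abort(sprintf("model '%s' is missing fields: %s", id,
                    paste(missing, collapse = ", ")), class = "gfreval_schema")
    }
    if (!m$native_scale %in% c("absolute_ml_min", "normalized_ml_min_173")) {
      abort(sprintf("model '%s': unknown native_scale '%s'", id, m$native_scale),
            class = "gfreval_schema")
    }
    if (!m$creatinine_unit %in% c("mg_dl", "umol_l")) {
      abort(sprintf("model '%s': unknown creatinine_unit '%s'", id, m$creatinine_unit),
            class = "gfreval_schema")
    }
  }
  models
}

lookup_model <- function(model_id, constants = NULL) {
  constants <- constants %||% gfr_constants()
  if (length(model_id) != 1L || !model_id %in% names(constants)) {
    abort(sprintf("unknown model id '%s'; registered models: %s",
                  paste(model_id, collapse = ","),
                  paste(names(constants), collapse = ", ")),
          class = "gfreval_lookup")
  }
  constants[[model_id]]
}

#' List the registered estimation models
#'
#' @param constants Optional constants list from [gfr_constants()].
#' @return A tibble with one row per model: id, display label, native
#'   output scale, creatinine unit expected by the published formula,
#'   and the source citation.
#' @examples
#' gfr_models()
#' @export
gfr_models <- function(constants = NULL) {
  constants <- constants %||% gfr_constants()
  purrr::imap_dfr(constants, function(m, id) {
    tibble::tibble(
      model_id = id,
      label = m$label %||% id,
      native_scale = m$native_scale,
      creatinine_unit = m$creatinine_unit,
      source_ref = gsub("\\s+", " ", trimws(m$source_ref))
    )
  })
}
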