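DIAGNOSIS_LEVELS <- c("solid_cancer", "hematological_cancer", "noncancer")
TRACER_LEVELS <- c("cr51_edta", "tc99m_dtpa")

COHORT_COLUMNS <- c("patient_id", "center", "diagnosis_group", "sex",
                    "race_black", "age", "height", "weight",
                    "creatinine_value", "creatinine_unit", "creatinine_date",
                    "mgfr", "tracer", "mgfr_date")

#' Default column mapping for cohort files
#'
#' @param ... Named overrides, e.g. `mgfr = "measured_gfr"` if the file
#'   calls that column differently.
#' @return Named character vector mapping canonical field names to file
#'   column names.
#' @export
cohort_schema <- function(...) {
  schema <- setNames(COHORT_COLUMNS, COHORT_COLUMNS)
  overrides <- c(...)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), COHORT_COLUMNS)
    if (length(bad)) {
      abort(sprintf("unknown schema field(s): %s", paste(bad, collapse = ", ")),
            class = "gfreval_schema")
    }
    schema[names(overrides)] <- overrides
  }
  schema
}

new_cohort <- function(tbl, provenance = "unknown",
                       filter_log = empty_filter_log(),
                       rejects = empty_rejects()) {
  tbl <- tibble::as_tibble(tbl)
  structure(tbl,
            class = c("gfr_cohort", class(tbl)),
            provenance = provenance,
            filter_log = filter_log,
            rejects = rejects)
}

empty_filter_log <- function() {
  tibble::tibble(rule = character(), n_before = integer(),
                 n_excluded = integer(), n_after = integer())
}

empty_rejects <- function() {
  tibble::tibble(row = integer(), reason = character())
}

#' Audit trail of inclusion filters applied to a cohort
#' @param cohort A `gfr_cohort`.
#' @return Tibble with one row per applied rule and its exclusion count.
#' @export
cohort_filter_log <- function(cohort) attr(cohort, "filter_log") %||% empty_filter_log()

#' Rows rejected during cohort ingestion
#' @param cohort A `gfr_cohort`.
#' @return Tibble of rejected input rows with reasons.
#' @export
cohort_rejects <- function(cohort) attr(cohort, "rejects") %||% empty_rejects()

append_filter_log <- function(cohort, rule, n_before, n_after) {
  log <- dplyr::bind_rows(cohort_filter_log(cohort),
                          tibble::tibble(rule = rule,
                                         n_before = as.integer(n_before),
                                         n_excluded = as.integer(n_before - n_after),
                                         n_after = as.integer(n_after)))
  attr(cohort, "filter_log") <- log
  cohort
}

#' @export
print.gfr_cohort <- function(x, ...) {
  cat(sprintf("<gfr_cohort> %d records (%s)\n", nrow(x),
              attr(x, "provenance") %||% "unknown"))
  log <- cohort_filter_log(x)
  if (nrow(log)) {
    cat("filters applied:\n")
    for (i in seq_len(nrow(log))) {
      cat(sprintf("  %-28s excluded %d\n", log$rule[i], log$n_excluded[i]))
    }
  }
  rej <- cohort_rejects(x)
  if (nrow(rej)) cat(sprintf("rejected rows at ingest: %d\n", nrow(rej)))
  NextMethod()
}

#' Read a patient cohort from a delimited file
#'
#' One row per creatinine/mGFR pair. Values are parsed and validated per
#' row; malformed rows are collected into a rejects table (see
#' [cohort_rejects()]) rather than silently dropped. Creatinine is
#' converted to mg/dL on ingest.
#'
#' @param path Path to a UTF-8 delimited file with a header row.
#' @param schema Column mapping from [cohort_schema()].
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A `gfr_cohort` tibble with typed columns, creatinine in mg/dL,
#'   and `rejects`/`filter_log` attributes.
#' @export
read_cohort <- function(path, schema = cohort_schema(), delim = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path), class = "gfreval_io")
  delim <- delim %||% if (grepl("\\.(tsv|txt)$", path)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing <- setdiff(unname(schema), names(raw))
  if (length(missing)) {
    abort(sprintf("missing mandatory column(s): %s", paste(missing, collapse = ", ")),
          class = "gfreval_schema")
  }
  raw <- raw[, unname(schema)]
  names(raw) <- names(schema)
  parsed <- parse_cohort_rows(raw)
  new_cohort(parsed$records, provenance = path, rejects = parsed$rejects)
}

parse_cohort_rows <- function(raw) {
  n <- nrow(raw)
  num <- function(x) suppressWarnings(as.numeric(x))
  dt <- function(x) as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  lgl <- function(x) {
    out <- rep(NA, length(x))
    out[tolower(x) %in% c("true", "t", "1", "yes")] <- TRUE
    out[tolower(x) %in% c("false", "f", "0", "no")] <- FALSE
    out
  }
  tbl <- tibble::tibble(
    patient_id = raw$patient_id,
    center = raw$center,
    diagnosis_group = raw$diagnosis_group,
    sex = raw$sex,
    race_black = lgl(raw$race_black),
    age = num(raw$age),
    height = num(raw$height),
    weight = num(raw$weight),
    creatinine_value = num(raw$creatinine_value),
    creatinine_unit = raw$creatinine_unit,
    creatinine_date = dt(raw$creatinine_date),
    mgfr = num(raw$mgfr),
    tracer = raw$tracer,
    mgfr_date = dt(raw$mgfr_date)
  )
  reasons <- character(n)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- TRUE
    ifelse(bad & reasons == "", why, reasons)
  }
  for (col in c("age", "height", "weight", "creatinine_value", "mgfr")) {
    reasons <- flag(!is.finite(tbl[[col]]) | tbl[[col]] <= 0,
                    sprintf("unparseable or non-positive number: %s", col))
  }
  reasons <- flag(is.na(tbl$creatinine_date), "unparseable date: creatinine_date")
  reasons <- flag(is.na(tbl$mgfr_date), "unparseable date: mgfr_date")
  reasons <- flag(!tbl$sex %in% c("male", "female"), "invalid sex")
  reasons <- flag(!tbl$diagnosis_group %in% DIAGNOSIS_LEVELS, "invalid diagnosis_group")
  reasons <- flag(!tbl$tracer %in% TRACER_LEVELS, "invalid tracer")
  reasons <- flag(!tbl$creatinine_unit %in% c("mg_dl", "umol_l"),
                  "invalid creatinine_unit")
  reasons <- flag(is.na(tbl$race_black), "invalid race_black")
  ok <- reasons == ""
  records <- tbl[ok, , drop = FALSE]
  records$creatinine_value <- creatinine_to_mgdl(records$creatinine_value,
                                                 records$creatinine_unit)
  records$creatinine_unit <- rep("mg_dl", nrow(records))
  records$creatinine <- records$creatinine_value
  list(records = records,
       rejects = tibble::tibble(row = which(!ok), reason = reasons[!ok]))
}

#' Write a cohort back to a delimited file
#'
#' @param cohort A `gfr_cohort` (or compatible tibble).
#' @param path Output path.
#' @param delim Field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, delim = ",") {
  out <- tibble::as_tibble(cohort)[, intersect(COHORT_COLUMNS, names(cohort))]
  readr::write_delim(out, path, delim = delim, progress = FALSE)
  invisible(path)
}

#' Apply the study inclusion filters
#'
#' Retains adults (age >= 18) with creatinine between 0.20 and 4.5 mg/dL
#' (both bounds inclusive) whose creatinine was drawn within 30 days of the
#' measured-GFR date (two-sided window). Each rule's exclusion count is
#' appended to the cohort's filter log. Idempotent.
#'
#' @param cohort A `gfr_cohort`.
#' @param creatinine_bounds Inclusive mg/dL bounds, default `c(0.20, 4.5)`.
#' @param max_days Maximum |creatinine date - mGFR date| in whole days.
#' @return The filtered `gfr_cohort`.
#' @export
apply_inclusion_filters <- function(cohort, creatinine_bounds = c(0.20, 4.5),
                                    max_days = 30) {
  stopifnot(length(creatinine_bounds) == 2, creatinine_bounds[1] < creatinine_bounds[2])
  n0 <- nrow(cohort)
  keep <- cohort$age >= 18
  cohort2 <- cohort[keep, , drop = FALSE]
  cohort2 <- restore_cohort(cohort2, cohort)
  cohort2 <- append_filter_log(cohort2, "adult (age >= 18)", n0, nrow(cohort2))

  n1 <- nrow(cohort2)
  scr <- if ("creatinine" %in% names(cohort2)) cohort2$creatinine else cohort2$creatinine_value
  keep <- scr >= creatinine_bounds[1] & scr <= creatinine_bounds[2]
  cohort3 <- restore_cohort(cohort2[keep, , drop = FALSE], cohort2)
  cohort3 <- append_filter_log(
    cohort3,
    sprintf("creatinine in [%.2f, %.2f] mg/dL", creatinine_bounds[1], creatinine_bounds[2]),
    n1, nrow(cohort3))

  n2 <- nrow(cohort3)
  gap <- abs(as.numeric(cohort3$creatinine_date - cohort3$mgfr_date))
  keep <- gap <= max_days
  cohort4 <- restore_cohort(cohort3[keep, , drop = FALSE], cohort3)
  append_filter_log(cohort4, sprintf("creatinine within %d days of mGFR", max_days),
                    n2, nrow(cohort4))
}

# subsetting a tibble drops our attributes; carry them over
restore_cohort <- function(subset, original) {
  new_cohort(subset,
             provenance = attr(original, "provenance") %||% "unknown",
             filter_log = cohort_filter_log(original),
             rejects = cohort_rejects(original))
}

#' Keep only each patient's first measured GFR
#'
#' For patients with multiple mGFR values, retains the record with the
#' earliest `mgfr_date`; same-date ties are broken by first appearance in
#' input order (stable). Output preserves input row order.
#'
#' @param cohort A `gfr_cohort`.
#' @return A `gfr_cohort` with exactly one record per `patient_id`.
#' @export
select_first_mgfr <- function(cohort) {
  n0 <- nrow(cohort)
  tbl <- tibble::as_tibble(cohort)
  tbl$.orig <- seq_len(nrow(tbl))
  tbl <- dplyr::arrange(tbl, .data$mgfr_date, .data$.orig)
  tbl <- dplyr::distinct(tbl, .data$patient_id, .keep_all = TRUE)
  tbl <- dplyr::arrange(tbl, .data$.orig)
  tbl$.orig <- NULL
  out <- restore_cohort(tbl, cohort)
  append_filter_log(out, "first mGFR per patient (by date)", n0, nrow(out))
}

#' Summarize a cohort in the study-table layout
#'
#' @param cohort A `gfr_cohort`.
#' @return List of class `cohort_summary` with `continuous` (mean, SD,
#'   min, Q1, median, Q3, max for mGFR, creatinine, age, weight, height,
#'   BSA; type-7 quantiles) and `categorical` (per-center totals,
#'   diagnosis, sex and race counts with a Total margin row).
#' @export
summarize_cohort <- function(cohort) {
  if (nrow(cohort) == 0) {
    abort("cannot summarize an empty cohort", class = "gfreval_empty")
  }
  tbl <- tibble::as_tibble(cohort)
  scr <- if ("creatinine" %in% names(tbl)) tbl$creatinine else tbl$creatinine_value
  bsa <- if ("bsa" %in% names(tbl)) tbl$bsa else dubois_bsa(tbl$weight, tbl$height)
  vars <- list(gfr = tbl$mgfr, creatinine = scr, age = tbl$age,
               weight = tbl$weight, height = tbl$height, bsa = bsa)
  continuous <- purrr::imap_dfr(vars, function(x, nm) {
    q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(variable = nm, mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
                   min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x))
  })
  per_center <- tbl |>
    dplyr::group_by(center = .data$center) |>
    dplyr::summarise(
      total = dplyr::n(),
      solid_cancer = sum(.data$diagnosis_group == "solid_cancer"),
      hematological_cancer = sum(.data$diagnosis_group == "hematological_cancer"),
      noncancer = sum(.data$diagnosis_group == "noncancer"),
      female = sum(.data$sex == "female"),
      race_black = sum(.data$race_black),
      .groups = "drop")
  total_row <- dplyr::summarise(per_center, center = "Total",
                                dplyr::across(dplyr::where(is.numeric), sum))
  structure(list(continuous = continuous,
                 categorical = dplyr::bind_rows(per_center, total_row),
                 n = nrow(tbl)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n\nContinuous variables:\n", x$n))
  print(x$continuous, ...)
  cat("\nCategorical counts by center:\n")
  print(x$categorical, ...)
  invisible(x)
}
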