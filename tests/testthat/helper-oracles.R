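# Independent brute-force oracles for the performance statistics; written
# against the definitions only (sorting + loops), deliberately not sharing
# any code path with the package implementation.

oracle_median <- function(x) {
  s <- sort(x)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

oracle_quantile7 <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

oracle_metrics <- function(mgfr, egfr) {
  r <- mgfr - egfr
  ss <- 0
  for (v in r) ss <- ss + v^2
  ape_count <- 0
  for (i in seq_along(mgfr)) {
    if (abs(egfr[i] - mgfr[i]) / mgfr[i] > 0.20) ape_count <- ape_count + 1
  }
  list(bias = oracle_median(r),
       precision = oracle_quantile7(r, 0.75) - oracle_quantile7(r, 0.25),
       accuracy = sqrt(ss / length(r)),
       one_minus_p20 = ape_count / length(mgfr))
}

# The toy worked example: four patients measured at 100 mL/min with
# estimates 80/90/110/125.
toy_residuals <- function() {
  residual_set(mgfr = rep(100, 4), egfr = c(80, 90, 110, 125), model_id = "toy")
}

random_patients <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      patient_id = sprintf("P%03d", seq_len(n)),
      center = sample(c("A", "B"), n, replace = TRUE),
      diagnosis_group = sample(c("solid_cancer", "noncancer"), n, replace = TRUE),
      sex = sample(c("male", "female"), n, replace = TRUE),
      race_black = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.1, 0.9)),
      age = runif(n, 18, 90),
      height = runif(n, 150, 195),
      weight = runif(n, 45, 110),
      creatinine = runif(n, 0.4, 3.5),
      creatinine_value = NA_real_,
      creatinine_unit = "mg_dl",
      creatinine_date = as.Date("2015-06-01") + sample(-20:20, n, replace = TRUE),
      mgfr = runif(n, 15, 180),
      tracer = "cr51_edta",
      mgfr_date = as.Date("2015-06-01")
    ) |>
      dplyr::mutate(creatinine_value = creatinine)
  })
}

# columns only, without the provenance/filter-log/rejects bookkeeping
cohort_columns <- function(x) {
  a <- tibble::as_tibble(x)
  attr(a, "provenance") <- NULL
  attr(a, "filter_log") <- NULL
  attr(a, "rejects") <- NULL
  class(a) <- c("tbl_df", "tbl", "data.frame")
  a
}

new_cohort_for_test <- function(tbl) {
  gfreval:::new_cohort(tbl, provenance = "test fixture")
}

write_cohort_csv <- function(tbl, path) {
  readr::write_csv(tbl, path, progress = FALSE)
  path
}
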