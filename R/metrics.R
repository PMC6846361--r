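METRIC_NAMES <- c("bias", "precision", "accuracy", "one_minus_p20")

#' Construct a residual set from paired measured and estimated GFR
#'
#' @param mgfr Measured GFR, mL/min.
#' @param egfr Estimated GFR, mL/min (absolute scale).
#' @param model_id Label for the model that produced `egfr`.
#' @param patient_id Optional record identifiers.
#' @return Tibble of class `residual_set` with `residual = mgfr - egfr`
#'   (the study's sign convention) and `ape = |egfr - mgfr| / mgfr`.
#' @export
residual_set <- function(mgfr, egfr, model_id = "model", patient_id = NULL) {
  if (length(mgfr) != length(egfr)) {
    abort("mgfr and egfr must have equal length", class = "gfreval_invalid")
  }
  if (length(mgfr) == 0) abort("empty residual set", class = "gfreval_empty")
  check_positive(mgfr, "mgfr")
  tbl <- tibble::tibble(
    patient_id = patient_id %||% sprintf("R%05d", seq_along(mgfr)),
    mgfr = as.numeric(mgfr),
    egfr = as.numeric(egfr),
    residual = as.numeric(mgfr) - as.numeric(egfr),
    ape = abs(as.numeric(egfr) - as.numeric(mgfr)) / as.numeric(mgfr)
  )
  structure(tbl, class = c("residual_set", class(tbl)), model_id = model_id)
}

#' Residuals of one model on a cohort
#'
#' @param cohort A `gfr_cohort` (or patient tibble accepted by
#'   [evaluate_model()]) carrying an `mgfr` column.
#' @param model_id Registered model id.
#' @param constants Optional constants list from [gfr_constants()].
#' @return A [residual_set()] with eGFR on the absolute mL/min scale.
#' @export
compute_residuals <- function(cohort, model_id, constants = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort", class = "gfreval_empty")
  if (!"mgfr" %in% names(cohort)) {
    abort("cohort has no 'mgfr' column", class = "gfreval_schema")
  }
  est <- evaluate_model(tibble::as_tibble(cohort), model_id, constants)
  residual_set(est$mgfr, est$egfr_absolute, model_id = model_id,
               patient_id = if ("patient_id" %in% names(est)) est$patient_id)
}

# one metric from residual/ape vectors; quantiles are type 7 throughout
metric_value <- function(residual, ape, metric) {
  switch(metric,
         bias = median(residual),
         precision = diff(quantile(residual, c(0.25, 0.75), type = 7, names = FALSE)),
         accuracy = sqrt(mean(residual^2)),
         one_minus_p20 = mean(ape > 0.20),  # strictly greater than 20%
         abort(sprintf("unknown metric '%s'", metric), class = "gfreval_lookup"))
}

#' Point performance metrics of a residual set
#'
#' Bias is the median residual, precision the residual interquartile range
#' (type-7 quantiles), accuracy the root-mean-squared error, and 1-P20 the
#' proportion of patients whose absolute percentage error strictly exceeds
#' 20%.
#'
#' @param rs A [residual_set()].
#' @return One-row tibble with model_id, n, bias, precision, accuracy and
#'   one_minus_p20.
#' @export
compute_metrics <- function(rs) {
  if (nrow(rs) == 0) abort("empty residual set", class = "gfreval_empty")
  tibble::tibble(
    model_id = attr(rs, "model_id") %||% "model",
    n = nrow(rs),
    bias = metric_value(rs$residual, rs$ape, "bias"),
    precision = metric_value(rs$residual, rs$ape, "precision"),
    accuracy = metric_value(rs$residual, rs$ape, "accuracy"),
    one_minus_p20 = metric_value(rs$residual, rs$ape, "one_minus_p20")
  )
}

#' Normal-approximation bootstrap confidence interval for one metric
#'
#' Pairs are resampled with replacement `reps` times, the metric is
#' recomputed on each resample, and the interval is the point estimate
#' +/- z * SD(bootstrap statistics) — the normal-distribution
#' approximation with 2000 repetitions used in the validation study.
#'
#' @param rs A [residual_set()].
#' @param metric One of `"bias"`, `"precision"`, `"accuracy"`,
#'   `"one_minus_p20"`.
#' @param reps Bootstrap repetitions (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed; results are deterministic given it.
#' @return One-row tibble with estimate, conf.low, conf.high, se, n,
#'   reps, level and seed.
#' @export
bootstrap_ci <- function(rs, metric = "accuracy", reps = 2000, level = 0.95,
                         seed = 1) {
  metric <- match.arg(metric, METRIC_NAMES)
  n <- nrow(rs)
  if (n < 2) abort("bootstrap needs at least 2 pairs", class = "gfreval_invalid")
  if (reps < 2) abort("reps must be >= 2", class = "gfreval_invalid")
  est <- metric_value(rs$residual, rs$ape, metric)
  boot <- withr::with_seed(derive_seed(seed, paste0("boot_", metric)), {
    vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_value(rs$residual[idx], rs$ape[idx], metric)
    }, numeric(1))
  })
  z <- qnorm(1 - (1 - level) / 2)
  se <- sd(boot)
  tibble::tibble(metric = metric, estimate = est,
                 conf.low = est - z * se, conf.high = est + z * se,
                 se = se, n = n, reps = reps, level = level, seed = seed)
}

#' Evaluate a set of models on a cohort
#'
#' The full pipeline behind the study's performance figure: for each model,
#' residuals against measured GFR, the four point metrics, and a
#' normal-approximation bootstrap CI per metric (one shared set of
#' patient-level resamples per model, so metrics of the same model are
#' computed on identical resamples).
#'
#' @param cohort A `gfr_cohort` or compatible patient tibble with `mgfr`.
#' @param models Character vector of registered model ids.
#' @param reps Bootstrap repetitions; `0` skips interval estimation.
#' @param level Confidence level.
#' @param seed Root seed; per-model streams are derived from it.
#' @param constants Optional constants list.
#' @return Object of class `gfr_evaluation`; see [tidy.gfr_evaluation()],
#'   [glance.gfr_evaluation()] and [autoplot.gfr_evaluation()].
#' @export
evaluate_models <- function(cohort, models = gfr_model_ids(), reps = 2000,
                            level = 0.95, seed = 1, constants = NULL) {
  if (nrow(cohort) == 0) abort("empty cohort", class = "gfreval_empty")
  rows <- purrr::map_dfr(models, function(id) {
    rs <- compute_residuals(cohort, id, constants)
    pt <- compute_metrics(rs)
    long <- tidyr::pivot_longer(pt, dplyr::all_of(METRIC_NAMES),
                                names_to = "metric", values_to = "estimate")
    if (reps > 0) {
      ci <- bootstrap_metrics(rs, reps, level, derive_seed(seed, id))
      long <- dplyr::left_join(long, ci, by = "metric")
    } else {
      long$conf.low <- NA_real_; long$conf.high <- NA_real_
    }
    long
  })
  structure(list(metrics = rows, models = models, n = nrow(cohort),
                 reps = reps, level = level, seed = seed),
            class = "gfr_evaluation")
}

# all four metrics on one shared set of resamples
bootstrap_metrics <- function(rs, reps, level, seed) {
  n <- nrow(rs)
  boot <- withr::with_seed(seed, {
    t(vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      vapply(METRIC_NAMES, function(mt) metric_value(rs$residual[idx], rs$ape[idx], mt),
             numeric(1))
    }, numeric(length(METRIC_NAMES))))
  })
  z <- qnorm(1 - (1 - level) / 2)
  est <- vapply(METRIC_NAMES, function(mt) metric_value(rs$residual, rs$ape, mt),
                numeric(1))
  se <- apply(boot, 2, sd)
  tibble::tibble(metric = METRIC_NAMES,
                 conf.low = est - z * se, conf.high = est + z * se)
}

#' Tidy a model evaluation into a long metric table
#'
#' @param x A `gfr_evaluation` from [evaluate_models()].
#' @param ... Unused.
#' @return Long tibble: model_id, metric, estimate, conf.low, conf.high.
#' @export
tidy.gfr_evaluation <- function(x, ...) x$metrics

#' One-row summary of a model evaluation run
#'
#' @param x A `gfr_evaluation` from [evaluate_models()].
#' @param ... Unused.
#' @return One-row tibble: n, n_models, reps, level, seed.
#' @export
glance.gfr_evaluation <- function(x, ...) {
  tibble::tibble(n = x$n, n_models = length(x$models), reps = x$reps,
                 level = x$level, seed = x$seed)
}

#' @export
print.gfr_evaluation <- function(x, ...) {
  cat(sprintf("<gfr_evaluation> %d models on %d patients (reps = %d, seed = %s)\n",
              length(x$models), x$n, x$reps, format(x$seed)))
  wide <- tidyr::pivot_wider(x$metrics[, c("model_id", "metric", "estimate")],
                             names_from = "metric", values_from = "estimate")
  print(wide, ...)
  invisible(x)
}
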