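#' Paired bootstrap comparison of two models
#'
#' Both models are evaluated on the same patients, so resampling is
#' patient-level and joint: each bootstrap draw resamples rows once and
#' recomputes the metric for both models on that resample. The two-sided
#' p-value comes from a normal approximation of the bootstrap distribution
#' of the difference.
#'
#' @param cohort A `gfr_cohort` or compatible tibble with `mgfr`.
#' @param model_a,model_b Registered model ids.
#' @param metric One of `"bias"`, `"precision"`, `"accuracy"`,
#'   `"one_minus_p20"`.
#' @param reps Bootstrap repetitions (default 2000).
#' @param level Confidence level for the delta interval.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @param seed Integer seed.
#' @param constants Optional constants list.
#' @return One-row tibble: per-model estimates, `delta` (a - b) with its
#'   normal-approximation CI, `p_value`, `reps`, `seed`.
#' @export
compare_models <- function(cohort, model_a, model_b, metric = "accuracy",
                           reps = 2000, level = 0.95,
                           alternative = c("two.sided", "less", "greater"),
                           seed = 1, constants = NULL) {
  metric <- match.arg(metric, METRIC_NAMES)
  alternative <- match.arg(alternative)
  rs_a <- compute_residuals(cohort, model_a, constants)
  rs_b <- compute_residuals(cohort, model_b, constants)
  if (nrow(rs_a) != nrow(rs_b) || !identical(rs_a$patient_id, rs_b$patient_id)) {
    abort("models must be evaluated on identical cohort rows", class = "gfreval_invalid")
  }
  n <- nrow(rs_a)
  if (n < 2) abort("comparison needs at least 2 pairs", class = "gfreval_invalid")
  est_a <- metric_value(rs_a$residual, rs_a$ape, metric)
  est_b <- metric_value(rs_b$residual, rs_b$ape, metric)
  delta <- est_a - est_b
  boot <- withr::with_seed(derive_seed(seed, paste0("cmp_", metric)), {
    vapply(seq_len(reps), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      metric_value(rs_a$residual[idx], rs_a$ape[idx], metric) -
        metric_value(rs_b$residual[idx], rs_b$ape[idx], metric)
    }, numeric(1))
  })
  se <- sd(boot)
  z <- qnorm(1 - (1 - level) / 2)
  p <- if (se == 0) {
    as.numeric(delta != 0) * 0 + as.numeric(delta == 0)  # 1 if identical, 0 otherwise
  } else {
    zstat <- delta / se
    switch(alternative,
           two.sided = 2 * pnorm(-abs(zstat)),
           less = pnorm(zstat),
           greater = pnorm(-zstat))
  }
  tibble::tibble(model_a = model_a, model_b = model_b, metric = metric,
                 estimate_a = est_a, estimate_b = est_b, delta = delta,
                 conf.low = delta - z * se, conf.high = delta + z * se,
                 se = se, p_value = min(max(p, 0), 1), n = n, reps = reps,
                 seed = seed, alternative = alternative)
}

#' Per-subgroup performance metrics
#'
#' Splits the cohort on one variable — categories as-is for discrete
#' variables, bins for continuous ones (quartile edges by default, the
#' type-7 convention) — and computes the four metrics per model per
#' subgroup. Subgroup sizes partition the cohort size.
#'
#' @param cohort A `gfr_cohort` or compatible tibble with `mgfr`.
#' @param models Registered model ids.
#' @param by Name of the grouping column (e.g. `"sex"`, `"age"`,
#'   `"center"`, `"creatinine"`).
#' @param breaks For numeric `by`: bin edges, or `NULL` for quartiles.
#' @param reps Bootstrap repetitions per subgroup (default 0: point
#'   estimates only).
#' @param seed Integer seed (used when `reps > 0`).
#' @param constants Optional constants list.
#' @return Tibble with one row per model x subgroup; empty subgroups keep
#'   their row with `n = 0` and missing metrics.
#' @export
subgroup_metrics <- function(cohort, models = gfr_model_ids(), by,
                             breaks = NULL, reps = 0, seed = 1,
                             constants = NULL) {
  tbl <- tibble::as_tibble(cohort)
  if (!by %in% names(tbl)) {
    abort(sprintf("grouping column '%s' not found", by), class = "gfreval_schema")
  }
  v <- tbl[[by]]
  if (is.numeric(v)) {
    if (is.null(breaks)) {
      breaks <- unique(quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE))
    }
    group <- cut(v, breaks = breaks, include.lowest = TRUE)
  } else {
    group <- factor(v)
  }
  purrr::map_dfr(levels(group), function(g) {
    sub <- tbl[!is.na(group) & group == g, , drop = FALSE]
    purrr::map_dfr(models, function(id) {
      if (nrow(sub) == 0) {
        return(tibble::tibble(subgroup = g, model_id = id, n = 0L,
                              bias = NA_real_, precision = NA_real_,
                              accuracy = NA_real_, one_minus_p20 = NA_real_))
      }
      rs <- compute_residuals(sub, id, constants)
      out <- dplyr::mutate(compute_metrics(rs), subgroup = g, .before = 1)
      if (reps > 0 && nrow(rs) >= 2) {
        ci <- bootstrap_metrics(rs, reps, 0.95, derive_seed(seed, paste(g, id)))
        out$accuracy_low <- ci$conf.low[ci$metric == "accuracy"]
        out$accuracy_high <- ci$conf.high[ci$metric == "accuracy"]
      }
      out
    })
  })
}

#' Matched random draws comparing two race groups
#'
#' Repeats the study's check for systematic differences between black and
#' nonblack patients: in each of `n_draws` draws, every minority-group
#' patient is matched 1:1 (without replacement) to a majority-group
#' patient of the same sex whose age differs by at most `age_tolerance`
#' years (nearest age wins), and the two matched samples are compared on
#' BSA, measured GFR and creatinine with a two-sample test.
#'
#' @param cohort A `gfr_cohort` or compatible tibble with `sex`, `age`,
#'   `race_black`, `mgfr`, creatinine and height/weight (or `bsa`).
#' @param group_var Logical column splitting the cohort (default
#'   `"race_black"`; `TRUE` is the minority group).
#' @param n_draws Number of random draws (default 10).
#' @param age_tolerance Maximum age difference in years (default 2).
#' @param test `"wilcoxon"` (rank-sum, default) or `"t"`.
#' @param variables Variables to compare.
#' @param seed Integer seed.
#' @return Tibble with one row per draw x variable: test statistic,
#'   p-value, matched-pair count and unmatched count (draws with any
#'   unmatched minority patient are flagged).
#' @export
matched_draw_comparison <- function(cohort, group_var = "race_black",
                                    n_draws = 10, age_tolerance = 2,
                                    test = c("wilcoxon", "t"),
                                    variables = c("bsa", "mgfr", "creatinine"),
                                    seed = 1) {
  test <- match.arg(test)
  tbl <- tibble::as_tibble(cohort)
  if (!"bsa" %in% names(tbl) && all(c("weight", "height") %in% names(tbl))) {
    tbl$bsa <- dubois_bsa(tbl$weight, tbl$height)
  }
  if (!"creatinine" %in% names(tbl) && "creatinine_value" %in% names(tbl)) {
    tbl$creatinine <- tbl$creatinine_value
  }
  flag <- as.logical(tbl[[group_var]])
  minority <- tbl[flag, , drop = FALSE]
  majority <- tbl[!flag, , drop = FALSE]
  if (nrow(minority) == 0 || nrow(majority) == 0) {
    abort("both groups must be non-empty", class = "gfreval_empty")
  }
  purrr::map_dfr(seq_len(n_draws), function(d) {
    withr::with_seed(derive_seed(seed, paste0("draw", d)), {
      m <- match_one_draw(minority, majority, age_tolerance)
      purrr::map_dfr(variables, function(v) {
        x <- minority[[v]][m$minority_idx]
        y <- majority[[v]][m$majority_idx]
        ht <- if (test == "wilcoxon") {
          suppressWarnings(wilcox.test(x, y, exact = FALSE))
        } else {
          t.test(x, y)
        }
        tibble::tibble(draw = d, variable = v,
                       statistic = unname(ht$statistic), p_value = ht$p.value,
                       n_pairs = length(x), n_unmatched = m$n_unmatched,
                       test = test)
      })
    })
  })
}

match_one_draw <- function(minority, majority, age_tolerance) {
  order_min <- sample.int(nrow(minority))  # random processing order per draw
  used <- rep(FALSE, nrow(majority))
  mi <- integer(0); ma <- integer(0); unmatched <- 0L
  for (i in order_min) {
    cand <- which(!used & majority$sex == minority$sex[i] &
                    abs(majority$age - minority$age[i]) <= age_tolerance)
    if (length(cand) == 0) { unmatched <- unmatched + 1L; next }
    gaps <- abs(majority$age[cand] - minority$age[i])
    best <- cand[gaps == min(gaps)]
    pick <- if (length(best) > 1) sample(best, 1) else best
    used[pick] <- TRUE
    mi <- c(mi, i); ma <- c(ma, pick)
  }
  list(minority_idx = mi, majority_idx = ma, n_unmatched = unmatched)
}
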