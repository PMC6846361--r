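# Published per-center margins of the validation cohort: totals, diagnosis
# counts, female and black counts, and the tracer used at each center.
CENTER_TABLE <- tibble::tribble(
  ~center,        ~total, ~solid, ~heme, ~noncancer, ~female, ~black, ~tracer,
  "Cambridge",       404,    227,   114,         63,     198,      6, "cr51_edta",
  "Edinburgh",       597,    472,    22,        103,     245,      0, "tc99m_dtpa",
  "London-Barts",    108,    108,     0,          0,       0,      0, "cr51_edta",
  "Manchester",     1777,   1777,     0,          0,    1066,     16, "cr51_edta",
  "Melbourne",       308,    308,     0,          0,     111,      0, "tc99m_dtpa",
  "Southampton",     436,    436,     0,          0,       0,      0, "cr51_edta",
  "Wales",           156,    156,     0,          0,      89,      0, "cr51_edta"
)

# Deterministic integer apportionment (largest remainder / Hamilton).
largest_remainder <- function(weights, total) {
  if (total == 0 || sum(weights) == 0) return(rep(0L, length(weights)))
  raw <- weights / sum(weights) * total
  base <- floor(raw)
  short <- total - sum(base)
  if (short > 0) {
    order_idx <- order(raw - base, decreasing = TRUE)
    base[order_idx[seq_len(short)]] <- base[order_idx[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Default cohort strata
#'
#' Expands the published per-center margins into center x diagnosis rows
#' with female and black counts allocated across diagnoses within each
#' center by deterministic largest-remainder apportionment (the source
#' tables give only the margins, not the full cross-classification).
#'
#' @param n Target cohort size. The default 3786 reproduces the published
#'   table exactly; other sizes rescale every cell proportionally
#'   (largest remainder) so the strata still sum to `n`.
#' @return Tibble with columns center, diagnosis_group, tracer, n,
#'   n_female, n_black.
#' @export
default_strata <- function(n = 3786) {
  rows <- purrr::pmap_dfr(CENTER_TABLE, function(center, total, solid, heme,
                                                 noncancer, female, black, tracer) {
    counts <- c(solid_cancer = solid, hematological_cancer = heme,
                noncancer = noncancer)
    counts <- counts[counts > 0]
    fem <- largest_remainder(counts, female)
    blk <- largest_remainder(counts, black)
    tibble::tibble(center = center, diagnosis_group = names(counts),
                   tracer = tracer, n = as.integer(counts),
                   n_female = fem, n_black = blk)
  })
  if (n != sum(rows$n)) {
    scaled <- largest_remainder(rows$n, n)
    rows$n_female <- pmin(largest_remainder(rows$n_female, round(sum(rows$n_female) * n / sum(rows$n))), scaled)
    rows$n_black <- pmin(largest_remainder(rows$n_black, round(sum(rows$n_black) * n / sum(rows$n))), scaled)
    rows$n <- scaled
    rows <- rows[rows$n > 0, , drop = FALSE]
  }
  rows
}

#' Synthetic-cohort generator configuration
#'
#' Defaults reproduce the published multicenter cohort: strata from the
#' per-center table (total 3786), age truncated-normal (mean 57, SD 16,
#' bounds 18-91), latent true GFR truncated-normal (mean 86, SD 32, bounds
#' 9-209), per-sex height/weight truncated normals calibrated to pooled
#' medians 169 cm / 74 kg with height-weight correlation 0.5 via a shared
#' size factor, measured-GFR noise SD 8 mL/min, multiplicative lognormal
#' creatinine noise (sdlog 0.06), creatinine bounds 0.20-4.5 mg/dL, 27%
#' same-day creatinine/mGFR sampling, and per-center creatinine
#' calibration factors of 1 (no assay bias).
#'
#' @param n Cohort size (default 3786).
#' @param truth_model Model id used as the data-generating truth linking
#'   creatinine to GFR (default `"ckd_epi"`).
#' @param creatinine_noise Lognormal SD of multiplicative creatinine
#'   measurement noise.
#' @param mgfr_noise Additive SD (mL/min) of measured-GFR noise.
#' @param center_calibration Named vector of multiplicative creatinine
#'   bias factors per center; `NULL` means 1 everywhere.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param same_day_fraction Probability that creatinine and mGFR share a
#'   date; otherwise the offset is uniform on +/-1..30 days.
#' @param ... Overrides for the remaining fields (`strata`, `age`, `gfr`,
#'   `height`, `weight`, `size_correlation`, `creatinine_bounds`,
#'   `mgfr_bounds`, `study_window`, `max_retries`).
#' @return List of class `gfr_config`.
#' @export
cohort_config <- function(n = 3786, truth_model = "ckd_epi",
                          creatinine_noise = 0.06, mgfr_noise = 8,
                          center_calibration = NULL, seed = 20190919,
                          same_day_fraction = 0.27, ...) {
  config <- list(
    n = n,
    strata = default_strata(n),
    truth_model = truth_model,
    age = list(mean = 57, sd = 16, min = 18, max = 91),
    gfr = list(mean = 86, sd = 32, min = 9, max = 209),
    height = list(male = c(mean = 175, sd = 7), female = c(mean = 162, sd = 7),
                  min = 137, max = 204),
    weight = list(male = c(mean = 80, sd = 17), female = c(mean = 68, sd = 16),
                  min = 33, max = 200),
    size_correlation = 0.5,
    creatinine_noise = creatinine_noise,
    mgfr_noise = mgfr_noise,
    creatinine_bounds = c(0.20, 4.5),
    mgfr_bounds = c(9, 209),
    center_calibration = center_calibration,
    same_day_fraction = same_day_fraction,
    study_window = as.Date(c("2014-01-01", "2017-12-31")),
    max_retries = 100,
    seed = seed
  )
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(config))
  if (length(bad)) {
    abort(sprintf("unknown config field(s): %s", paste(bad, collapse = ", ")),
          class = "gfreval_schema")
  }
  config <- modifyList(config, overrides)
  validate_config(config)
  structure(config, class = "gfr_config")
}

validate_config <- function(config) {
  check <- function(ok, field, why) {
    if (!ok) abort(sprintf("invalid config field '%s': %s", field, why),
                   class = "gfreval_invalid")
  }
  check(all(config$strata$n >= 0), "strata", "counts must be >= 0")
  check(config$creatinine_noise >= 0, "creatinine_noise", "must be >= 0")
  check(config$mgfr_noise >= 0, "mgfr_noise", "must be >= 0")
  check(config$creatinine_bounds[1] < config$creatinine_bounds[2],
        "creatinine_bounds", "must be ordered")
  check(config$mgfr_bounds[1] < config$mgfr_bounds[2], "mgfr_bounds",
        "must be ordered")
  if (!is.null(config$center_calibration)) {
    check(all(config$center_calibration > 0), "center_calibration",
          "factors must be > 0")
  }
  check(config$truth_model %in% gfr_model_ids(), "truth_model",
        "must be a registered model id")
  invisible(config)
}

rtruncnorm <- function(n, mean, sd, lo, hi) {
  qnorm(runif(n, pnorm((lo - mean) / sd), pnorm((hi - mean) / sd))) * sd + mean
}

#' Generate a synthetic validation cohort
#'
#' Per stratum, demographics are drawn first; a latent true GFR is drawn
#' from its truncated normal; the truth model is inverted (analytically
#' where its creatinine dependence permits, numerically otherwise) to find
#' the noiseless creatinine consistent with that GFR; multiplicative
#' lognormal noise and the center's calibration factor are then applied to
#' creatinine, and additive (truncated) noise to the measured GFR. Records
#' whose final creatinine falls outside the configured bounds are redrawn
#' (bounded retries), so a generated cohort always passes
#' [apply_inclusion_filters()] with zero exclusions.
#'
#' @param config A [cohort_config()].
#' @return List of class `synthetic_cohort` with elements `cohort` (a
#'   `gfr_cohort`), `truth` (tibble of per-record latent true GFR and
#'   noiseless creatinine) and `config`.
#' @examples
#' sc <- generate_cohort(cohort_config(n = 200, seed = 1))
#' nrow(sc$cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_config(config)
  withr::with_seed(derive_seed(config$seed, "generate"), {
    skel <- strata_skeleton(config$strata)
    n <- nrow(skel)
    female <- skel$sex == "female"

    age <- rtruncnorm(n, config$age$mean, config$age$sd, config$age$min, config$age$max)

    lam <- sqrt(config$size_correlation)
    hw <- draw_height_weight(n, female, config, lam)

    bsa <- dubois_bsa(hw$weight, hw$height)
    cal <- rep(1, n)
    if (!is.null(config$center_calibration)) {
      unknown <- setdiff(names(config$center_calibration), unique(skel$center))
      if (length(unknown)) {
        abort(sprintf("center_calibration names unknown center(s): %s",
                      paste(unknown, collapse = ", ")), class = "gfreval_invalid")
      }
      idx <- match(skel$center, names(config$center_calibration))
      cal[!is.na(idx)] <- config$center_calibration[idx[!is.na(idx)]]
    }

    draw <- draw_gfr_creatinine(n, age, female, skel$race_black, hw, bsa, cal, config)

    mgfr <- draw$true_gfr + rnorm(n, 0, config$mgfr_noise)
    for (i in seq_len(config$max_retries)) {
      out <- mgfr < config$mgfr_bounds[1] | mgfr > config$mgfr_bounds[2]
      if (!any(out)) break
      mgfr[out] <- draw$true_gfr[out] + rnorm(sum(out), 0, config$mgfr_noise)
    }
    mgfr <- pmin(pmax(mgfr, config$mgfr_bounds[1]), config$mgfr_bounds[2])

    window_days <- as.integer(config$study_window[2] - config$study_window[1])
    mgfr_date <- config$study_window[1] + floor(runif(n) * (window_days + 1))
    same_day <- runif(n) < config$same_day_fraction
    offset <- sample(c(-30:-1, 1:30), n, replace = TRUE)
    offset[same_day] <- 0L
    creatinine_date <- mgfr_date + offset

    tbl <- tibble::tibble(
      patient_id = sprintf("P%05d", seq_len(n)),
      center = skel$center,
      diagnosis_group = skel$diagnosis_group,
      sex = skel$sex,
      race_black = skel$race_black,
      age = age,
      height = hw$height,
      weight = hw$weight,
      creatinine_value = draw$creatinine,
      creatinine_unit = "mg_dl",
      creatinine = draw$creatinine,
      creatinine_date = creatinine_date,
      mgfr = mgfr,
      tracer = skel$tracer,
      mgfr_date = mgfr_date
    )
    truth <- tibble::tibble(patient_id = tbl$patient_id,
                            true_gfr = draw$true_gfr,
                            creatinine_noiseless = draw$creatinine_noiseless)
    structure(list(cohort = new_cohort(tbl, provenance = "synthetic generator"),
                   truth = truth, config = config),
              class = "synthetic_cohort")
  })
}

strata_skeleton <- function(strata) {
  purrr::pmap_dfr(strata, function(center, diagnosis_group, tracer, n,
                                   n_female, n_black) {
    if (n == 0) return(NULL)
    sex <- rep(c("female", "male"), c(n_female, n - n_female))
    # spread black records across both sexes proportionally
    blk_f <- if (n_female > 0) largest_remainder(c(n_female, n - n_female), n_black)[1] else 0L
    race <- rep(FALSE, n)
    if (n_black > 0) {
      f_idx <- which(sex == "female")
      m_idx <- which(sex == "male")
      race[utils::head(f_idx, blk_f)] <- TRUE
      race[utils::head(m_idx, n_black - blk_f)] <- TRUE
    }
    tibble::tibble(center = center, diagnosis_group = diagnosis_group,
                   tracer = tracer, sex = sex, race_black = race)
  })
}

draw_height_weight <- function(n, female, config, lam) {
  h_mu <- ifelse(female, config$height$female["mean"], config$height$male["mean"])
  h_sd <- ifelse(female, config$height$female["sd"], config$height$male["sd"])
  w_mu <- ifelse(female, config$weight$female["mean"], config$weight$male["mean"])
  w_sd <- ifelse(female, config$weight$female["sd"], config$weight$male["sd"])
  height <- rep(NA_real_, n); weight <- rep(NA_real_, n)
  todo <- rep(TRUE, n)
  while (any(todo)) {
    k <- sum(todo)
    zc <- rnorm(k); z1 <- rnorm(k); z2 <- rnorm(k)
    h <- h_mu[todo] + h_sd[todo] * (lam * zc + sqrt(1 - lam^2) * z1)
    w <- w_mu[todo] + w_sd[todo] * (lam * zc + sqrt(1 - lam^2) * z2)
    ok <- h >= config$height$min & h <= config$height$max &
      w >= config$weight$min & w <= config$weight$max
    idx <- which(todo)[ok]
    height[idx] <- h[ok]; weight[idx] <- w[ok]
    todo[idx] <- FALSE
  }
  list(height = height, weight = weight)
}

draw_gfr_creatinine <- function(n, age, female, black, hw, bsa, cal, config) {
  true_gfr <- rep(NA_real_, n)
  scr0 <- rep(NA_real_, n)  # noiseless inversion
  scr <- rep(NA_real_, n)   # after noise and calibration
  todo <- rep(TRUE, n)
  for (attempt in seq_len(config$max_retries)) {
    if (!any(todo)) break
    idx <- which(todo)
    g <- rtruncnorm(length(idx), config$gfr$mean, config$gfr$sd,
                    config$gfr$min, config$gfr$max)
    s0 <- invert_gfr(config$truth_model, g, age[idx], female[idx], black[idx],
                     hw$weight[idx], hw$height[idx], bsa[idx])
    s <- s0 * exp(rnorm(length(idx), 0, config$creatinine_noise)) * cal[idx]
    ok <- !is.na(s) & s >= config$creatinine_bounds[1] & s <= config$creatinine_bounds[2]
    keep <- idx[ok]
    true_gfr[keep] <- g[ok]; scr0[keep] <- s0[ok]; scr[keep] <- s[ok]
    todo[keep] <- FALSE
  }
  if (any(todo)) {
    abort(sprintf("creatinine inversion failed for %d record(s) after %d retries",
                  sum(todo), config$max_retries), class = "gfreval_generation")
  }
  list(true_gfr = true_gfr, creatinine_noiseless = scr0, creatinine = scr)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> n = %d, truth model = %s, seed = %s\n",
              nrow(x$cohort), x$config$truth_model, format(x$config$seed)))
  invisible(x)
}

#' Apply per-center creatinine calibration factors to an existing cohort
#'
#' Emulates intercenter assay (non-IDMS calibration) bias: each center's
#' creatinine values are multiplied by its factor; nothing else changes.
#' Because every model's eGFR is decreasing in creatinine, a factor above 1
#' lowers eGFR (and worsens accuracy of an otherwise well-calibrated truth
#' model) at that center.
#'
#' @param cohort A `gfr_cohort` (or compatible tibble) with `center` and
#'   creatinine columns.
#' @param center_calibration Named numeric vector of positive factors,
#'   names matching centers present in the cohort.
#' @return The cohort with creatinine scaled.
#' @export
inject_center_bias <- function(cohort, center_calibration) {
  if (is.null(names(center_calibration)) || any(!nzchar(names(center_calibration)))) {
    abort("center_calibration must be a named vector", class = "gfreval_invalid")
  }
  if (any(center_calibration <= 0)) {
    abort("calibration factors must be > 0", class = "gfreval_invalid")
  }
  unknown <- setdiff(names(center_calibration), unique(cohort$center))
  if (length(unknown)) {
    abort(sprintf("unknown center(s) in calibration map: %s",
                  paste(unknown, collapse = ", ")), class = "gfreval_invalid")
  }
  factor <- unname(center_calibration[cohort$center])
  factor[is.na(factor)] <- 1
  for (col in intersect(c("creatinine", "creatinine_value"), names(cohort))) {
    cohort[[col]] <- cohort[[col]] * factor
  }
  cohort
}
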