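# Vectorised numeric core shared by the public estimators and by the
# synthetic-cohort inversion. `creatinine` is always mg/dL here; models whose
# published formula expects umol/L convert internally. Returns a list with
# `absolute` (mL/min) and `normalized` (mL/min/1.73 m^2); both are always
# populated because either scale is derivable from the other via BSA.
egfr_core <- function(model_id, age, female, black, weight, height, bsa,
                      creatinine, constants = NULL) {
  m <- lookup_model(model_id, constants)
  co <- m$coefficients
  scr <- creatinine
  scr_um <- scr * UMOL_PER_MGDL
  fem <- as.numeric(female)

  native <- switch(
    model_id,
    cockcroft_gault = (co$age_base - age) * weight *
      ifelse(female, co$female_factor, 1) / (co$denominator * scr),
    jelliffe = (co$intercept - co$age_slope * (age - co$age_offset)) *
      ifelse(female, co$female_factor, 1) / scr,
    mdrd186 = co$scale * scr^co$creatinine_exp * age^co$age_exp *
      ifelse(female, co$female_factor, 1) * ifelse(black, co$black_factor, 1),
    ckd_epi = {
      kappa <- ifelse(female, co$kappa_female, co$kappa_male)
      alpha <- ifelse(female, co$alpha_female, co$alpha_male)
      co$scale * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^co$beta *
        co$age_base^age * ifelse(female, co$female_factor, 1) *
        ifelse(black, co$black_factor, 1)
    },
    mayo = {
      s <- pmax(scr, co$creatinine_clamp)
      exp(co$intercept + co$inv_creatinine / s + co$inv_creatinine_sq / s^2 +
            co$age * age + co$female_offset * fem)
    },
    wright = (co$intercept - co$age_slope * age) * bsa *
      (1 - co$female_reduction * fem) / scr_um,
    martin = co$scale * weight * (1 - co$age_slope * age) *
      (1 - co$female_reduction * fem) / scr_um,
    camgfr = {
      lp <- co$intercept + co$bsa * bsa + co$age * age +
        co$log_creatinine * log(scr) + co$creatinine * scr
      pmax(lp, 1e-6)^2
    },
    abort(sprintf("no evaluator for model '%s'", model_id), class = "gfreval_lookup")
  )

  if (m$native_scale == "normalized_ml_min_173") {
    list(absolute = native * bsa / 1.73, normalized = native)
  } else {
    list(absolute = native, normalized = native * 1.73 / bsa)
  }
}

prepare_model_input <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("age", "sex", "weight", "height")
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")),
          class = "gfreval_schema")
  }
  if (!"creatinine" %in% names(data)) {
    if (all(c("creatinine_value", "creatinine_unit") %in% names(data))) {
      data$creatinine <- creatinine_to_mgdl(data$creatinine_value, data$creatinine_unit)
    } else {
      abort("need a 'creatinine' column (mg/dL) or 'creatinine_value' + 'creatinine_unit'",
            class = "gfreval_schema")
    }
  }
  if (!all(data$sex %in% c("male", "female"))) {
    abort("sex must be 'male' or 'female'", class = "gfreval_invalid")
  }
  if (!"race_black" %in% names(data)) data$race_black <- FALSE
  data$race_black[is.na(data$race_black)] <- FALSE  # missing race treated as nonblack
  check_positive(data$creatinine, "creatinine")
  check_positive(data$weight, "weight")
  check_positive(data$height, "height")
  check_positive(data$age, "age")
  if (!"bsa" %in% names(data)) data$bsa <- dubois_bsa(data$weight, data$height)
  data
}

#' Estimate GFR for each patient under one model
#'
#' Evaluates a registered model row-wise over a patient table. Normalized
#' models (CKD-EPI, MDRD-186, Mayo, Jelliffe) are also rescaled by BSA/1.73
#' so that `egfr_absolute` (mL/min) is always available for comparison with
#' tracer-measured GFR and for Calvert dosing.
#'
#' @param data Data frame with columns `age` (years), `sex`
#'   (`"male"`/`"female"`), `weight` (kg), `height` (cm) and `creatinine`
#'   (mg/dL; or `creatinine_value` + `creatinine_unit`). Optional:
#'   `race_black` (logical, default `FALSE`), `bsa` (derived by
#'   [dubois_bsa()] when absent).
#' @param model_id One registered model id; see [gfr_model_ids()].
#' @param constants Optional constants list from [gfr_constants()].
#' @return The input tibble with `bsa`, `model_id`, `egfr_absolute`
#'   (mL/min) and `egfr_normalized` (mL/min/1.73 m^2) appended.
#' @examples
#' pt <- data.frame(age = 40, sex = "male", weight = 72, height = 180,
#'                  creatinine = 1.0)
#' evaluate_model(pt, "cockcroft_gault")
#' @export
evaluate_model <- function(data, model_id, constants = NULL) {
  data <- prepare_model_input(data)
  est <- egfr_core(model_id, data$age, data$sex == "female", data$race_black,
                   data$weight, data$height, data$bsa, data$creatinine, constants)
  data$model_id <- model_id
  data$egfr_absolute <- est$absolute
  data$egfr_normalized <- est$normalized
  data
}

#' Estimate GFR under several models at once
#'
#' @inheritParams evaluate_model
#' @param models Character vector of model ids (default: all eight).
#' @return Long tibble: one row per patient x model with `.row` indexing
#'   the input row, `model_id`, `egfr_absolute` and `egfr_normalized`.
#' @examples
#' pt <- data.frame(age = 60, sex = "female", weight = 74, height = 169,
#'                  creatinine = 0.95)
#' estimate_gfr(pt)
#' @export
estimate_gfr <- function(data, models = gfr_model_ids(), constants = NULL) {
  data <- prepare_model_input(data)
  data$.row <- seq_len(nrow(data))
  purrr::map_dfr(models, function(id) {
    est <- egfr_core(id, data$age, data$sex == "female", data$race_black,
                     data$weight, data$height, data$bsa, data$creatinine, constants)
    tibble::tibble(.row = data$.row, model_id = id,
                   egfr_absolute = est$absolute,
                   egfr_normalized = est$normalized)
  })
}

#' Append per-model eGFR columns to a patient table
#'
#' Wide companion to [estimate_gfr()]: adds one `egfr_<model>` column
#' (absolute mL/min) per requested model.
#'
#' @inheritParams estimate_gfr
#' @return The input tibble with one absolute-eGFR column per model.
#' @export
add_egfr <- function(data, models = gfr_model_ids(), constants = NULL) {
  data <- prepare_model_input(data)
  for (id in models) {
    est <- egfr_core(id, data$age, data$sex == "female", data$race_black,
                     data$weight, data$height, data$bsa, data$creatinine, constants)
    data[[paste0("egfr_", id)]] <- est$absolute
  }
  data
}

# Solve creatinine (mg/dL) such that the model's *absolute* eGFR equals
# `gfr` for the given covariates. Analytic for models that are pure powers
# or reciprocals of creatinine; numeric root-finding for Mayo and CamGFR.
# Returns NA where no solution exists (target outside the model's range).
invert_gfr <- function(model_id, gfr, age, female, black, weight, height, bsa,
                       constants = NULL) {
  m <- lookup_model(model_id, constants)
  co <- m$coefficients
  fem <- as.numeric(female)
  norm_target <- gfr * 1.73 / bsa   # target on the normalized scale

  out <- switch(
    model_id,
    cockcroft_gault = (co$age_base - age) * weight *
      ifelse(female, co$female_factor, 1) / (co$denominator * gfr),
    jelliffe = {
      tgt <- if (m$native_scale == "normalized_ml_min_173") norm_target else gfr
      (co$intercept - co$age_slope * (age - co$age_offset)) *
        ifelse(female, co$female_factor, 1) / tgt
    },
    mdrd186 = {
      base <- co$scale * age^co$age_exp * ifelse(female, co$female_factor, 1) *
        ifelse(black, co$black_factor, 1)
      (norm_target / base)^(1 / co$creatinine_exp)
    },
    ckd_epi = {
      kappa <- ifelse(female, co$kappa_female, co$kappa_male)
      alpha <- ifelse(female, co$alpha_female, co$alpha_male)
      base <- co$scale * co$age_base^age * ifelse(female, co$female_factor, 1) *
        ifelse(black, co$black_factor, 1)
      r <- norm_target / base
      # r < 1 lies on the scr > kappa branch (exponent beta), r >= 1 on alpha
      ifelse(r < 1, kappa * r^(1 / co$beta), kappa * r^(1 / alpha))
    },
    wright = (co$intercept - co$age_slope * age) * bsa *
      (1 - co$female_reduction * fem) / gfr / UMOL_PER_MGDL,
    martin = co$scale * weight * (1 - co$age_slope * age) *
      (1 - co$female_reduction * fem) / gfr / UMOL_PER_MGDL,
    mayo = ,
    camgfr = invert_numeric(model_id, gfr, age, female, black, weight, height,
                            bsa, constants),
    abort(sprintf("no inverse for model '%s'", model_id), class = "gfreval_lookup")
  )
  out[!is.finite(out) | out <= 0] <- NA_real_
  out
}

invert_numeric <- function(model_id, gfr, age, female, black, weight, height,
                           bsa, constants) {
  # strictly decreasing search range; Mayo starts just above its stationary
  # point at scr ~ 0.8055 mg/dL (clamped region is non-invertible anyway)
  lo <- if (model_id == "mayo") 0.806 else 0.01
  hi <- 60
  vapply(seq_along(gfr), function(i) {
    f <- function(s) {
      egfr_core(model_id, age[i], female[i], black[i], weight[i], height[i],
                bsa[i], s, constants)$absolute - gfr[i]
    }
    flo <- f(lo); fhi <- f(hi)
    if (!is.finite(flo) || !is.finite(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = 1e-12)$root
  }, numeric(1))
}
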