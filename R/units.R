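# micromoles of creatinine per litre in 1 mg/dL (molar mass 113.12 g/mol)
UMOL_PER_MGDL <- 88.42

#' DuBois & DuBois body surface area
#'
#' BSA (m^2) = 0.007184 * weight^0.425 * height^0.725, the convention used
#' throughout the multicenter GFR-model validation framework.
#'
#' @param weight Body weight in kg (vectorised).
#' @param height Height in cm (vectorised).
#' @return Body surface area in m^2.
#' @examples
#' dubois_bsa(74, 169) # 1.85 m^2, the cohort median
#' @export
dubois_bsa <- function(weight, height) {
  check_positive(weight, "weight")
  check_positive(height, "height")
  0.007184 * weight^0.425 * height^0.725
}

#' Convert serum creatinine to mg/dL
#'
#' @param value Creatinine concentration(s), positive.
#' @param unit `"mg_dl"` (identity) or `"umol_l"`; recycled against `value`.
#' @return Creatinine in mg/dL (1 mg/dL = 88.42 umol/L).
#' @export
creatinine_to_mgdl <- function(value, unit = "mg_dl") {
  check_positive(value, "creatinine")
  if (!all(unit %in% c("mg_dl", "umol_l"))) {
    abort(sprintf("unknown creatinine unit(s): %s",
                  paste(unique(setdiff(unit, c("mg_dl", "umol_l"))), collapse = ", ")),
          class = "gfreval_invalid")
  }
  ifelse(rep_len(unit, length(value)) == "umol_l", value / UMOL_PER_MGDL, value)
}

#' Convert a BSA-normalized GFR to absolute mL/min
#'
#' Models reporting mL/min/1.73 m^2 are rescaled by `bsa / 1.73` before
#' comparison with tracer-measured GFR, which is absolute.
#'
#' @param value GFR in mL/min/1.73 m^2.
#' @param bsa Body surface area in m^2.
#' @return GFR in mL/min.
#' @export
denormalize_gfr <- function(value, bsa) {
  check_positive(value, "value")
  check_positive(bsa, "bsa")
  value * bsa / 1.73
}

#' Carboplatin dose from the Calvert equation
#'
#' dose (mg) = target AUC * (GFR + 25), linear in both arguments, so any
#' error in estimated GFR propagates linearly into the prescribed dose.
#'
#' @param target_auc Target area under the free-carboplatin concentration
#'   curve, mg.min/mL (commonly 4-7).
#' @param gfr Glomerular filtration rate in mL/min (absolute).
#' @return Dose in mg.
#' @examples
#' calvert_dose(5, 86) # 555 mg at the cohort mean GFR
#' @export
calvert_dose <- function(target_auc, gfr) {
  if (any(!is.finite(target_auc)) || any(target_auc < 0)) {
    abort("target_auc must be finite and >= 0", class = "gfreval_invalid")
  }
  if (any(!is.finite(gfr)) || any(gfr < 0)) {
    abort("gfr must be finite and >= 0", class = "gfreval_invalid")
  }
  target_auc * (gfr + 25)
}

check_positive <- function(x, what) {
  if (length(x) == 0 || any(!is.finite(x)) || any(x <= 0)) {
    abort(sprintf("%s must be positive and finite", what), class = "gfreval_invalid")
  }
  invisible(x)
}
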