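# Coefficient registry for the creatinine-based GFR / CrCl estimation models.
#
# Every model declares its native output scale (absolute_ml_min or
# normalized_ml_min_173) and the creatinine unit its published formula
# expects.  Values entered here must be traceable to the source_ref; a user
# can point gfr_constants() at an edited copy of this file to override any
# coefficient without touching package code (e.g. to treat the Jelliffe
# output as absolute rather than BSA-normalized, flip its native_scale).
models:
  camgfr:
    label: "CamGFR"
    native_scale: absolute_ml_min
    creatinine_unit: mg_dl
    source_ref: >
      Janowitz et al., J Clin Oncol 35(24):2798-2805 (2017).
      UNVERIFIED TRANSCRIPTION of the square-root-scale model taken from
      secondary literature; verify every coefficient against the primary
      reference (or the authors' online calculator) before clinical use.
    coefficients:
      intercept: 1.8140
      bsa: 4.7328
      age: -0.0072
      log_creatinine: -1.0920
      creatinine: -0.6700
  ckd_epi:
    label: "CKD-EPI"
    native_scale: normalized_ml_min_173
    creatinine_unit: mg_dl
    source_ref: "Levey et al., Ann Intern Med 150(9):604-612 (2009). 2009 creatinine equation."
    coefficients:
      scale: 141
      kappa_female: 0.7
      kappa_male: 0.9
      alpha_female: -0.329
      alpha_male: -0.411
      beta: -1.209
      age_base: 0.993
      female_factor: 1.018
      black_factor: 1.159
  mdrd186:
    label: "MDRD-186"
    native_scale: normalized_ml_min_173
    creatinine_unit: mg_dl
    source_ref: "Levey et al., Ann Intern Med 130(6):461-470 (1999). 186-coefficient (non-IDMS) 4-variable MDRD equation."
    coefficients:
      scale: 186
      creatinine_exp: -1.154
      age_exp: -0.203
      female_factor: 0.742
      black_factor: 1.212
  mayo:
    label: "Mayo"
    native_scale: normalized_ml_min_173
    creatinine_unit: mg_dl
    source_ref: "Rule et al., Ann Intern Med 141(12):929-937 (2004). Mayo Clinic quadratic equation; creatinine below the clamp is set to the clamp."
    coefficients:
      intercept: 1.911
      inv_creatinine: 5.249
      inv_creatinine_sq: -2.114
      age: -0.00686
      female_offset: -0.205
      creatinine_clamp: 0.8
  wright:
    label: "Wright"
    native_scale: absolute_ml_min
    creatinine_unit: umol_l
    source_ref: "Wright et al., Br J Cancer 84(4):452-459 (2001). GFR = (6580 - 38.8*age) * BSA * (1 - 0.168*female) / SCr[umol/L]."
    coefficients:
      intercept: 6580
      age_slope: 38.8
      female_reduction: 0.168
  martin:
    label: "Martin"
    native_scale: absolute_ml_min
    creatinine_unit: umol_l
    source_ref: >
      Martin et al. (1998), creatinine-clearance model for oncology patients.
      UNVERIFIED TRANSCRIPTION: CrCl = 163 * weight * (1 - 0.00496*age) *
      (1 - 0.252*female) / SCr[umol/L]; verify against the primary reference
      before clinical use.
    coefficients:
      scale: 163
      age_slope: 0.00496
      female_reduction: 0.252
  cockcroft_gault:
    label: "Cockcroft-Gault"
    native_scale: absolute_ml_min
    creatinine_unit: mg_dl
    source_ref: "Cockcroft & Gault, Nephron 16(1):31-41 (1976). CrCl = (140 - age)*weight*(0.85 if female)/(72*SCr)."
    coefficients:
      age_base: 140
      denominator: 72
      female_factor: 0.85
  jelliffe:
    label: "Jelliffe"
    native_scale: normalized_ml_min_173
    creatinine_unit: mg_dl
    source_ref: "Jelliffe, Ann Intern Med 79(4):604 (1973). CrCl = (98 - 0.8*(age - 20))*(0.9 if female)/SCr, per 1.73 m2."
    coefficients:
      intercept: 98
      age_slope: 0.8
      age_offset: 20
      female_factor: 0.9
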