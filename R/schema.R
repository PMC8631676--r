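#' Canonical cohort column schema
#'
#' A cohort is an ordinary tibble with one row per patient. This table is the
#' package-wide contract for the columns that the scoring, quantification and
#' simulation functions understand. Units are fixed: amplitudes in mV,
#' durations in ms, echo linear dimensions in cm, weight in kg, height in cm,
#' LV mass in g, LV mass index in g/m2. There is no unit auto-detection.
#'
#' Columns fall into four groups:
#' \describe{
#'   \item{identity}{`id` (unique string), `age_years`, `sex` (`"male"` or
#'     `"female"`; the aliases `"M"`, `"F"`, `"male"`, `"female"` are accepted
#'     case-insensitively on read and normalized — anything else is an error).}
#'   \item{ecg}{Per-lead wave amplitudes (`R_amp_<lead>_mV`, `S_amp_<lead>_mV`,
#'     S waves stored as non-negative magnitudes), T-wave amplitude in lead I
#'     (`T_amp_I_mV`, may be negative on T inversion), peak-to-peak QRS
#'     amplitudes (`QRS_ppk_aVL_mV`, `QRS_ppk_aVF_mV`), `QRS_dur_ms`,
#'     `QRS_axis_deg`, intrinsicoid deflection in V5/V6 (ms), negative P
#'     terminal force in V1 in Ashman units (1 unit = 1 mm depth x 0.04 s),
#'     the ST strain-pattern flag, ST depression at J+40 ms (mm), and the
#'     digitalis flag.}
#'   \item{echo}{Diastolic LV linear dimensions `IVST_cm`, `LVID_cm`,
#'     `LVPWT_cm`.}
#'   \item{anthro}{`weight_kg`, `height_cm`.}
#' }
#'
#' Unknown columns are carried through readers and writers untouched; the
#' clinical ECG export this schema emulates carries hundreds of parameters and
#' only the columns named here are ever interpreted.
#'
#' @return A tibble with columns `column`, `type` (`"character"`, `"numeric"`
#'   or `"logical"`), `group`, and `description`.
#' @export
#' @examples
#' cohort_schema()
cohort_schema <- function() {
  amp <- function(kind, lead) {
    tibble::tibble(
      column = sprintf("%s_amp_%s_mV", kind, lead), type = "numeric",
      group = "ecg",
      description = sprintf("%s-wave amplitude in lead %s (mV%s)", kind, lead,
                            if (kind == "S") ", magnitude" else "")
    )
  }
  limb <- c("I", "II", "III", "aVR", "aVL", "aVF")
  dplyr::bind_rows(
    tibble::tibble(column = "id", type = "character", group = "identity",
                   description = "opaque patient identifier, unique in a cohort"),
    tibble::tibble(column = "age_years", type = "numeric", group = "identity",
                   description = "age in years"),
    tibble::tibble(column = "sex", type = "character", group = "identity",
                   description = "\"male\" or \"female\""),
    tibble::tibble(column = "T_amp_I_mV", type = "numeric", group = "ecg",
                   description = "T-wave amplitude in lead I (mV, signed)"),
    tibble::tibble(column = c("QRS_ppk_aVL_mV", "QRS_ppk_aVF_mV"),
                   type = "numeric", group = "ecg",
                   description = c("peak-to-peak QRS amplitude in aVL (mV)",
                                   "peak-to-peak QRS amplitude in aVF (mV)")),
    purrr::map_dfr(limb, ~ amp("R", .x)),
    purrr::map_dfr(limb, ~ amp("S", .x)),
    amp("R", "V5"), amp("R", "V6"), amp("S", "V1"), amp("S", "V2"),
    amp("S", "V3"),
    tibble::tibble(
      column = c("QRS_dur_ms", "QRS_axis_deg", "intrinsicoid_V5_ms",
                 "intrinsicoid_V6_ms", "P_term_force_ashman",
                 "ST_dep_mm_j40"),
      type = "numeric", group = "ecg",
      description = c("QRS duration (ms)", "frontal-plane QRS axis (degrees)",
                      "intrinsicoid deflection in V5 (ms)",
                      "intrinsicoid deflection in V6 (ms)",
                      "negative P terminal force, V1 (Ashman units)",
                      "ST depression 40 ms after the J point (mm)")),
    tibble::tibble(column = c("ST_strain", "on_digitalis"), type = "logical",
                   group = "ecg",
                   description = c("ST strain pattern present",
                                   "patient on digitalis")),
    tibble::tibble(column = c("IVST_cm", "LVID_cm", "LVPWT_cm"),
                   type = "numeric", group = "echo",
                   description = c("interventricular septal thickness, diastole (cm)",
                                   "LV internal diameter, diastole (cm)",
                                   "LV posterior wall thickness, diastole (cm)")),
    tibble::tibble(column = c("weight_kg", "height_cm"), type = "numeric",
                   group = "anthro",
                   description = c("body weight (kg)", "height (cm)"))
  )
}

# columns a criterion or computation needs; names are registry keys
schema_requirements <- function() {
  limb <- c("I", "II", "III", "aVR", "aVL", "aVF")
  list(
    sokolow = "R_amp_aVL_mV",
    cornell = c("sex", "S_amp_V3_mV", "R_amp_aVL_mV"),
    dalfo   = c("sex", "S_amp_V3_mV", "R_amp_aVL_mV"),
    vdp     = c("sex", "S_amp_V3_mV", "R_amp_aVL_mV", "QRS_dur_ms"),
    romhilt = c(sprintf("R_amp_%s_mV", limb), sprintf("S_amp_%s_mV", limb),
                "R_amp_V5_mV", "R_amp_V6_mV", "S_amp_V1_mV", "S_amp_V2_mV",
                "QRS_dur_ms", "QRS_axis_deg", "intrinsicoid_V5_ms",
                "intrinsicoid_V6_ms", "P_term_force_ashman", "ST_strain",
                "on_digitalis"),
    chcm    = c("T_amp_I_mV", "QRS_ppk_aVL_mV", "QRS_ppk_aVF_mV"),
    echo    = c("sex", "IVST_cm", "LVID_cm", "LVPWT_cm", "weight_kg",
                "height_cm")
  )
}

# error if any of `cols` is missing or (check_na) contains NA; names the field
require_features <- function(data, cols, context, check_na = TRUE) {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    stop(sprintf("%s: missing required column(s): %s", context,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (check_na) {
    for (col in cols) {
      bad <- which(is.na(data[[col]]))
      if (length(bad) > 0) {
        stop(sprintf("%s: missing value in required feature '%s' (row %s)",
                     context, col, bad[1]), call. = FALSE)
      }
    }
  }
  invisible(data)
}

normalize_sex <- function(x) {
  key <- tolower(trimws(as.character(x)))
  out <- dplyr::case_when(
    key %in% c("m", "male") ~ "male",
    key %in% c("f", "female") ~ "female",
    .default = NA_character_
  )
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad) > 0) {
    stop(sprintf("sex: unrecognized value '%s' (row %s); expected one of M, F, male, female",
                 x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

check_sex <- function(sex, context = "sex") {
  if (any(is.na(sex)) || !all(sex %in% c("male", "female"))) {
    stop(sprintf("%s: must be \"male\" or \"female\"", context), call. = FALSE)
  }
  invisible(sex)
}
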