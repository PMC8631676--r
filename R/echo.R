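#' Body surface area (Mosteller)
#'
#' `BSA = sqrt(weight_kg * height_cm / 3600)` in m2.
#'
#' @param weight_kg Body weight in kg (> 0).
#' @param height_cm Height in cm (> 0).
#' @return BSA in m2 (vectorized).
#' @export
#' @examples
#' mosteller_bsa(36, 100)       # exactly 1
#' mosteller_bsa(77.8, 168.1)   # ~1.906
mosteller_bsa <- function(weight_kg, height_cm) {
  if (any(!is.finite(weight_kg)) || any(!is.finite(height_cm)) ||
      any(weight_kg <= 0) || any(height_cm <= 0)) {
    stop("mosteller_bsa: weight_kg and height_cm must be finite and positive",
         call. = FALSE)
  }
  sqrt(weight_kg * height_cm / 3600)
}

#' Left ventricular mass (linear/cube method)
#'
#' Devereux cube formula from diastolic linear measurements:
#' `LVM = 0.8 * 1.04 * ((LVID + LVPWT + IVST)^3 - LVID^3) + 0.6` grams.
#'
#' @param ivst_cm Interventricular septal thickness, diastole (cm, >= 0).
#' @param lvid_cm LV internal diameter, diastole (cm, > 0).
#' @param lvpwt_cm LV posterior wall thickness, diastole (cm, >= 0).
#' @return LV mass in grams (vectorized).
#' @export
#' @examples
#' lv_mass(1.04, 4.38, 1.04)  # ~155 g, a typical non-hypertrophic heart
lv_mass <- function(ivst_cm, lvid_cm, lvpwt_cm) {
  if (any(!is.finite(ivst_cm)) || any(!is.finite(lvid_cm)) ||
      any(!is.finite(lvpwt_cm)) ||
      any(ivst_cm < 0) || any(lvpwt_cm < 0) || any(lvid_cm <= 0)) {
    stop("lv_mass: wall thicknesses must be >= 0 and LVID > 0", call. = FALSE)
  }
  0.8 * 1.04 * ((lvid_cm + lvpwt_cm + ivst_cm)^3 - lvid_cm^3) + 0.6
}

#' Left ventricular mass index
#'
#' `LVMI = LVM / BSA` in g/m2.
#'
#' @param lvm_g LV mass in grams.
#' @param bsa_m2 Body surface area in m2 (> 0).
#' @return LVMI in g/m2 (vectorized).
#' @export
lvmi <- function(lvm_g, bsa_m2) {
  if (any(!is.finite(bsa_m2)) || any(bsa_m2 <= 0)) {
    stop("lvmi: bsa_m2 must be positive", call. = FALSE)
  }
  lvm_g / bsa_m2
}

# sex-specific LVMI cutoffs (g/m2): LVH positive strictly above `lvh`;
# severity bands are continuous half-open intervals anchored at the cutoffs
lvmi_cutoffs <- function(sex) {
  male <- sex == "male"
  list(lvh      = ifelse(male, 115, 95),
       moderate = ifelse(male, 131, 108),
       severe   = ifelse(male, 148, 121))
}

#' Classify LVH status and severity from indexed LV mass
#'
#' LVH is positive strictly above the sex-specific LVMI cutoff (male
#' 115 g/m2, female 95 g/m2). Severity uses continuous half-open bands
#' anchored at the cutoffs so that classification is total for non-integer
#' LVMI: male mild (115, 131], moderate (131, 148], severe > 148; female mild
#' (95, 108], moderate (108, 121], severe > 121.
#'
#' @param sex `"male"` or `"female"` (vectorized).
#' @param lvmi_g_per_m2 LVMI in g/m2.
#' @return A tibble with columns `lvh_positive` (logical) and `severity`
#'   (factor: none, mild, moderate, severe).
#' @export
#' @examples
#' classify_lvh("male", 134.2)   # positive, moderate
#' classify_lvh("male", 115)     # negative ("above 115" is strict)
classify_lvh <- function(sex, lvmi_g_per_m2) {
  check_sex(sex, "classify_lvh: sex")
  if (any(!is.finite(lvmi_g_per_m2))) {
    stop("classify_lvh: lvmi must be finite", call. = FALSE)
  }
  cut <- lvmi_cutoffs(sex)
  positive <- lvmi_g_per_m2 > cut$lvh
  severity <- dplyr::case_when(
    !positive ~ "none",
    lvmi_g_per_m2 <= cut$moderate ~ "mild",
    lvmi_g_per_m2 <= cut$severe ~ "moderate",
    .default = "severe"
  )
  tibble::tibble(
    lvh_positive = positive,
    severity = factor(severity, levels = c("none", "mild", "moderate", "severe"))
  )
}

#' Relative wall thickness
#'
#' `RWT = 2 * LVPWT / LVID` (dimensionless).
#'
#' @inheritParams lv_mass
#' @return RWT (vectorized).
#' @export
rwt <- function(lvpwt_cm, lvid_cm) {
  if (any(!is.finite(lvid_cm)) || any(lvid_cm <= 0) || any(lvpwt_cm < 0)) {
    stop("rwt: LVID must be positive and LVPWT non-negative", call. = FALSE)
  }
  2 * lvpwt_cm / lvid_cm
}

#' Left ventricular geometry class
#'
#' Partitions LV geometry by LVH status and relative wall thickness:
#' normal (no LVH, RWT <= 0.42), concentric remodeling (no LVH, RWT > 0.42),
#' concentric hypertrophy (LVH, RWT > 0.42), eccentric hypertrophy (LVH,
#' RWT <= 0.42). Every (lvh, rwt) pair maps to exactly one class.
#'
#' @param lvh_positive Logical LVH status.
#' @param rwt Relative wall thickness (>= 0).
#' @return Factor with levels normal, remodeling, concentric_lvh,
#'   eccentric_lvh (vectorized).
#' @export
#' @examples
#' lv_geometry(FALSE, 0.50)  # remodeling
#' lv_geometry(TRUE, 0.42)   # eccentric_lvh (boundary is inclusive)
lv_geometry <- function(lvh_positive, rwt) {
  if (any(!is.finite(rwt)) || any(rwt < 0)) {
    stop("lv_geometry: rwt must be finite and >= 0", call. = FALSE)
  }
  if (any(is.na(lvh_positive))) {
    stop("lv_geometry: lvh_positive must not be missing", call. = FALSE)
  }
  cls <- dplyr::case_when(
    !lvh_positive & rwt <= 0.42 ~ "normal",
    !lvh_positive ~ "remodeling",
    rwt > 0.42 ~ "concentric_lvh",
    .default = "eccentric_lvh"
  )
  factor(cls, levels = c("normal", "remodeling", "concentric_lvh",
                         "eccentric_lvh"))
}

#' Echocardiographic ground truth for a cohort
#'
#' Computes, per patient, the full echo-derived reference standard used to
#' evaluate ECG criteria: BSA ([mosteller_bsa()]), LV mass ([lv_mass()]), LVMI
#' ([lvmi()]), LVH status and severity ([classify_lvh()]), RWT ([rwt()]) and
#' geometry class ([lv_geometry()]).
#'
#' @param cohort A cohort tibble with echo columns `IVST_cm`, `LVID_cm`,
#'   `LVPWT_cm`, `weight_kg`, `height_cm` and `sex`.
#' @return The cohort with columns `bsa_m2`, `lvm_g`, `lvmi_g_per_m2`, `rwt`,
#'   `lvh_positive`, `severity`, `geometry` appended.
#' @export
#' @examples
#' generate_cohort(cohort_config(n_patients = 4, seed = 1)) |>
#'   echo_ground_truth()
echo_ground_truth <- function(cohort) {
  cohort <- validate_cohort(cohort)
  require_features(cohort, schema_requirements()$echo, "echo_ground_truth")
  derived <- c("bsa_m2", "lvm_g", "lvmi_g_per_m2", "rwt", "lvh_positive",
               "severity", "geometry")
  cohort <- dplyr::select(cohort, -dplyr::any_of(derived))
  out <- cohort |>
    dplyr::mutate(
      bsa_m2 = mosteller_bsa(.data$weight_kg, .data$height_cm),
      lvm_g = lv_mass(.data$IVST_cm, .data$LVID_cm, .data$LVPWT_cm),
      lvmi_g_per_m2 = lvmi(.data$lvm_g, .data$bsa_m2),
      rwt = rwt(.data$LVPWT_cm, .data$LVID_cm)
    )
  out |>
    dplyr::bind_cols(classify_lvh(out$sex, out$lvmi_g_per_m2)) |>
    dplyr::mutate(geometry = lv_geometry(.data$lvh_positive, .data$rwt))
}
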