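#' @title Classical ECG criteria for left ventricular hypertrophy
#' @description Vectorized calculators for the comparator criteria battery:
#'   Sokolow-Lyon (aVL form), Cornell voltage, Dalfo voltage, the Cornell
#'   voltage-duration product and the Romhilt-Estes point score. Each returns
#'   one row per input with the criterion name, the numeric score (mV sum,
#'   mV*ms product, or points) and the dichotomous call at the criterion's
#'   published threshold. Voltage thresholds are strict (`>`); Romhilt-Estes
#'   item comparisons use `>=`. S-wave amplitudes are magnitudes (mV, >= 0).
#' @name criteria
NULL

criterion_tbl <- function(name, score, positive, ...) {
  tibble::tibble(criterion = name, score = score, positive = positive, ...)
}

check_amp <- function(x, what) {
  if (any(is.na(x)) || any(!is.finite(x)) || any(x < 0)) {
    stop(sprintf("%s: amplitude must be finite and non-negative", what),
         call. = FALSE)
  }
  invisible(x)
}

#' @rdname criteria
#' @param r_avl_mv R-wave amplitude in aVL (mV).
#' @return A tibble with columns `criterion`, `score`, `positive` (and, for
#'   [romhilt_estes()], one column per point item).
#' @export
#' @examples
#' sokolow_avl(1.2)                  # positive: R aVL > 1.1 mV
#' cornell("male", 1.5, 1.4)         # score 2.9 mV, positive
#' dalfo("female", 0.8, 0.7)         # score 1.5 mV, positive
#' vdp_cornell("male", 1.5, 1.5, 90) # 270 mV*ms, positive
sokolow_avl <- function(r_avl_mv) {
  check_amp(r_avl_mv, "sokolow_avl: r_avl_mv")
  criterion_tbl("sokolow", r_avl_mv, r_avl_mv > 1.1)
}

voltage_sum <- function(name, sex, s_v3_mv, r_avl_mv, male_thr, female_thr) {
  check_sex(sex, paste0(name, ": sex"))
  check_amp(s_v3_mv, paste0(name, ": s_v3_mv"))
  check_amp(r_avl_mv, paste0(name, ": r_avl_mv"))
  score <- s_v3_mv + r_avl_mv
  thr <- ifelse(sex == "male", male_thr, female_thr)
  criterion_tbl(name, score, score > thr)
}

#' @rdname criteria
#' @param sex `"male"` or `"female"`.
#' @param s_v3_mv S-wave magnitude in V3 (mV).
#' @export
cornell <- function(sex, s_v3_mv, r_avl_mv) {
  voltage_sum("cornell", sex, s_v3_mv, r_avl_mv, 2.8, 2.0)
}

#' @rdname criteria
#' @export
dalfo <- function(sex, s_v3_mv, r_avl_mv) {
  voltage_sum("dalfo", sex, s_v3_mv, r_avl_mv, 1.6, 1.4)
}

#' @rdname criteria
#' @param qrs_dur_ms QRS duration (ms, > 0).
#' @details The voltage-duration product adds 0.6 mV to the Cornell voltage
#'   sum in females before multiplying by QRS duration; positive above
#'   244 mV*ms for either sex.
#' @export
vdp_cornell <- function(sex, r_avl_mv, s_v3_mv, qrs_dur_ms) {
  check_sex(sex, "vdp_cornell: sex")
  check_amp(r_avl_mv, "vdp_cornell: r_avl_mv")
  check_amp(s_v3_mv, "vdp_cornell: s_v3_mv")
  if (any(is.na(qrs_dur_ms)) || any(qrs_dur_ms <= 0)) {
    stop("vdp_cornell: qrs_dur_ms must be positive", call. = FALSE)
  }
  score <- (r_avl_mv + s_v3_mv + ifelse(sex == "female", 0.6, 0)) * qrs_dur_ms
  criterion_tbl("vdp", score, score > 244)
}

#' Romhilt-Estes point score
#'
#' Awards points for six items and calls LVH at `>= 4` points:
#' \itemize{
#'   \item 3 — negative P terminal force in V1 `>= 1` Ashman unit
#'     (1 unit = 1 mm depth x 0.04 s);
#'   \item 3 — any limb-lead R or S magnitude `>= 2.0` mV, or R in V5/V6
#'     `>= 3.0` mV, or S in V1/V2 `>= 3.0` mV (one group, awarded at most
#'     once);
#'   \item 3 — ST strain pattern without digitalis;
#'   \item 1 — QRS duration `>= 90` ms;
#'   \item 2 — left axis deviation, QRS axis `<= -30` degrees;
#'   \item 1 — intrinsicoid deflection in V5 or V6 `>= 50` ms.
#' }
#' Maximum 13 points.
#'
#' @param ecg A data frame (usually a cohort tibble) carrying the columns in
#'   `schema_requirements()$romhilt`; rows are scored independently.
#' @return A tibble with `criterion`, `score` (points), `positive`, and one
#'   column of awarded points per item (`pts_*`).
#' @export
#' @examples
#' ecg <- generate_cohort(cohort_config(n_patients = 3, seed = 1))
#' romhilt_estes(ecg)
romhilt_estes <- function(ecg) {
  req <- schema_requirements()$romhilt
  require_features(ecg, req, "romhilt_estes")
  limb <- c("I", "II", "III", "aVR", "aVL", "aVF")
  amp_cols <- c(sprintf("R_amp_%s_mV", limb), sprintf("S_amp_%s_mV", limb))
  limb_max <- do.call(pmax, ecg[amp_cols])
  voltage <- limb_max >= 2.0 |
    pmax(ecg$R_amp_V5_mV, ecg$R_amp_V6_mV) >= 3.0 |
    pmax(ecg$S_amp_V1_mV, ecg$S_amp_V2_mV) >= 3.0
  pts <- tibble::tibble(
    pts_p_terminal = 3L * (ecg$P_term_force_ashman >= 1),
    pts_voltage = 3L * voltage,
    pts_strain = 3L * (ecg$ST_strain & !ecg$on_digitalis),
    pts_qrs_duration = 1L * (ecg$QRS_dur_ms >= 90),
    pts_left_axis = 2L * (ecg$QRS_axis_deg <= -30),
    pts_intrinsicoid = 1L * (pmax(ecg$intrinsicoid_V5_ms,
                                  ecg$intrinsicoid_V6_ms) >= 50)
  )
  score <- rowSums(pts)
  dplyr::bind_cols(criterion_tbl("romhilt", score, score >= 4), pts)
}

# registry: required columns + a cohort -> tibble(score, positive) scorer
criteria_registry <- function() {
  req <- schema_requirements()
  list(
    sokolow = list(required = req$sokolow,
                   fn = function(d) sokolow_avl(d$R_amp_aVL_mV)),
    cornell = list(required = req$cornell,
                   fn = function(d) cornell(d$sex, d$S_amp_V3_mV, d$R_amp_aVL_mV)),
    dalfo = list(required = req$dalfo,
                 fn = function(d) dalfo(d$sex, d$S_amp_V3_mV, d$R_amp_aVL_mV)),
    vdp = list(required = req$vdp,
               fn = function(d) vdp_cornell(d$sex, d$R_amp_aVL_mV,
                                            d$S_amp_V3_mV, d$QRS_dur_ms)),
    romhilt = list(required = req$romhilt, fn = romhilt_estes),
    chcm = list(required = req$chcm,
                fn = function(d) {
                  res <- chcm_classify(d)
                  criterion_tbl("chcm", as.numeric(res$positive), res$positive)
                })
  )
}

#' Names of the registered ECG-LVH criteria
#'
#' @return Character vector of criterion names accepted by
#'   [score_criteria()] and the command-line interface.
#' @export
lvh_criteria <- function() names(criteria_registry())

#' Score a cohort against one or more ECG-LVH criteria
#'
#' @param cohort A cohort tibble.
#' @param criteria Character vector of criterion names (see [lvh_criteria()]);
#'   defaults to the full battery.
#' @return A long tibble with one row per patient per criterion: `id` (when
#'   present), `criterion`, `score`, `positive`.
#' @export
#' @examples
#' generate_cohort(cohort_config(n_patients = 5, seed = 1)) |>
#'   score_criteria(criteria = c("dalfo", "chcm"))
score_criteria <- function(cohort, criteria = lvh_criteria()) {
  registry <- criteria_registry()
  unknown <- setdiff(criteria, names(registry))
  if (length(unknown) > 0) {
    stop(sprintf("unknown criterion: %s (valid: %s)",
                 paste(unknown, collapse = ", "),
                 paste(names(registry), collapse = ", ")), call. = FALSE)
  }
  cohort <- validate_cohort(cohort)
  purrr::map_dfr(criteria, function(name) {
    entry <- registry[[name]]
    res <- tryCatch(
      {
        require_features(cohort, entry$required, "input")
        entry$fn(cohort)
      },
      error = function(e) {
        stop(sprintf("criterion '%s': %s", name, conditionMessage(e)),
             call. = FALSE)
      }
    )
    out <- res[, c("criterion", "score", "positive")]
    if ("id" %in% names(cohort)) out <- dplyr::bind_cols(
      tibble::tibble(id = cohort$id), out)
    out
  })
}
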