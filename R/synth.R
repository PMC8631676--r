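default_echo_params <- function() {
  # class-conditional diastolic echo and anthropometric distributions
  # (mean, sd) for the non-LVH and LVH mixture components
  list(
    IVST_cm   = list(neg = c(1.04, 0.19), pos = c(1.34, 0.27), floor = 0.4),
    LVID_cm   = list(neg = c(4.38, 0.63), pos = c(4.77, 0.80), floor = 2.0),
    LVPWT_cm  = list(neg = c(1.04, 0.19), pos = c(1.33, 0.24), floor = 0.4),
    weight_kg = list(neg = c(77.8, 16.1), pos = c(78.2, 17.6), floor = 35),
    height_cm = list(neg = c(168.1, 9.6), pos = c(166.3, 9.7), floor = 130)
  )
}

default_ecg_params <- function() {
  # class-conditional ECG measurement distributions (mean, sd, floor);
  # voltages rise and lead-I T amplitude falls with LVH
  limb <- c("I", "II", "III", "aVR", "aVL", "aVF")
  p <- list(
    T_amp_I_mV = list(neg = c(0.15, 0.12), pos = c(0.02, 0.15), floor = -1),
    QRS_ppk_aVL_mV = list(neg = c(0.55, 0.30), pos = c(0.95, 0.45), floor = 0.02),
    QRS_ppk_aVF_mV = list(neg = c(0.55, 0.32), pos = c(0.80, 0.42), floor = 0.02),
    S_amp_V3_mV = list(neg = c(0.60, 0.35), pos = c(1.05, 0.50), floor = 0),
    R_amp_V5_mV = list(neg = c(1.20, 0.50), pos = c(1.80, 0.70), floor = 0),
    R_amp_V6_mV = list(neg = c(1.10, 0.45), pos = c(1.60, 0.65), floor = 0),
    S_amp_V1_mV = list(neg = c(0.90, 0.40), pos = c(1.40, 0.60), floor = 0),
    S_amp_V2_mV = list(neg = c(1.10, 0.45), pos = c(1.60, 0.65), floor = 0),
    QRS_dur_ms = list(neg = c(92, 10), pos = c(100, 12), floor = 60),
    QRS_axis_deg = list(neg = c(30, 30), pos = c(0, 35), floor = -180),
    intrinsicoid_V5_ms = list(neg = c(38, 6), pos = c(45, 8), floor = 10),
    intrinsicoid_V6_ms = list(neg = c(38, 6), pos = c(45, 8), floor = 10),
    P_term_force_ashman = list(neg = c(0.40, 0.35), pos = c(0.90, 0.60), floor = 0),
    ST_dep_mm_j40 = list(neg = c(0.10, 0.20), pos = c(0.50, 0.50), floor = 0)
  )
  # aVL and aVF wave amplitudes are derived in generate_cohort() as
  # fractions of the lead's peak-to-peak amplitude, which guarantees the
  # dominance invariant QRS_ppk >= |R|, |S|
  for (l in setdiff(limb, c("aVL", "aVF"))) {
    p[[sprintf("R_amp_%s_mV", l)]] <- list(neg = c(0.30, 0.18),
                                           pos = c(0.50, 0.28), floor = 0)
    p[[sprintf("S_amp_%s_mV", l)]] <- list(neg = c(0.30, 0.18),
                                           pos = c(0.50, 0.28), floor = 0)
  }
  # binary flags: class-conditional Bernoulli probabilities
  p$ST_strain <- list(neg = 0.05, pos = 0.30)
  p$on_digitalis <- list(neg = 0.05, pos = 0.05)
  p
}

#' Configuration for the synthetic cohort generator
#'
#' Defines a seeded two-class generative model of the cohorts the ECG-LVH
#' criteria are evaluated on. Echo linear dimensions and anthropometrics are
#' drawn from class-conditional truncated normals (LVH hearts have thicker
#' walls and larger cavities); the echo-derived LVH classification of the
#' generated measurements defines the ground truth; ECG measurements are then
#' drawn class-conditionally with voltages shifted up and lead-I T-wave
#' amplitude shifted down in LVH. The LVH mixture weight is internally
#' calibrated (by a seeded Monte Carlo estimate of the per-component
#' echo-positive rates) so that the empirical echo-LVH prevalence matches
#' `lvh_prevalence`.
#'
#' @param n_patients Number of patients.
#' @param lvh_prevalence Target echo-LVH prevalence (default 0.462).
#' @param sex_ratio Fraction male (default 0.532).
#' @param seed Integer seed; identical configs generate identical cohorts.
#' @param ecg_effect_scale Scales the LVH-vs-control shift of every ECG
#'   feature: 1 = full configured effects, 0 = ECG independent of class.
#' @param n_noise_features Number of uninformative numeric columns
#'   (`noise_01`, ...) emulating the bulk of an automated ECG export.
#' @param noise_sd Standard deviation of the noise features.
#' @param echo_params,ecg_params Class-conditional distribution tables; see
#'   the package defaults in the source for the expected shape.
#' @param ivst_lvpwt_cor Correlation between septal and posterior wall
#'   thickness (default 0.8).
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_patients, lvh_prevalence = 0.462,
                          sex_ratio = 0.532, seed = 1L,
                          ecg_effect_scale = 1, n_noise_features = 5,
                          noise_sd = 1,
                          echo_params = default_echo_params(),
                          ecg_params = default_ecg_params(),
                          ivst_lvpwt_cor = 0.8) {
  stopifnot(n_patients >= 1,
            lvh_prevalence >= 0, lvh_prevalence <= 1,
            sex_ratio >= 0, sex_ratio <= 1,
            ecg_effect_scale >= 0,
            noise_sd > 0, abs(ivst_lvpwt_cor) < 1)
  structure(list(n_patients = as.integer(n_patients),
                 lvh_prevalence = lvh_prevalence, sex_ratio = sex_ratio,
                 seed = as.integer(seed),
                 ecg_effect_scale = ecg_effect_scale,
                 n_noise_features = as.integer(n_noise_features),
                 noise_sd = noise_sd, echo_params = echo_params,
                 ecg_params = ecg_params, ivst_lvpwt_cor = ivst_lvpwt_cor),
            class = "cohort_config")
}

#' Read a generator configuration from YAML or JSON
#'
#' Scalar fields override the [cohort_config()] defaults; distribution
#' tables (`echo_params`, `ecg_params`) cannot be overridden from file.
#'
#' @param path YAML (or JSON) file of scalar config fields.
#' @return A `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("n_patients", "lvh_prevalence", "sex_ratio", "seed",
               "ecg_effect_scale", "n_noise_features", "noise_sd",
               "ivst_lvpwt_cor")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(cohort_config, raw)
}

# truncated-normal draw by redrawing below the floor
rtnorm <- function(n, mean, sd, floor) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < floor)
  guard <- 0
  while (length(bad) > 0 && guard < 100) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < floor]
    guard <- guard + 1
  }
  pmax(x, floor)
  }

draw_echo <- function(n, positive, cfg) {
  ep <- cfg$echo_params
  pick <- function(name, z = NULL) {
    par <- ep[[name]]
    m <- ifelse(positive, par$pos[1], par$neg[1])
    s <- ifelse(positive, par$pos[2], par$neg[2])
    if (is.null(z)) rtnorm(n, m, s, par$floor) else pmax(m + s * z, par$floor)
  }
  # correlated wall thicknesses via a shared latent normal
  rho <- cfg$ivst_lvpwt_cor
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  tibble::tibble(
    IVST_cm = pick("IVST_cm", z1),
    LVID_cm = pick("LVID_cm"),
    LVPWT_cm = pick("LVPWT_cm", z2),
    weight_kg = pick("weight_kg"),
    height_cm = pick("height_cm"))
}

echo_positive <- function(echo, sex) {
  lvmi_val <- lvmi(lv_mass(echo$IVST_cm, echo$LVID_cm, echo$LVPWT_cm),
                   mosteller_bsa(echo$weight_kg, echo$height_cm))
  classify_lvh(sex, lvmi_val)$lvh_positive
}

# Monte Carlo estimate of P(echo-LVH | mixture component), used to calibrate
# the mixture weight so the realized echo prevalence hits the target
calibrate_mixture <- function(cfg, n_cal = 3000) {
  sex <- sample(c("male", "female"), n_cal, replace = TRUE,
                prob = c(cfg$sex_ratio, 1 - cfg$sex_ratio))
  a <- mean(echo_positive(draw_echo(n_cal, rep(TRUE, n_cal), cfg), sex))
  b <- mean(echo_positive(draw_echo(n_cal, rep(FALSE, n_cal), cfg), sex))
  p <- cfg$lvh_prevalence
  if (a == b) {
    w <- p
  } else {
    w <- (p - b) / (a - b)
  }
  if (w < 0 || w > 1) {
    warning(sprintf(
      "target prevalence %.3f outside the achievable range [%.3f, %.3f]; clipping",
      p, min(a, b), max(a, b)), call. = FALSE)
    w <- min(max(w, 0), 1)
  }
  w
}

#' Generate a synthetic patient cohort
#'
#' Draws a fully populated cohort tibble under the model described in
#' [cohort_config()]: a latent LVH mixture component per patient
#' (`lvh_latent`), class-conditional echo dimensions and anthropometrics,
#' the echo-derived ground truth, and class-conditional ECG measurements
#' (conditioned on the echo-derived class). The result passes
#' [validate_cohort()], contains no missing values, and is reproducible
#' given the config seed.
#'
#' @param config A [cohort_config()].
#' @return A cohort tibble including the echo ground-truth columns of
#'   [echo_ground_truth()] and the latent component flag `lvh_latent`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 7))
#' mean(cohort$lvh_positive)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  cfg <- config
  n <- cfg$n_patients
  withr::with_seed(cfg$seed, {
    w <- calibrate_mixture(cfg)
    sex <- sample(c("male", "female"), n, replace = TRUE,
                  prob = c(cfg$sex_ratio, 1 - cfg$sex_ratio))
    latent <- stats::runif(n) < w
    echo <- draw_echo(n, latent, cfg)
    lvh <- echo_positive(echo, sex)

    eff <- cfg$ecg_effect_scale
    ecg <- purrr::imap_dfc(cfg$ecg_params, function(par, name) {
      if (length(par$neg) == 1) {              # Bernoulli flag
        pr <- par$neg + eff * (par$pos - par$neg)
        stats::runif(n) < ifelse(lvh, pr, par$neg)
      } else {
        m <- par$neg[1] + eff * (par$pos[1] - par$neg[1])
        s <- par$neg[2] + eff * (par$pos[2] - par$neg[2])
        rtnorm(n, ifelse(lvh, m, par$neg[1]),
               ifelse(lvh, s, par$neg[2]), par$floor)
      }
    })
    # aVL/aVF wave amplitudes as fractions of the lead's peak-to-peak
    # amplitude: dominance (ppk >= |R|, |S|) holds by construction and the
    # lead keeps a realistic low-voltage tail
    ecg$R_amp_aVL_mV <- ecg$QRS_ppk_aVL_mV * stats::runif(n, 0.50, 0.95)
    ecg$S_amp_aVL_mV <- ecg$QRS_ppk_aVL_mV * stats::runif(n, 0.05, 0.50)
    ecg$R_amp_aVF_mV <- ecg$QRS_ppk_aVF_mV * stats::runif(n, 0.50, 0.95)
    ecg$S_amp_aVF_mV <- ecg$QRS_ppk_aVF_mV * stats::runif(n, 0.05, 0.50)
    noise <- NULL
    if (cfg$n_noise_features > 0) {
      noise <- purrr::map_dfc(seq_len(cfg$n_noise_features), function(i) {
        tibble::tibble(!!sprintf("noise_%02d", i) :=
                         stats::rnorm(n, 0, cfg$noise_sd))
      })
    }
    age <- rtnorm(n, ifelse(lvh, 68.8, 65.8), ifelse(lvh, 12.1, 14.5), 35)
    cohort <- dplyr::bind_cols(
      tibble::tibble(id = sprintf("P%05d", seq_len(n)),
                     age_years = age, sex = sex, lvh_latent = latent),
      ecg, echo)
    if (!is.null(noise)) cohort <- dplyr::bind_cols(cohort, noise)
    echo_ground_truth(validate_cohort(cohort))
  })
}

#' Plant decision-tree labels on a cohort
#'
#' Labels every patient by evaluating `tree` on its features, then flips each
#' label independently with probability `label_noise`. Used for
#' parameter-recovery experiments on the tree learner.
#'
#' @param cohort A cohort tibble containing the tree's features.
#' @param tree An `lvh_tree` (default the packaged CHCM tree).
#' @param label_noise Flip probability in `[0, 1]`.
#' @param seed Seed for the noise flips.
#' @return The cohort with a logical `planted_label` column appended.
#' @export
#' @examples
#' generate_cohort(cohort_config(n_patients = 10, seed = 1)) |>
#'   plant_tree_labels(label_noise = 0.1, seed = 2)
plant_tree_labels <- function(cohort, tree = chcm_tree(), label_noise = 0,
                              seed = 1L) {
  stopifnot(label_noise >= 0, label_noise <= 1)
  labels <- evaluate_tree(tree, cohort, trace = FALSE)$positive
  flips <- withr::with_seed(seed,
                            stats::runif(nrow(cohort)) < label_noise)
  dplyr::mutate(cohort, planted_label = xor(labels, flips))
}
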