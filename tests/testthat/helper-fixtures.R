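# one-row patient record with every criterion input at a benign default;
# override any field by name
ecg_row <- function(...) {
  defaults <- list(
    id = "p1", sex = "male", age_years = 60,
    T_amp_I_mV = 0.2, QRS_ppk_aVL_mV = 0.5, QRS_ppk_aVF_mV = 0.5,
    R_amp_I_mV = 0.5, S_amp_I_mV = 0.2,
    R_amp_II_mV = 0.5, S_amp_II_mV = 0.2,
    R_amp_III_mV = 0.3, S_amp_III_mV = 0.2,
    R_amp_aVR_mV = 0.2, S_amp_aVR_mV = 0.5,
    R_amp_aVL_mV = 0.4, S_amp_aVL_mV = 0.1,
    R_amp_aVF_mV = 0.4, S_amp_aVF_mV = 0.1,
    R_amp_V5_mV = 1.5, R_amp_V6_mV = 1.2,
    S_amp_V1_mV = 0.8, S_amp_V2_mV = 1.0, S_amp_V3_mV = 0.5,
    QRS_dur_ms = 80, QRS_axis_deg = 30,
    intrinsicoid_V5_ms = 40, intrinsicoid_V6_ms = 40,
    P_term_force_ashman = 0.3, ST_dep_mm_j40 = 0,
    ST_strain = FALSE, on_digitalis = FALSE,
    IVST_cm = 1.0, LVID_cm = 4.4, LVPWT_cm = 1.0,
    weight_kg = 78, height_cm = 168)
  mods <- list(...)
  defaults[names(mods)] <- mods
  tibble::as_tibble(defaults)
}

# brute-force oracles, independent of the package's split-search code -------

oracle_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# exhaustive search over every (feature, midpoint) pair by information gain;
# ties: first feature in column order, then smallest threshold
oracle_best_split <- function(X, y) {
  best <- list(feature = NA_character_, threshold = NA_real_, gain = 0)
  n <- length(y)
  parent <- oracle_entropy(c(sum(y), n - sum(y)))
  for (f in names(X)) {
    v <- sort(unique(X[[f]]))
    if (length(v) < 2) next
    for (i in seq_len(length(v) - 1)) {
      thr <- (v[i] + v[i + 1]) / 2
      left <- X[[f]] <= thr
      gain <- parent -
        sum(left) / n * oracle_entropy(c(sum(y[left]), sum(left) - sum(y[left]))) -
        sum(!left) / n * oracle_entropy(c(sum(y[!left]), sum(!left) - sum(y[!left])))
      if (gain > best$gain + 1e-12) {
        best <- list(feature = f, threshold = thr, gain = gain)
      }
    }
  }
  best
}

# features exercised by the planted-recovery experiments
recovery_features <- function(cohort) {
  c("T_amp_I_mV", "QRS_ppk_aVL_mV", "QRS_ppk_aVF_mV",
    grep("^noise_", names(cohort), value = TRUE),
    "R_amp_V5_mV", "QRS_dur_ms")
}
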