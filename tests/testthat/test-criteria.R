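test_that("voltage criteria apply their published thresholds strictly", {
  expect_true(sokolow_avl(1.2)$positive)
  expect_false(sokolow_avl(1.1)$positive)   # strict boundary
  expect_false(sokolow_avl(0)$positive)
  expect_error(sokolow_avl(-0.1), "non-negative")

  r <- cornell("male", 1.5, 1.4)
  expect_equal(r$score, 2.9); expect_true(r$positive)
  expect_false(cornell("female", 1.0, 1.0)$positive)  # 2.0 not > 2.0
  expect_false(cornell("male", 0, 0)$positive)
  expect_error(cornell("x", 1, 1), "male")

  expect_true(dalfo("female", 0.8, 0.7)$positive)     # 1.5 > 1.4
  expect_false(dalfo("male", 0.8, 0.8)$positive)      # 1.6 not > 1.6
  expect_true(dalfo("male", 1.0, 0.7)$positive)

  v <- vdp_cornell("female", 0.5, 1.0, 100)
  expect_equal(v$score, 210); expect_false(v$positive)
  v2 <- vdp_cornell("male", 1.5, 1.5, 90)
  expect_equal(v2$score, 270); expect_true(v2$positive)
  expect_false(vdp_cornell("male", 0, 0, 100)$positive)
  expect_error(vdp_cornell("male", 1, 1, 0), "positive")
})

test_that("Romhilt-Estes awards points per item and calls LVH at 4 points", {
  # precordial voltage alone: 3 points, below the cutoff
  r <- romhilt_estes(ecg_row(R_amp_V5_mV = 3.2))
  expect_equal(r$score, 3); expect_false(r$positive)
  expect_equal(r$pts_voltage, 3L)

  # voltage + prolonged QRS: 4 points, positive
  r2 <- romhilt_estes(ecg_row(R_amp_V5_mV = 3.2, QRS_dur_ms = 95))
  expect_equal(r2$score, 4); expect_true(r2$positive)

  # all six items: 13 points
  r3 <- romhilt_estes(ecg_row(
    P_term_force_ashman = 1.5, R_amp_II_mV = 2.5, ST_strain = TRUE,
    QRS_dur_ms = 95, QRS_axis_deg = -40, intrinsicoid_V5_ms = 55))
  expect_equal(r3$score, 13); expect_true(r3$positive)

  # strain on digitalis earns nothing
  r4 <- romhilt_estes(ecg_row(ST_strain = TRUE, on_digitalis = TRUE))
  expect_equal(r4$pts_strain, 0L)
  r5 <- romhilt_estes(ecg_row(ST_strain = TRUE, on_digitalis = FALSE))
  expect_equal(r5$pts_strain, 3L)

  # the 3-point voltage group is awarded at most once
  r6 <- romhilt_estes(ecg_row(R_amp_V5_mV = 3.5, S_amp_V1_mV = 3.5,
                              R_amp_II_mV = 2.5))
  expect_equal(r6$pts_voltage, 3L)

  expect_error(romhilt_estes(ecg_row()[, 1:5]), "missing required column")
})

test_that("Romhilt-Estes points stay in 0..13 and components sum to the score", {
  cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 9))
  r <- romhilt_estes(cohort)
  expect_true(all(r$score >= 0 & r$score <= 13))
  pts <- dplyr::select(r, dplyr::starts_with("pts_"))
  expect_equal(rowSums(pts), r$score)
  expect_equal(r$positive, r$score >= 4)
})

test_that("raising a contributing amplitude never flips a call to negative", {
  withr::with_seed(31, {
    for (i in 1:100) {
      sex <- sample(c("male", "female"), 1)
      s <- runif(1, 0, 2); r <- runif(1, 0, 2); bump <- runif(1, 0, 1)
      expect_true(cornell(sex, s, r)$positive <=
                    cornell(sex, s + bump, r)$positive)
      expect_true(dalfo(sex, s, r)$positive <=
                    dalfo(sex, s, r + bump)$positive)
      expect_true(sokolow_avl(r)$positive <= sokolow_avl(r + bump)$positive)
      d <- runif(1, 60, 140)
      expect_true(vdp_cornell(sex, r, s, d)$positive <=
                    vdp_cornell(sex, r + bump, s, d)$positive)
    }
  })
})

test_that("a Cornell-positive patient is always Dalfo-positive", {
  withr::with_seed(77, {
    sex <- sample(c("male", "female"), 500, replace = TRUE)
    s <- runif(500, 0, 2.5); r <- runif(500, 0, 2.5)
    cr <- cornell(sex, s, r); da <- dalfo(sex, s, r)
    expect_true(all(da$positive[cr$positive]))
  })
})

test_that("score_criteria runs the battery per patient with a registry", {
  # all-zero amplitudes: every criterion negative
  zero <- ecg_row(
    T_amp_I_mV = 0, QRS_ppk_aVL_mV = 0, QRS_ppk_aVF_mV = 0,
    R_amp_I_mV = 0, S_amp_I_mV = 0, R_amp_II_mV = 0, S_amp_II_mV = 0,
    R_amp_III_mV = 0, S_amp_III_mV = 0, R_amp_aVR_mV = 0, S_amp_aVR_mV = 0,
    R_amp_aVL_mV = 0, S_amp_aVL_mV = 0, R_amp_aVF_mV = 0, S_amp_aVF_mV = 0,
    R_amp_V5_mV = 0, R_amp_V6_mV = 0, S_amp_V1_mV = 0, S_amp_V2_mV = 0,
    S_amp_V3_mV = 0, P_term_force_ashman = 0, intrinsicoid_V5_ms = 0,
    intrinsicoid_V6_ms = 0)
  res <- score_criteria(zero)
  expect_equal(nrow(res), length(lvh_criteria()))
  expect_false(any(res$positive))

  # amplitudes between the Dalfo and Cornell thresholds: only Dalfo fires
  only_dalfo <- ecg_row(sex = "male", S_amp_V3_mV = 1.0, R_amp_aVL_mV = 0.8,
                        QRS_ppk_aVL_mV = 0.9)
  res2 <- score_criteria(only_dalfo)
  expect_equal(res2$criterion[res2$positive], "dalfo")

  # single-criterion registry call
  res3 <- score_criteria(ecg_row(), criteria = "sokolow")
  expect_equal(nrow(res3), 1)

  expect_error(score_criteria(ecg_row(), criteria = "nope"),
               "unknown criterion.*sokolow")
})
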