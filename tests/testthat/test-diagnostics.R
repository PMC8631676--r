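test_that("compare tallies a 2x2 table like a hand count", {
  all_pos <- compare(rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(unclass(all_pos)[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 0L))
  flipped <- compare(c(TRUE, FALSE, TRUE), c(FALSE, TRUE, FALSE))
  expect_equal(flipped$tp + flipped$tn, 0L)

  withr::with_seed(12, {
    pred <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    truth <- sample(c(TRUE, FALSE), 10, replace = TRUE)
    cm <- compare(pred, truth)
    hand <- c(0, 0, 0, 0)
    for (i in 1:10) {
      hand <- hand + c(pred[i] && truth[i], pred[i] && !truth[i],
                       !pred[i] && truth[i], !pred[i] && !truth[i])
    }
    expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), hand)
  })
  expect_error(compare(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("metrics derive correctly from a confusion matrix", {
  m <- metrics_from_cm(confusion_matrix(31, 14, 43, 68))
  expect_equal(round(100 * m$accuracy, 1), 63.5)
  expect_equal(round(100 * m$ppv, 1), 68.9)
  expect_equal(round(100 * m$npv, 1), 61.3)
  expect_equal(round(100 * m$sensitivity, 1), 41.9)
  expect_equal(round(100 * m$specificity, 1), 82.9)

  perfect <- metrics_from_cm(confusion_matrix(1, 0, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$npv, 1)

  degenerate <- metrics_from_cm(confusion_matrix(0, 0, 5, 0))
  expect_equal(degenerate$sensitivity, 0)
  expect_true(is.na(degenerate$ppv))          # absent, not coerced to 0
  expect_match(degenerate$undefined, "ppv")
})

test_that("confusion matrices reconstruct from printed rates bit-exactly", {
  cm <- reconstruct_cm(156, 0.474, 0.42, 0.829)
  expect_equal(c(cm$tp, cm$fp, cm$fn, cm$tn), c(31, 14, 43, 68))
  cm2 <- reconstruct_cm(100, 0, 0.5, 1)
  expect_equal(c(cm2$tp, cm2$fn, cm2$tn), c(0, 0, 100))
  cm3 <- reconstruct_cm(10, 0.5, 1, 1)
  expect_equal(c(cm3$tp, cm3$fp, cm3$fn, cm3$tn), c(5, 0, 0, 5))
})

test_that("rate identities hold and invert", {
  # agreement to the printed three-decimal precision
  expect_equal(round(implied_prevalence(0.743, 0.687, 0.538), 3), 0.329)
  expect_equal(round(implied_prevalence(0.611, 0.646, 0.611), 3), 0.476)
  expect_equal(accuracy_from_rates(1, 1, 0.3), 1)
  expect_equal(round(accuracy_from_rates(0.743, 0.687, 0.329), 3), 0.705)
  expect_equal(round(npv_from_rates(0.743, 0.687, 0.329), 3), 0.845)
  expect_error(implied_prevalence(0, 0.5, 0.5), "degenerate")

  # forward-backward inversion to numerical precision
  withr::with_seed(41, {
    for (i in 1:200) {
      p <- runif(1, 0.05, 0.95); se <- runif(1, 0.05, 1); sp <- runif(1, 0, 0.95)
      ppv <- se * p / (se * p + (1 - sp) * (1 - p))
      expect_equal(implied_prevalence(se, sp, ppv), p, tolerance = 1e-12)
    }
  })

  # the accuracy identity is exact for any integer confusion matrix
  withr::with_seed(42, {
    for (i in 1:100) {
      cells <- rpois(4, 20) + c(1, 0, 1, 0)
      m <- metrics_from_cm(do.call(confusion_matrix, as.list(cells)))
      expect_equal(m$accuracy,
                   m$sensitivity * m$prevalence +
                     m$specificity * (1 - m$prevalence))
    }
  })
})

test_that("binomial intervals match the exact test and bracket the estimate", {
  expect_equal(binomial_ci(0, 20)[["lower"]], 0)
  expect_equal(binomial_ci(20, 20)[["upper"]], 1)

  # independent oracle: stats::binom.test computes Clopper-Pearson
  for (case in list(c(99, 156), c(3, 10), c(0, 7), c(45, 45))) {
    ours <- binomial_ci(case[1], case[2], method = "clopper_pearson")
    ref <- stats::binom.test(case[1], case[2])$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-12)
  }

  # independent oracle: prop.test without continuity correction is Wilson
  for (case in list(c(99, 156), c(3, 10), c(40, 45))) {
    ours <- binomial_ci(case[1], case[2], method = "wilson")
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
  }

  # Clopper-Pearson contains the point estimate everywhere and is at least
  # as wide as Wilson for interior counts (at k = 0 or k = n the one-sided
  # exact interval can be marginally narrower)
  grid <- tidyr::expand_grid(n = c(10, 50, 156), k_frac = c(0, 0.25, 0.5, 0.9, 1))
  for (i in seq_len(nrow(grid))) {
    n <- grid$n[i]; k <- round(grid$k_frac[i] * n)
    cp <- binomial_ci(k, n, "clopper_pearson")
    wi <- binomial_ci(k, n, "wilson")
    expect_lte(cp[["lower"]], k / n + 1e-12)
    expect_gte(cp[["upper"]], k / n - 1e-12)
    if (k > 0 && k < n) expect_gte(diff(cp), diff(wi) - 1e-12)
  }
  expect_error(binomial_ci(5, 0), "n >= 1")
})

test_that("reconstructed matrices return the input rates within rounding", {
  withr::with_seed(43, {
    for (i in 1:50) {
      n <- sample(50:400, 1)
      p <- runif(1, 0.1, 0.9); se <- runif(1); sp <- runif(1)
      cm <- reconstruct_cm(n, p, se, sp)
      m <- metrics_from_cm(cm)
      cases <- cm$tp + cm$fn; controls <- cm$fp + cm$tn
      if (cases > 0) expect_lte(abs(m$sensitivity - se), 0.5 / cases)
      if (controls > 0) expect_lte(abs(m$specificity - sp), 0.5 / controls)
    }
  })
})

test_that("criterion evaluation reports a comparison table with a reference", {
  cohort <- generate_cohort(cohort_config(n_patients = 250, seed = 17))
  ev <- evaluate_criteria(cohort, criteria = c("sokolow", "dalfo", "chcm"),
                          reference = "chcm")
  expect_setequal(ev$criterion, c("sokolow", "dalfo", "chcm"))
  expect_equal(ev$delta_accuracy[ev$criterion == "chcm"], 0)
  expect_true(all(c("n_variables", "accuracy_lo", "accuracy_hi", "ppv",
                    "npv") %in% names(ev)))
  expect_s3_class(autoplot(ev), "ggplot")

  # report writer round-trips the table
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(ev, path)
  back <- readr::read_csv(path, show_col_types = FALSE)
  expect_equal(back$accuracy, ev$accuracy)
  txt <- withr::local_tempfile(fileext = ".txt")
  write_report(ev, txt, format = "text")
  expect_match(readLines(txt)[1], "reference: chcm")
})
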