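#' Confusion matrix from counts or paired calls
#'
#' @param tp,fp,fn,tn Non-negative integer cell counts, total >= 1.
#' @return A `confusion_matrix` list with fields `tp`, `fp`, `fn`, `tn`.
#' @export
#' @examples
#' confusion_matrix(31, 14, 43, 68)
confusion_matrix <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(cells < 0) || any(cells != round(cells)) || sum(cells) < 1) {
    stop("confusion_matrix: cells must be non-negative integers, total >= 1",
         call. = FALSE)
  }
  structure(as.list(as.integer(cells)), names = names(cells),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              truth = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' @rdname confusion_matrix
#' @param predictions,truth Equal-length logical vectors; `truth` is the
#'   reference standard (echo-LVH).
#' @export
compare <- function(predictions, truth) {
  if (length(predictions) != length(truth) || length(truth) < 1) {
    stop("compare: predictions and truth must have equal length >= 1",
         call. = FALSE)
  }
  if (any(is.na(predictions)) || any(is.na(truth))) {
    stop("compare: missing values are not allowed", call. = FALSE)
  }
  confusion_matrix(tp = sum(predictions & truth),
                   fp = sum(predictions & !truth),
                   fn = sum(!predictions & truth),
                   tn = sum(!predictions & !truth))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Diagnostic metrics from a confusion matrix
#'
#' Computes accuracy, sensitivity, specificity, predictive values and
#' prevalence, with a 95% confidence interval on the accuracy. Ratios whose
#' denominator is zero are reported as `NA` (never coerced to 0 or 1) and
#' named, with the reason, in the `undefined` column.
#'
#' @param cm A [confusion_matrix()].
#' @param ci_method `"clopper_pearson"` (default) or `"wilson"`.
#' @param level Confidence level for the accuracy interval.
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `n`, `prevalence`,
#'   `accuracy`, `accuracy_lo`, `accuracy_hi`, `sensitivity`, `specificity`,
#'   `ppv`, `npv`, `undefined`.
#' @export
#' @examples
#' metrics_from_cm(confusion_matrix(31, 14, 43, 68))
metrics_from_cm <- function(cm, ci_method = c("clopper_pearson", "wilson"),
                            level = 0.95) {
  stopifnot(inherits(cm, "confusion_matrix"))
  ci_method <- match.arg(ci_method)
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  undefined <- character()
  ratio <- function(num, den, what) {
    if (den == 0) {
      undefined <<- c(undefined, sprintf("%s (denominator 0)", what))
      NA_real_
    } else num / den
  }
  se <- ratio(cm$tp, cm$tp + cm$fn, "sensitivity")
  sp <- ratio(cm$tn, cm$tn + cm$fp, "specificity")
  ppv <- ratio(cm$tp, cm$tp + cm$fp, "ppv")
  npv <- ratio(cm$tn, cm$tn + cm$fn, "npv")
  acc <- (cm$tp + cm$tn) / n
  ci <- binomial_ci(cm$tp + cm$tn, n, method = ci_method, level = level)
  tibble::tibble(
    tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn, n = n,
    prevalence = (cm$tp + cm$fn) / n,
    accuracy = acc, accuracy_lo = ci[1], accuracy_hi = ci[2],
    sensitivity = se, specificity = sp, ppv = ppv, npv = npv,
    undefined = paste(undefined, collapse = "; "))
}

#' Reconstruct a confusion matrix from printed summary rates
#'
#' Inverts the usual reporting direction: given a cohort size, prevalence,
#' sensitivity and specificity, rebuilds the integer 2x2 table. Rounding is
#' half-away-from-zero, applied in a fixed order (cases first, then
#' tp and tn) so the reconstruction is bit-exact and reproducible.
#'
#' @param n Cohort size (>= 1).
#' @param prevalence,sensitivity,specificity Fractions in `[0, 1]`.
#' @return A [confusion_matrix()].
#' @export
#' @examples
#' # external-validation cohort: n = 156, prevalence 47.4%, Se 42%, Sp 82.9%
#' reconstruct_cm(156, 0.474, 0.42, 0.829)
reconstruct_cm <- function(n, prevalence, sensitivity, specificity) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  cases <- round_half_away(prevalence * n)
  controls <- n - cases
  tp <- round_half_away(sensitivity * cases)
  tn <- round_half_away(specificity * controls)
  confusion_matrix(tp = tp, fp = controls - tn, fn = cases - tp, tn = tn)
}

#' Prevalence implied by sensitivity, specificity and PPV
#'
#' Inverts the Bayes identity
#' `PPV = Se p / (Se p + (1 - Sp)(1 - p))` for the prevalence `p`:
#' `odds = PPV (1 - Sp) / (Se (1 - PPV))`, `p = odds / (1 + odds)`.
#' Useful for checking the internal consistency of published
#' diagnostic-performance tables.
#'
#' @param sensitivity,specificity,ppv Fractions.
#' @return The implied prevalence.
#' @export
#' @examples
#' implied_prevalence(0.743, 0.687, 0.538)  # ~0.329
implied_prevalence <- function(sensitivity, specificity, ppv) {
  num <- ppv * (1 - specificity)
  den <- sensitivity * (1 - ppv)
  if (den <= 0) {
    if (num > 0) {
      stop("implied_prevalence: degenerate combination (Se*(1-PPV) = 0 with a positive numerator)",
           call. = FALSE)
    }
    return(if (ppv == 0) 0 else NA_real_)
  }
  odds <- num / den
  odds / (1 + odds)
}

#' Accuracy and NPV from sensitivity, specificity and prevalence
#'
#' Standard rate identities: `accuracy = Se p + Sp (1 - p)` and
#' `NPV = Sp (1 - p) / (Sp (1 - p) + (1 - Se) p)`.
#'
#' @inheritParams implied_prevalence
#' @param prevalence Fraction in `[0, 1]`.
#' @return The accuracy / NPV as a fraction.
#' @export
#' @examples
#' accuracy_from_rates(0.743, 0.687, 0.329)  # ~0.705
#' npv_from_rates(0.743, 0.687, 0.329)       # ~0.845
accuracy_from_rates <- function(sensitivity, specificity, prevalence) {
  stopifnot(prevalence >= 0, prevalence <= 1)
  sensitivity * prevalence + specificity * (1 - prevalence)
}

#' @rdname accuracy_from_rates
#' @export
npv_from_rates <- function(sensitivity, specificity, prevalence) {
  den <- specificity * (1 - prevalence) + (1 - sensitivity) * prevalence
  if (den == 0) {
    stop("npv_from_rates: undefined (no predicted negatives)", call. = FALSE)
  }
  specificity * (1 - prevalence) / den
}

#' Binomial confidence interval
#'
#' Exact Clopper-Pearson interval via beta quantiles
#' (`lower = qbeta(a/2, s, n-s+1)`, `upper = qbeta(1-a/2, s+1, n-s)`, with
#' the conventional 0 and 1 endpoints at s = 0 and s = n), or the Wilson
#' score interval.
#'
#' @param successes,n Counts, `0 <= successes <= n`, `n >= 1`.
#' @param method `"clopper_pearson"` or `"wilson"`.
#' @param level Confidence level (default 0.95).
#' @return Numeric `c(lower, upper)`.
#' @export
#' @examples
#' binomial_ci(99, 156)
binomial_ci <- function(successes, n, method = c("clopper_pearson", "wilson"),
                        level = 0.95) {
  method <- match.arg(method)
  if (n < 1 || successes < 0 || successes > n) {
    stop("binomial_ci: need 0 <= successes <= n with n >= 1", call. = FALSE)
  }
  alpha <- 1 - level
  if (method == "clopper_pearson") {
    lower <- if (successes == 0) 0 else
      stats::qbeta(alpha / 2, successes, n - successes + 1)
    upper <- if (successes == n) 1 else
      stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    phat <- successes / n
    denom <- 1 + z^2 / n
    center <- (phat + z^2 / (2 * n)) / denom
    half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
    lower <- max(0, center - half)
    upper <- min(1, center + half)
  }
  c(lower = lower, upper = upper)
}

# number of distinct ECG measurements each criterion consumes
criterion_n_variables <- function() {
  c(sokolow = 1, cornell = 2, dalfo = 2, vdp = 3, romhilt = 6, chcm = 3)
}

#' Evaluate ECG criteria against the echo reference standard
#'
#' Scores the requested criteria on a cohort, compares every call with the
#' echo-derived LVH ground truth, and assembles a diagnostic-performance
#' report (accuracy with CI, sensitivity, specificity, PPV, NPV, and the
#' accuracy difference against a reference criterion) in the conventional
#' comparison-table layout.
#'
#' @inheritParams score_criteria
#' @param reference Criterion whose accuracy anchors `delta_accuracy`.
#' @param ci_method Passed to [metrics_from_cm()].
#' @param truth Optional logical column name holding the ground truth;
#'   when `NULL` the truth is computed with [echo_ground_truth()].
#' @return A tibble of class `lvh_evaluation`, one row per criterion.
#' @export
#' @examples
#' generate_cohort(cohort_config(n_patients = 150, seed = 1)) |>
#'   evaluate_criteria(criteria = c("dalfo", "chcm"), reference = "chcm")
evaluate_criteria <- function(cohort, criteria = lvh_criteria(),
                              reference = "chcm",
                              ci_method = c("clopper_pearson", "wilson"),
                              truth = NULL) {
  ci_method <- match.arg(ci_method)
  if (!reference %in% criteria) criteria <- c(reference, criteria)
  if (is.null(truth)) {
    gt <- echo_ground_truth(cohort)$lvh_positive
  } else {
    if (!truth %in% names(cohort)) {
      stop("evaluate_criteria: truth column '", truth, "' not found",
           call. = FALSE)
    }
    gt <- cohort[[truth]]
    if (!is.logical(gt)) gt <- as.character(gt) == "positive"
  }
  scores <- score_criteria(cohort, criteria)
  nv <- criterion_n_variables()
  rows <- purrr::map_dfr(criteria, function(name) {
    pred <- scores$positive[scores$criterion == name]
    dplyr::bind_cols(
      tibble::tibble(criterion = name,
                     n_variables = unname(nv[name])),
      metrics_from_cm(compare(pred, gt), ci_method = ci_method))
  })
  ref_acc <- rows$accuracy[rows$criterion == reference][1]
  out <- rows |>
    dplyr::mutate(delta_accuracy = .data$accuracy - ref_acc,
                  .after = "n_variables")
  class(out) <- c("lvh_evaluation", class(out))
  attr(out, "reference") <- reference
  out
}

#' Plot a diagnostic-performance comparison
#'
#' Point-range plot of per-criterion accuracy with its confidence interval,
#' plus sensitivity and specificity markers.
#'
#' @param object An `lvh_evaluation` from [evaluate_criteria()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.lvh_evaluation <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "rate", values_to = "value")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = stats::reorder(.data$criterion,
                                                  .data$accuracy))) +
    ggplot2::geom_pointrange(ggplot2::aes(y = .data$accuracy,
                                          ymin = .data$accuracy_lo,
                                          ymax = .data$accuracy_hi)) +
    ggplot2::geom_point(data = long,
                        ggplot2::aes(y = .data$value, shape = .data$rate),
                        color = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "proportion",
                  shape = NULL,
                  title = "Diagnostic performance vs echo-LVH") +
    ggplot2::theme_minimal()
}

#' Write an evaluation report
#'
#' Writes the per-criterion metrics table as CSV, or as an aligned
#' human-readable text table when `format = "text"`.
#'
#' @param evaluation An `lvh_evaluation`.
#' @param path Output file.
#' @param format `"csv"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(evaluation, path, format = c("csv", "text")) {
  format <- match.arg(format)
  if (format == "csv") {
    readr::write_csv(evaluation, path, progress = FALSE)
  } else {
    fmt_pct <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", 100 * x))
    lines <- c(
      sprintf("Diagnostic performance vs echo-LVH (reference: %s)",
              attr(evaluation, "reference") %||% "none"),
      sprintf("%-10s %4s %8s %22s %6s %6s %6s %6s",
              "criterion", "#var", "dAcc", "accuracy (CI95%)", "Se", "Sp",
              "PPV", "NPV"),
      purrr::pmap_chr(evaluation, function(criterion, n_variables,
                                           delta_accuracy, accuracy,
                                           accuracy_lo, accuracy_hi,
                                           sensitivity, specificity, ppv,
                                           npv, ...) {
        sprintf("%-10s %4d %8s %22s %6s %6s %6s %6s",
                criterion, n_variables, fmt_pct(delta_accuracy),
                sprintf("%s (%s-%s)", fmt_pct(accuracy), fmt_pct(accuracy_lo),
                        fmt_pct(accuracy_hi)),
                fmt_pct(sensitivity), fmt_pct(specificity), fmt_pct(ppv),
                fmt_pct(npv))
      }))
    writeLines(lines, path)
  }
  invisible(path)
}
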