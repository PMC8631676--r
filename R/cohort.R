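#' Read a patient cohort from CSV or JSON
#'
#' Reads a tabular cohort (one record per patient) and validates it against
#' the canonical schema (see [cohort_schema()]). Canonical numeric columns are
#' parsed as doubles, logical flag columns as logicals, and `sex` is
#' normalized from the documented aliases (`"M"`, `"F"`, `"male"`, `"female"`,
#' case-insensitive). Columns outside the schema are carried through
#' untouched. Validation failures name the offending column (and row where
#' applicable).
#'
#' @param path Path to the file.
#' @param format `"csv"` (RFC-4180, header row required, UTF-8) or `"json"`
#'   (array of objects). Guessed from the file extension when omitted.
#' @param require Character vector of columns that must be present with no
#'   missing values (e.g. `schema_requirements()$chcm` via a criterion name),
#'   or `NULL` to only validate the columns actually present.
#' @return A tibble, one row per patient.
#' @export
#' @examples
#' path <- tempfile(fileext = ".csv")
#' write_cohort(generate_cohort(cohort_config(n_patients = 5, seed = 1)), path)
#' read_cohort(path)
read_cohort <- function(path, format = c("auto", "csv", "json"),
                        require = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "csv") {
    raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE, show_col_types = FALSE)
  } else {
    obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
    if (length(obj) == 0) obj <- data.frame()
    raw <- tibble::as_tibble(obj)
  }
  cohort <- coerce_schema_types(raw)
  # non-schema columns are carried through with guessed types
  known <- cohort_schema()$column
  for (col in setdiff(names(cohort), known)) {
    if (is.character(cohort[[col]])) {
      cohort[[col]] <- utils::type.convert(cohort[[col]], as.is = TRUE,
                                           na.strings = c("NA", ""))
    }
  }
  validate_cohort(cohort, require = require)
}

coerce_schema_types <- function(raw) {
  schema <- cohort_schema()
  out <- raw
  for (i in seq_len(nrow(schema))) {
    col <- schema$column[i]
    if (!col %in% names(out)) next
    x <- out[[col]]
    if (schema$type[i] == "numeric" && !is.numeric(x)) {
      parsed <- suppressWarnings(as.numeric(x))
      bad <- which(!is.na(x) & x != "" & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("parse error: non-numeric value '%s' in column '%s' (row %s)",
                     x[bad[1]], col, bad[1]), call. = FALSE)
      }
      parsed[!is.na(x) & x == ""] <- NA_real_
      out[[col]] <- parsed
    } else if (schema$type[i] == "logical" && !is.logical(x)) {
      key <- toupper(trimws(as.character(x)))
      parsed <- dplyr::case_when(
        key %in% c("TRUE", "T", "1") ~ TRUE,
        key %in% c("FALSE", "F", "0") ~ FALSE,
        .default = NA
      )
      bad <- which(!is.na(x) & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("parse error: non-logical value '%s' in column '%s' (row %s)",
                     x[bad[1]], col, bad[1]), call. = FALSE)
      }
      out[[col]] <- parsed
    } else if (schema$type[i] == "character" && !is.character(x)) {
      out[[col]] <- as.character(x)
    }
  }
  if ("sex" %in% names(out)) out$sex <- normalize_sex(out$sex)
  out
}

#' Validate a cohort tibble against the canonical schema
#'
#' Checks type and range invariants for every canonical column present:
#' amplitudes finite, S-wave magnitudes and peak-to-peak amplitudes
#' non-negative, peak-to-peak QRS at least as large as the R and S magnitudes
#' of the same lead when all are present, positive durations and echo
#' dimensions, valid sex levels, and unique patient ids. Errors name the
#' violating column and first offending row.
#'
#' @inheritParams read_cohort
#' @param cohort A cohort tibble.
#' @return The cohort, invisibly validated (returned for piping).
#' @export
validate_cohort <- function(cohort, require = NULL) {
  stopifnot(is.data.frame(cohort))
  cohort <- tibble::as_tibble(cohort)
  fail <- function(col, rows, what) {
    stop(sprintf("invalid cohort: column '%s' %s (row %s)", col, what, rows[1]),
         call. = FALSE)
  }
  schema <- cohort_schema()
  present <- intersect(schema$column, names(cohort))
  for (col in present) {
    x <- cohort[[col]]
    type <- schema$type[schema$column == col]
    if (type == "numeric") {
      if (!is.numeric(x)) stop(sprintf("invalid cohort: column '%s' is not numeric", col), call. = FALSE)
      bad <- which(!is.na(x) & !is.finite(x))
      if (length(bad) > 0) fail(col, bad, "contains a non-finite value")
    }
  }
  nonneg <- grep("^(S_amp_|QRS_ppk_)", present, value = TRUE)
  nonneg <- c(nonneg, intersect(c("QRS_dur_ms", "P_term_force_ashman",
                                  "intrinsicoid_V5_ms", "intrinsicoid_V6_ms"),
                                present))
  for (col in nonneg) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] < 0)
    if (length(bad) > 0) fail(col, bad, "must be non-negative")
  }
  for (col in intersect(c("QRS_dur_ms", "IVST_cm", "LVID_cm", "LVPWT_cm",
                          "weight_kg", "height_cm"), present)) {
    bad <- which(!is.na(cohort[[col]]) & cohort[[col]] <= 0)
    if (length(bad) > 0) fail(col, bad, "must be positive")
  }
  # peak-to-peak QRS dominates the individual wave magnitudes in its lead
  for (lead in c("aVL", "aVF")) {
    ppk <- sprintf("QRS_ppk_%s_mV", lead)
    r <- sprintf("R_amp_%s_mV", lead)
    s <- sprintf("S_amp_%s_mV", lead)
    if (all(c(ppk, r, s) %in% present)) {
      ok <- is.na(cohort[[ppk]]) | is.na(cohort[[r]]) | is.na(cohort[[s]]) |
        (cohort[[ppk]] >= abs(cohort[[r]]) - 1e-9 &
           cohort[[ppk]] >= abs(cohort[[s]]) - 1e-9)
      if (!all(ok)) fail(ppk, which(!ok), "must be >= |R| and |S| amplitudes of the same lead")
    }
  }
  if ("sex" %in% present) {
    known <- is.na(cohort$sex) | cohort$sex %in% c("male", "female")
    if (!all(known)) fail("sex", which(!known), "must be \"male\" or \"female\"")
  }
  if ("id" %in% present && nrow(cohort) > 0) {
    dup <- which(duplicated(cohort$id))
    if (length(dup) > 0) fail("id", dup, "contains a duplicate patient id")
  }
  if (!is.null(require)) {
    if (length(require) == 1 && require %in% names(schema_requirements())) {
      require <- schema_requirements()[[require]]
    }
    require_features(cohort, require, context = "cohort validation")
  }
  cohort
}

#' Write a cohort to CSV or JSON
#'
#' The written file round-trips through [read_cohort()] field-for-field;
#' numeric values are serialized at full double precision. Optional columns
#' that are absent from the tibble are simply omitted from the file.
#'
#' @param cohort A cohort tibble.
#' @param path Output path.
#' @param format `"csv"` or `"json"`; guessed from the extension when omitted.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  cohort <- validate_cohort(cohort)
  ok <- tryCatch({
    if (format == "csv") {
      readr::write_csv(cohort, path, progress = FALSE)
    } else {
      jsonlite::write_json(cohort, path, dataframe = "rows", digits = NA,
                           auto_unbox = TRUE, na = "null")
    }
    TRUE
  }, error = function(e) {
    stop("I/O error writing cohort to ", path, ": ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(path)
}
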