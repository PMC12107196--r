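#' Categorize a Charlson Comorbidity Index score
#'
#' Cut-offs: 0 = none, 1-2 = mild, 3-4 = moderate, >= 5 = severe.
#'
#' @param score nonnegative integer vector of CCI scores.
#' @return factor with levels `none < mild < moderate < severe`.
#' @export
categorize_cci <- function(score) {
  if (any(score < 0, na.rm = TRUE)) {
    abort("CCI score must be nonnegative", "edrisk_domain_error")
  }
  cut(score, breaks = c(-Inf, 0, 2, 4, Inf),
      labels = c("none", "mild", "moderate", "severe"))
}

#' Categorize vital signs
#'
#' Systolic blood pressure: hypotension < 90, normal 90-130, hypertension
#' > 130 mm Hg. Pulse: bradycardia < 60, normal 60-90, tachycardia > 90 bpm.
#' Temperature: hypothermia < 35.5, normal 35.5-37.5, hyperthermia > 37.5 degC.
#' The written ranges are inclusive at both ends, so boundary values are
#' "normal"; only the strict inequalities fall outside.
#'
#' @param sbp,pulse,temp numeric vectors (equal length).
#' @param bounds plausibility bounds; values outside raise a validation error.
#' @return data frame with factor columns `sbp_cat`, `pulse_cat`, `temp_cat`
#'   (levels ordered `normal`, low, high so that `normal` is the reference).
#' @export
categorize_vitals <- function(sbp, pulse, temp,
                              bounds = list(sbp = c(40, 300),
                                            pulse = c(20, 250),
                                            temp = c(30, 45))) {
  check <- function(x, b, what) {
    if (any(!is.na(x) & (x < b[1] | x > b[2]))) {
      abort(sprintf("%s outside plausible range [%g, %g]", what, b[1], b[2]),
            "edrisk_validation_error")
    }
  }
  check(sbp, bounds$sbp, "sbp"); check(pulse, bounds$pulse, "pulse")
  check(temp, bounds$temp, "temp")
  band <- function(x, lo, hi, low_lab, high_lab) {
    factor(ifelse(x < lo, low_lab, ifelse(x > hi, high_lab, "normal")),
           levels = c("normal", low_lab, high_lab))
  }
  data.frame(
    sbp_cat = band(sbp, 90, 130, "hypotension", "hypertension"),
    pulse_cat = band(pulse, 60, 90, "bradycardia", "tachycardia"),
    temp_cat = band(temp, 35.5, 37.5, "hypothermia", "hyperthermia")
  )
}

#' Add category columns to presentation records
#'
#' Adds `sbp_cat`, `pulse_cat`, `temp_cat` and `cci_cat`, and normalises the
#' ICD-10 code (upper case, whitespace stripped).
#'
#' @param records registry data frame.
#' @inheritParams categorize_vitals
#' @return the records with four additional factor columns.
#' @export
categorize_records <- function(records, bounds = NULL) {
  records$icd10 <- toupper(trimws(records$icd10))
  vit <- if (is.null(bounds)) {
    categorize_vitals(records$sbp, records$pulse, records$temp)
  } else {
    categorize_vitals(records$sbp, records$pulse, records$temp, bounds)
  }
  records$sbp_cat <- vit$sbp_cat
  records$pulse_cat <- vit$pulse_cat
  records$temp_cat <- vit$temp_cat
  records$cci_cat <- categorize_cci(records$cci)
  records
}

#' Impute trivially missing fields
#'
#' Records missing the primary diagnosis code or the admission outcome are
#' dropped (reason "no primary diagnosis"). Remaining missing numeric fields
#' are filled with the column mean or median of the observed values; missing
#' categorical demographics (`sex`, `ethnicity`) with the modal category.
#' Non-missing values are never altered.
#'
#' @param records registry data frame.
#' @param numeric_strategy `"mean"` or `"median"`.
#' @param categorical_strategy only `"mode"` is supported.
#' @return list with `records` (complete), `log` (one row per imputed cell:
#'   id, column, value) and `dropped` (one row per dropped record: id, reason).
#' @export
impute_missing <- function(records, numeric_strategy = c("mean", "median"),
                           categorical_strategy = "mode") {
  numeric_strategy <- match.arg(numeric_strategy)
  stopifnot(categorical_strategy == "mode")
  drop <- is.na(records$icd10) | is.na(records$admitted)
  dropped <- data.frame(id = records$id[drop],
                        reason = rep("no primary diagnosis", sum(drop)),
                        stringsAsFactors = FALSE)
  rec <- records[!drop, , drop = FALSE]
  log <- list()
  fill_num <- function(x) {
    if (numeric_strategy == "mean") mean(x, na.rm = TRUE)
    else stats::median(x, na.rm = TRUE)
  }
  num_cols <- c("age", "sbp", "pulse", "temp", "cci", "prior_ed", "prior_inpt",
                "prior_surg", "prior_icu", "prior_hd", "prior_ica",
                "prior_infect")
  for (col in intersect(num_cols, names(rec))) {
    miss <- which(is.na(rec[[col]]))
    if (length(miss)) {
      v <- fill_num(rec[[col]])
      log[[col]] <- data.frame(id = rec$id[miss], column = col,
                               value = as.character(v), stringsAsFactors = FALSE)
      rec[[col]][miss] <- v
    }
  }
  for (col in c("sex", "ethnicity")) {
    miss <- which(is.na(rec[[col]]))
    if (length(miss)) {
      tab <- table(rec[[col]])
      mode_val <- names(tab)[which.max(tab)]
      log[[col]] <- data.frame(id = rec$id[miss], column = col,
                               value = mode_val, stringsAsFactors = FALSE)
      rec[[col]][miss] <- mode_val
    }
  }
  log <- if (length(log)) do.call(rbind, c(log, make.row.names = FALSE)) else {
    data.frame(id = character(), column = character(), value = character(),
               stringsAsFactors = FALSE)
  }
  list(records = rec, log = log, dropped = dropped)
}

#' Exclude low-frequency diagnosis codes
#'
#' Removes presentations whose primary ICD-10 code occurs fewer than
#' `min_count` times, to keep per-code admission-risk estimates stable. The
#' default of 15 mirrors the primary analysis; 10 is the usual sensitivity
#' setting.
#'
#' @param records registry data frame (codes already normalised).
#' @param min_count minimum presentations per retained code (>= 1).
#' @return list with `records` (retained rows) and `report`, a
#'   `filter_report` list: `min_count`, `n_records_in`, `n_records_kept`,
#'   `n_records_excluded`, `excluded_codes`.
#' @export
filter_low_frequency_codes <- function(records, min_count = 15L) {
  if (min_count < 1) abort("min_count must be >= 1", "edrisk_domain_error")
  counts <- table(records$icd10)
  excluded_codes <- sort(names(counts)[counts < min_count])
  keep <- !(records$icd10 %in% excluded_codes)
  report <- structure(list(
    min_count = as.integer(min_count),
    n_records_in = nrow(records),
    n_records_kept = sum(keep),
    n_records_excluded = sum(!keep),
    excluded_codes = excluded_codes
  ), class = "filter_report")
  list(records = records[keep, , drop = FALSE], report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Low-frequency code filter (min_count = %d): kept %d / %d records; %d excluded across %d codes\n",
    x$min_count, x$n_records_kept, x$n_records_in, x$n_records_excluded,
    length(x$excluded_codes)))
  invisible(x)
}

#' Preprocess a raw registry
#'
#' Convenience wrapper: drop records without a diagnosis or disposition,
#' impute trivially missing fields, categorize vitals and comorbidity, and
#' apply the low-frequency code filter.
#'
#' @inheritParams impute_missing
#' @inheritParams filter_low_frequency_codes
#' @return list with `records`, `filter_report`, `imputation_log`, `dropped`.
#' @export
preprocess_registry <- function(records, min_count = 15L,
                                numeric_strategy = "mean") {
  imp <- impute_missing(records, numeric_strategy = numeric_strategy)
  rec <- categorize_records(imp$records)
  flt <- filter_low_frequency_codes(rec, min_count)
  list(records = flt$records, filter_report = flt$report,
       imputation_log = imp$log, dropped = imp$dropped)
}
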