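#' @keywords internal
"_PACKAGE"

# Record schema ---------------------------------------------------------
#
# A patient record is a named list (or one data.frame row) with:
#   patient_id            character
#   age                   years, integer-ish >= 18
#   sex                   "male" | "female"
#   bmi                   kg/m^2, > 0
#   alcohol_over_14       logical (max weekly intake in prior 6 months > 14 units)
#   metabolic_syndrome    logical
#   alt, alp, ggt         U/L
#   bilirubin_total       µmol/L
#   albumin               g/L
#   ast                   U/L        (optional at request; needed for scores)
#   platelets             10^9/L     (optional at request; needed for scores)
# optional reflex/screen analytes (NA when not measured):
#   transferrin_saturation %          a1at g/L
#   hbv_positive, hcv_positive, autoantibody_positive   logical
#   crp mg/L   caeruloplasmin g/L
#   direct_bilirubin µmol/L   haptoglobin g/L
#   ha, piiinp, timp1      ELF analyte concentrations (assay units, > 0)

#' Column names of the patient record schema
#'
#' @return Character vector of all recognised record fields, required first.
#' @export
record_fields <- function() {
  c("patient_id", "age", "sex", "bmi", "alcohol_over_14", "metabolic_syndrome",
    "alt", "alp", "ggt", "bilirubin_total", "albumin", "ast", "platelets",
    "transferrin_saturation", "a1at", "hbv_positive", "hcv_positive",
    "autoantibody_positive", "crp", "caeruloplasmin",
    "direct_bilirubin", "haptoglobin", "ha", "piiinp", "timp1")
}

req_num_fields <- c("age", "bmi", "alt", "alp", "ggt", "bilirubin_total", "albumin")
opt_num_fields <- c("ast", "platelets", "transferrin_saturation", "a1at",
                    "crp", "caeruloplasmin", "direct_bilirubin", "haptoglobin",
                    "ha", "piiinp", "timp1")
logical_fields <- c("alcohol_over_14", "metabolic_syndrome",
                    "hbv_positive", "hcv_positive", "autoantibody_positive")

has_value <- function(x) !is.null(x) && length(x) == 1L && !is.na(x)

#' Validate one patient record
#'
#' Enforces the record schema: required demographics and first-line analytes
#' present, numeric values finite and non-negative, age at least 18 (an
#' adult primary-care pathway), BMI positive, sex one of male/female, and
#' direct bilirubin never exceeding total. Optional analytes may be `NA`
#' (not measured) but when present must be valid.
#'
#' @param record Named list or single data.frame row.
#' @return The record as a named list, with logical fields coerced.
#'   Validation failure signals a condition of class `ilft_validation_error`
#'   whose message names the offending field.
#' @export
validate_record <- function(record) {
  rec <- as.list(record)
  fail <- function(field, why) {
    stop(structure(
      class = c("ilft_validation_error", "error", "condition"),
      list(message = sprintf("invalid record%s: field '%s' %s",
                             if (has_value(rec$patient_id))
                               paste0(" '", rec$patient_id, "'") else "",
                             field, why),
           call = NULL, field = field)))
  }
  for (f in c("patient_id", "sex", req_num_fields)) {
    if (!has_value(rec[[f]])) fail(f, "is missing")
  }
  if (!rec$sex %in% c("male", "female")) fail("sex", "must be 'male' or 'female'")
  for (f in req_num_fields) {
    v <- rec[[f]]
    if (!is.numeric(v) || !is.finite(v)) fail(f, "must be a finite number")
    if (v < 0) fail(f, "must be non-negative")
  }
  if (rec$age < 18) fail("age", "must be >= 18 (adult pathway)")
  if (rec$bmi <= 0) fail("bmi", "must be positive")
  for (f in opt_num_fields) {
    if (!has_value(rec[[f]])) { rec[f] <- list(NA_real_); next }
    v <- rec[[f]]
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      fail(f, "must be a finite non-negative number when present")
    }
  }
  for (f in logical_fields) {
    if (!has_value(rec[[f]])) {
      rec[f] <- list(if (f %in% c("alcohol_over_14", "metabolic_syndrome"))
        fail(f, "is missing") else NA)
    } else {
      v <- rec[[f]]
      if (is.character(v)) v <- tolower(v) %in% c("true", "t", "1", "yes")
      if (is.numeric(v)) v <- v != 0
      if (!is.logical(v)) fail(f, "must be logical")
      rec[[f]] <- v
    }
  }
  if (has_value(rec$direct_bilirubin) &&
      rec$direct_bilirubin > rec$bilirubin_total) {
    fail("direct_bilirubin", "cannot exceed bilirubin_total")
  }
  rec
}

#' Read patient records from CSV or JSON
#'
#' CSV must be comma-delimited UTF-8 with a header row using the schema
#' column names ([record_fields()]); JSON must be an array of objects with
#' the same keys. Missing optional analytes may be empty/`null`.
#'
#' @param path Input file; format inferred from the `.json`/`.csv` extension
#'   unless `format` is given.
#' @param format `"csv"`, `"json"`, or `NULL` to infer.
#' @return List of raw (unvalidated) record lists.
#' @export
read_records <- function(path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    recs <- jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    recs <- lapply(seq_len(nrow(df)), function(i) as.list(df[i, , drop = FALSE]))
  }
  lapply(recs, function(r) {
    r[vapply(r, function(v) length(v) == 1L && (is.null(v) || identical(v, "")),
             logical(1))] <- NA
    r
  })
}

#' Write patient records to CSV or JSON
#'
#' @param records List of record lists.
#' @param path Output file.
#' @param format `"csv"` or `"json"`; inferred from the extension when `NULL`.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path, format = NULL) {
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  df <- records_to_df(records)
  if (format == "json") {
    jsonlite::write_json(df, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, na = "")
  }
  invisible(path)
}

records_to_df <- function(records) {
  cols <- record_fields()
  out <- lapply(cols, function(f) {
    vapply(records, function(r) {
      v <- r[[f]]
      if (!has_value(v)) NA else v
    }, if (f %in% c("patient_id", "sex")) NA_character_
       else if (f %in% logical_fields) NA
       else NA_real_)
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
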