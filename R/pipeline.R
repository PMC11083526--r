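#' Run one patient record through the whole pathway
#'
#' Orchestrates validation, the first-line cascade decision, fibrosis
#' scoring with reflex ELF, aetiology screen interpretation and outcome
#' classification for a single record.
#'
#' On a full cascade, FIB-4 is computed from age/AST/ALT/platelets; NFS is
#' additionally computed and merged when the presumed aetiology is
#' MASLD/MetALD (i.e. the metabolic-syndrome flag is set). ELF is computed
#' only when the indirect band reflexes it (indeterminate or high, or not
#' computable — which reflexes and flags) and the ELF analytes were
#' measured. Missing AST or platelets never abort the cascade: the fibrosis
#' result carries a `not_computable` band instead.
#'
#' @param record Named list or single data.frame row in the record schema.
#' @param thresholds Thresholds list.
#' @param registry Outcome registry data frame.
#' @param legacy_nomenclature Passed to [classify()].
#' @return A classified-record list: `patient_id`, `tier`, `added_assays`,
#'   `abnormal_analytes`, `fib4`, `nfs`, `elf`, `indirect_band`,
#'   `elf_band`, `final_fibrosis_category`, `urgent_prognosis`,
#'   `outcomes` (list of coded outcomes) and `record_referral`.
#' @examples
#' rec <- list(patient_id = "p1", age = 52, sex = "male", bmi = 27,
#'             alcohol_over_14 = TRUE, metabolic_syndrome = FALSE,
#'             alt = 80, alp = 100, ggt = 120, bilirubin_total = 12,
#'             albumin = 44, ast = 40, platelets = 300,
#'             transferrin_saturation = 30, a1at = 1.5)
#' classify_record(rec)$outcomes[[1]]$code
#' @export
classify_record <- function(record, thresholds = ilft_thresholds(),
                            registry = load_registry(),
                            legacy_nomenclature = FALSE) {
  th <- thresholds
  rec <- validate_record(record)
  plan <- evaluate_first_line(rec, rec, th)

  findings <- NULL
  fibrosis <- NULL
  if (plan$tier == "full") {
    findings <- interpret_screen(rec, rec, th)
    fib4 <- compute_fib4(rec$age, rec$ast, rec$alt, rec$platelets)
    use_nfs <- isTRUE(rec$metabolic_syndrome)
    nfs <- if (use_nfs) {
      compute_nfs(rec$age, rec$bmi, rec$metabolic_syndrome, rec$ast,
                  rec$alt, rec$platelets, rec$albumin)
    } else NA_real_
    band <- band_indirect(fib4, nfs, use_nfs, th)
    elf <- NA_real_
    if (band != "low" && has_value(rec$ha) && has_value(rec$piiinp) &&
        has_value(rec$timp1)) {
      elf <- compute_elf(rec$ha, rec$piiinp, rec$timp1, th)
    }
    fibrosis <- assess_fibrosis(band, elf, th, fib4 = fib4, nfs = nfs)
  }

  cls <- classify(rec, rec, plan, findings, fibrosis, registry, th,
                  legacy_nomenclature)
  list(patient_id = rec$patient_id,
       tier = plan$tier,
       added_assays = plan$added_assays,
       abnormal_analytes = plan$abnormal_analytes,
       fib4 = if (is.null(fibrosis)) NA_real_ else fibrosis$fib4,
       nfs = if (is.null(fibrosis)) NA_real_ else fibrosis$nfs,
       elf = if (is.null(fibrosis)) NA_real_ else fibrosis$elf,
       indirect_band = if (is.null(fibrosis)) NA_character_ else fibrosis$indirect_band,
       elf_band = if (is.null(fibrosis)) NA_character_ else fibrosis$elf_band,
       final_fibrosis_category = if (is.null(fibrosis)) NA_character_
                                 else fibrosis$final_category,
       urgent_prognosis = !is.null(fibrosis) && isTRUE(fibrosis$urgent_prognosis),
       outcomes = cls$outcomes,
       record_referral = cls$record_referral)
}

#' Run a cohort file through the pathway and write outputs
#'
#' Reads records from CSV or JSON, classifies each, and writes a per-record
#' JSON file, a flat CSV export (one row per record-outcome pair), a
#' cohort summary (JSON) and a structured log of the rules that fired.
#' Malformed rows are rejected individually (with a line-numbered report in
#' the log) and processing continues; any rejection makes the returned
#' status non-zero.
#'
#' @param input Path to a records file (`.csv` or `.json`).
#' @param output Output stem: writes `<output>.json`, `<output>.csv`,
#'   `<output>_summary.json` and `<output>.log`.
#' @param config Optional YAML thresholds file; `NULL` for defaults.
#' @param registry_path Optional registry file; `NULL` for the shipped one.
#' @param legacy_nomenclature Passed to [classify()].
#' @return Invisibly, a list: `status` (0 when every row classified),
#'   `results`, `summary`, `rejects` (data frame of row / patient_id /
#'   message), `log` (character vector).
#' @export
run_pipeline <- function(input, output, config = NULL, registry_path = NULL,
                         legacy_nomenclature = FALSE) {
  th <- if (is.null(config)) ilft_thresholds() else load_thresholds(config)
  registry <- if (is.null(registry_path)) load_registry()
              else load_registry(registry_path)
  records <- read_records(input)

  results <- vector("list", length(records))
  log <- character(0)
  rej_row <- integer(0); rej_id <- character(0); rej_msg <- character(0)
  kept <- logical(length(records))
  for (i in seq_along(records)) {
    res <- tryCatch(
      classify_record(records[[i]], th, registry, legacy_nomenclature),
      ilft_validation_error = function(e) e)
    if (inherits(res, "condition")) {
      rej_row <- c(rej_row, i)
      pid <- records[[i]]$patient_id
      rej_id <- c(rej_id, if (has_value(pid)) as.character(pid) else NA_character_)
      rej_msg <- c(rej_msg, conditionMessage(res))
      log <- c(log, sprintf("REJECT row %d: %s", i, conditionMessage(res)))
    } else {
      kept[i] <- TRUE
      results[[i]] <- res
      log <- c(log, sprintf(
        "row %d patient %s: tier=%s; codes=%s; referral=%s", i,
        res$patient_id, res$tier,
        paste(vapply(res$outcomes, `[[`, "", "code"), collapse = "+"),
        res$record_referral))
    }
  }
  results <- results[kept]
  rejects <- data.frame(row = rej_row, patient_id = rej_id, message = rej_msg,
                        stringsAsFactors = FALSE)
  summary <- summarize_cohort(results)

  jsonlite::write_json(results, paste0(output, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  utils::write.csv(results_to_flat_df(results), paste0(output, ".csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(unclass(summary), paste0(output, "_summary.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
  writeLines(log, paste0(output, ".log"))
  invisible(list(status = if (nrow(rejects)) 1L else 0L,
                 results = results, summary = summary,
                 rejects = rejects, log = log))
}

#' Flatten classified records to one row per (record, outcome)
#'
#' @param results List of classified-record lists from [classify_record()].
#' @return Data frame suitable for CSV export.
#' @export
results_to_flat_df <- function(results) {
  rows <- list()
  for (res in results) {
    for (o in res$outcomes) {
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = res$patient_id, tier = res$tier,
        fib4 = res$fib4, nfs = res$nfs, elf = res$elf,
        indirect_band = or_na(res$indirect_band),
        elf_band = or_na(res$elf_band),
        final_fibrosis_category = or_na(res$final_fibrosis_category),
        urgent_prognosis = res$urgent_prognosis,
        code = o$code, description = o$description, category = o$category,
        referral = o$referral, record_referral = res$record_referral,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) {
    return(data.frame(patient_id = character(0)))
  }
  do.call(rbind, rows)
}

or_na <- function(x) if (has_value(x)) x else NA_character_
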