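#' Evaluate the first-line liver panel and decide the reflex cascade
#'
#' Applies the trigger rules to the first-line panel (ALT, ALP, GGT, total
#' bilirubin; albumin is collected but carries no trigger of its own) and
#' returns the reflex tier plus the assays that cascade:
#'
#' * **full** — ALT above its trigger, or GGT above its URL, or total
#'   bilirubin above the mild band, or ALP above the full-cascade limit: the
#'   complete aetiology screen is added (AST, iron studies, A1AT, HBV/HCV
#'   serology, liver autoantibodies; plus CRP when the patient is under 45,
#'   with caeruloplasmin added downstream only if CRP is not elevated).
#' * **limited_bilirubin** — a mild, *isolated* elevation of total bilirubin
#'   (within the mild band): only direct (conjugated) bilirubin and
#'   haptoglobin are added, to assess for Gilbert syndrome vs haemolysis.
#' * **alp_advisory** — a mild, *isolated* ALP elevation (above the URL but
#'   not above the full-cascade limit): no assays are added; the outcome is
#'   advice to repeat ALP and GGT in three months.
#' * **none** — everything within limits.
#'
#' If both bilirubin and ALP are mildly elevated and nothing else is, neither
#' is an "only abnormality": the record escalates to a full screen
#' (fail-safe).
#'
#' @param panel Validated record (list) holding `alt`, `alp`, `ggt`,
#'   `bilirubin_total` at minimum.
#' @param context Validated record holding `age` (the CRP age gate).
#' @param thresholds Thresholds list, see [ilft_thresholds()].
#' @return A `cascade_plan` list: `tier` (one of `"none"`,
#'   `"alp_advisory"`, `"limited_bilirubin"`, `"full"`), `added_assays`
#'   (character vector) and `abnormal_analytes` (character vector).
#' @examples
#' rec <- list(alt = 20, alp = 250, ggt = 30, bilirubin_total = 10)
#' evaluate_first_line(rec, list(age = 50), ilft_thresholds())$tier
#' @export
evaluate_first_line <- function(panel, context, thresholds = ilft_thresholds()) {
  th <- thresholds
  for (f in c("alt", "alp", "ggt", "bilirubin_total")) {
    v <- panel[[f]]
    if (!has_value(v)) {
      stop(structure(class = c("ilft_validation_error", "error", "condition"),
                     list(message = sprintf("field '%s' missing from first-line panel", f),
                          call = NULL, field = f)))
    }
    if (!is.numeric(v) || !is.finite(v) || v < 0) {
      stop(structure(class = c("ilft_validation_error", "error", "condition"),
                     list(message = sprintf("field '%s' must be a finite non-negative number", f),
                          call = NULL, field = f)))
    }
  }
  alt <- panel$alt; alp <- panel$alp; ggt <- panel$ggt
  bili <- panel$bilirubin_total

  abnormal <- character(0)
  if (alt > th$alt_trigger) abnormal <- c(abnormal, "alt")
  if (alp > th$alp_url) abnormal <- c(abnormal, "alp")
  if (ggt > th$ggt_url) abnormal <- c(abnormal, "ggt")
  if (bili >= th$bili_mild_low) abnormal <- c(abnormal, "bilirubin_total")

  full_trigger <- alt > th$alt_trigger || ggt > th$ggt_url ||
    bili > th$bili_mild_high || alp > th$alp_full_cascade

  if (full_trigger || length(abnormal) > 1L) {
    assays <- c("ast", "iron_studies", "a1at", "hbv_serology",
                "hcv_serology", "autoantibodies")
    if (context$age < th$crp_age_limit) assays <- c(assays, "crp")
    return(new_cascade_plan("full", assays, abnormal))
  }
  if (identical(abnormal, "bilirubin_total")) {
    return(new_cascade_plan("limited_bilirubin",
                            c("direct_bilirubin", "haptoglobin"), abnormal))
  }
  if (identical(abnormal, "alp")) {
    return(new_cascade_plan("alp_advisory", character(0), abnormal))
  }
  new_cascade_plan("none", character(0), character(0))
}

new_cascade_plan <- function(tier, added_assays, abnormal_analytes) {
  structure(list(tier = tier,
                 added_assays = added_assays,
                 abnormal_analytes = abnormal_analytes),
            class = "cascade_plan")
}

#' @export
print.cascade_plan <- function(x, ...) {
  cat("cascade tier:", x$tier, "\n")
  cat("abnormal analytes:",
      if (length(x$abnormal_analytes)) paste(x$abnormal_analytes, collapse = ", ")
      else "(none)", "\n")
  cat("added assays:",
      if (length(x$added_assays)) paste(x$added_assays, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}
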