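aetiology_names <- c("iron_overload", "a1at_deficiency", "hepatitis_b",
                     "hepatitis_c", "autoimmune", "wilson_possible",
                     "gilbert_pattern", "haemolysis_pattern")

finding <- function(aetiology, status, detail = "") {
  list(aetiology = aetiology, status = status, detail = detail)
}

#' Interpret the reflexed aetiology screen
#'
#' Produces exactly one finding per aetiology with status `positive`,
#' `negative` or `not_tested`:
#'
#' * `iron_overload` — transferrin saturation above the cutoff (45% default).
#' * `a1at_deficiency` — serum A1AT below 1.0 g/L (reflex phenotyping is
#'   recommended in the detail text; phenotype interpretation is out of
#'   scope).
#' * `hepatitis_b` / `hepatitis_c` — laboratory-adjudicated serology flags.
#' * `autoimmune` — liver autoantibody flag (AIH / PBC / SLE patterns).
#' * `wilson_possible` — age-gated: fires only under 45 years, when CRP is
#'   not elevated (caeruloplasmin is an acute-phase reactant, so an elevated
#'   CRP blocks its addition) and caeruloplasmin is below the cutoff
#'   (0.20 g/L default).
#' * `gilbert_pattern` / `haemolysis_pattern` — from [gilbert_check()] on
#'   the limited-bilirubin tier; `not_tested` here.
#'
#' An analyte never cascaded (absent) yields `not_tested`. A caeruloplasmin
#' value supplied despite an elevated CRP is a protocol violation: a warning
#' is raised but the finding is still computed from the value.
#'
#' @param screen Validated record holding whichever screen analytes were
#'   measured (`transferrin_saturation`, `a1at`, `hbv_positive`,
#'   `hcv_positive`, `autoantibody_positive`, `crp`, `caeruloplasmin`).
#' @param context Validated record holding `age` for the Wilson gate.
#' @param thresholds Thresholds list.
#' @return Named list of findings (one per aetiology), each a list with
#'   `aetiology`, `status`, `detail`.
#' @examples
#' scr <- list(a1at = 0.8, crp = 2, caeruloplasmin = 0.12)
#' f <- interpret_screen(scr, list(age = 40))
#' f$a1at_deficiency$status
#' @export
interpret_screen <- function(screen, context, thresholds = ilft_thresholds()) {
  th <- thresholds
  out <- list()

  out$iron_overload <- if (!has_value(screen$transferrin_saturation)) {
    finding("iron_overload", "not_tested")
  } else if (screen$transferrin_saturation > th$tsat_cutoff) {
    finding("iron_overload", "positive",
            sprintf("transferrin saturation %.0f%% — consider haemochromatosis (HFE genotyping)",
                    screen$transferrin_saturation))
  } else finding("iron_overload", "negative")

  out$a1at_deficiency <- if (!has_value(screen$a1at)) {
    finding("a1at_deficiency", "not_tested")
  } else if (screen$a1at < th$a1at_cutoff) {
    finding("a1at_deficiency", "positive",
            sprintf("A1AT %.1f g/L — phenotyping recommended", screen$a1at))
  } else finding("a1at_deficiency", "negative")

  out$hepatitis_b <- bool_finding("hepatitis_b", screen$hbv_positive,
                                  "HBV serology positive — confirmatory testing follows")
  out$hepatitis_c <- bool_finding("hepatitis_c", screen$hcv_positive,
                                  "HCV serology positive — confirmatory testing follows")
  out$autoimmune <- bool_finding("autoimmune", screen$autoantibody_positive,
                                 "liver autoantibodies positive — consider AIH/PBC/SLE")

  # Wilson pathway: CRP gates caeruloplasmin, age gates the whole branch
  crp <- screen$crp
  cp <- screen$caeruloplasmin
  crp_elevated <- has_value(crp) && crp > th$crp_elevated
  if (has_value(cp) && crp_elevated) {
    warning("protocol violation: caeruloplasmin supplied despite elevated CRP (",
            crp, " mg/L); finding computed anyway", call. = FALSE)
  }
  out$wilson_possible <- if (!has_value(cp)) {
    finding("wilson_possible", "not_tested")
  } else if (context$age < th$crp_age_limit && !crp_elevated &&
             cp < th$caeruloplasmin_cutoff) {
    finding("wilson_possible", "positive",
            sprintf("caeruloplasmin %.2f g/L in a patient under %d — consider Wilson disease",
                    cp, as.integer(th$crp_age_limit)))
  } else finding("wilson_possible", "negative")

  out$gilbert_pattern <- finding("gilbert_pattern", "not_tested")
  out$haemolysis_pattern <- finding("haemolysis_pattern", "not_tested")
  out
}

bool_finding <- function(aetiology, flag, pos_detail) {
  if (!has_value(flag)) finding(aetiology, "not_tested")
  else if (isTRUE(flag)) finding(aetiology, "positive", pos_detail)
  else finding(aetiology, "negative")
}

#' Bilirubin sub-typing on the limited cascade
#'
#' For a mild, isolated elevation of total bilirubin the pathway measures
#' direct (conjugated) bilirubin and haptoglobin and classifies the pattern:
#'
#' * `gilbert_likely` — predominantly unconjugated (direct/total below the
#'   conjugated-fraction cutoff, default 0.20) with no evidence of
#'   haemolysis (haptoglobin at/above its lower limit, default 0.3 g/L).
#' * `haemolysis_suspected` — haptoglobin below the lower limit.
#' * `conjugated_pattern` — conjugated fraction at/above the cutoff with
#'   normal haptoglobin.
#'
#' @param bilirubin_total Total bilirubin, µmol/L.
#' @param direct_bilirubin Direct bilirubin, µmol/L; must not exceed total.
#' @param haptoglobin g/L.
#' @param thresholds Thresholds list.
#' @return One of `"gilbert_likely"`, `"conjugated_pattern"`,
#'   `"haemolysis_suspected"`, or `"not_applicable"` when direct bilirubin
#'   or haptoglobin was not measured.
#' @examples
#' gilbert_check(40, 6, 1.2) # gilbert_likely
#' @export
gilbert_check <- function(bilirubin_total, direct_bilirubin, haptoglobin,
                          thresholds = ilft_thresholds()) {
  th <- thresholds
  if (!has_value(direct_bilirubin) || !has_value(haptoglobin)) {
    return("not_applicable")
  }
  if (direct_bilirubin > bilirubin_total) {
    stop(structure(class = c("ilft_validation_error", "error", "condition"),
                   list(message = "direct bilirubin exceeds total bilirubin",
                        call = NULL, field = "direct_bilirubin")))
  }
  if (haptoglobin < th$haptoglobin_low) return("haemolysis_suspected")
  fraction <- direct_bilirubin / bilirubin_total
  if (fraction < th$conjugated_fraction) "gilbert_likely" else "conjugated_pattern"
}
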