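#' FIB-4 index
#'
#' Indirect fibrosis score: `age * AST / (platelets * sqrt(ALT))`, with age
#' in years, AST and ALT in U/L and platelets in 10^9/L.
#'
#' @param age Years.
#' @param ast AST, U/L.
#' @param alt ALT, U/L; must be positive.
#' @param platelets Platelet count, 10^9/L; must be positive.
#' @return The unitless score, or `NA_real_` (not computable) when any
#'   input is missing or ALT/platelets are zero. Division errors are never
#'   propagated.
#' @examples
#' compute_fib4(61, 60, 40, 150) # 3.858
#' @export
compute_fib4 <- function(age, ast, alt, platelets) {
  if (!all(vapply(list(age, ast, alt, platelets), has_value, logical(1)))) {
    return(NA_real_)
  }
  if (alt <= 0 || platelets <= 0) return(NA_real_)
  age * ast / (platelets * sqrt(alt))
}

#' NAFLD fibrosis score (NFS)
#'
#' Indirect fibrosis score used for presumed MASLD/MetALD only:
#' `-1.675 + 0.037*age + 0.094*BMI + 1.13*dysglycaemia + 0.99*AST/ALT
#'  - 0.013*platelets - 0.66*albumin`, with albumin in g/dL. UK laboratories
#' report albumin in g/L, so the `albumin` argument is taken in g/L and
#' divided by 10 internally. The pathway collects a metabolic-syndrome
#' tick-box rather than IFG/diabetes status, so that flag stands in for the
#' dysglycaemia term (a documented proxy).
#'
#' @param age Years.
#' @param bmi kg/m^2.
#' @param dysglycaemia Logical; impaired fasting glycaemia or diabetes
#'   (proxied by the metabolic-syndrome flag).
#' @param ast,alt U/L; ALT must be positive.
#' @param platelets 10^9/L.
#' @param albumin g/L (converted to g/dL internally).
#' @return The unitless score, or `NA_real_` when any input is missing.
#' @examples
#' compute_nfs(50, 32, TRUE, 40, 50, 200, 40) # -0.135
#' @export
compute_nfs <- function(age, bmi, dysglycaemia, ast, alt, platelets, albumin) {
  if (!all(vapply(list(age, bmi, dysglycaemia, ast, alt, platelets, albumin),
                  has_value, logical(1)))) {
    return(NA_real_)
  }
  if (alt <= 0) return(NA_real_)
  -1.675 + 0.037 * age + 0.094 * bmi + 1.13 * as.numeric(dysglycaemia) +
    0.99 * ast / alt - 0.013 * platelets - 0.66 * (albumin / 10)
}

#' Enhanced Liver Fibrosis (ELF) score
#'
#' Direct serum fibrosis marker combining hyaluronic acid (HA), procollagen
#' III N-terminal peptide (PIIINP) and tissue inhibitor of matrix
#' metalloproteinase-1 (TIMP-1):
#' `2.278 + 0.851*ln(HA) + 0.751*ln(PIIINP) + 0.394*ln(TIMP-1)`. The
#' coefficient set is the manufacturer's published calibration, pinned in
#' the thresholds config so an alternative calibration can be swapped in.
#'
#' @param ha,piiinp,timp1 Analyte concentrations; all strictly positive
#'   (logarithms must be defined).
#' @param thresholds Thresholds list carrying the calibration coefficients.
#' @return Finite unitless score, strictly increasing in each analyte.
#' @examples
#' compute_elf(20, 8, 100) # 8.203
#' @export
compute_elf <- function(ha, piiinp, timp1, thresholds = ilft_thresholds()) {
  for (nm in c("ha", "piiinp", "timp1")) {
    v <- get(nm)
    if (!has_value(v) || !is.numeric(v) || !is.finite(v) || v <= 0) {
      stop(structure(class = c("ilft_validation_error", "error", "condition"),
                     list(message = sprintf("ELF analyte '%s' must be a positive finite number", nm),
                          call = NULL, field = nm)))
    }
  }
  th <- thresholds
  th$elf_intercept + th$elf_coef_ha * log(ha) +
    th$elf_coef_piiinp * log(piiinp) + th$elf_coef_timp1 * log(timp1)
}

#' Stage an ELF score
#'
#' Half-open stage boundaries: absent/mild below 7.7, moderate from 7.7 to
#' below 9.8, severe from 9.8 to below 11.3, cirrhosis at 11.3 and above
#' (defaults; configurable).
#'
#' @param elf Unitless ELF score, or `NA` for absent.
#' @param thresholds Thresholds list.
#' @return One of `"absent_mild"`, `"moderate"`, `"severe"`, `"cirrhosis"`,
#'   or `NA_character_` when `elf` is absent.
#' @export
elf_band <- function(elf, thresholds = ilft_thresholds()) {
  if (!has_value(elf)) return(NA_character_)
  th <- thresholds
  if (elf < th$elf_mild) "absent_mild"
  else if (elf < th$elf_referral) "moderate"
  else if (elf < th$elf_cirrhosis) "severe"
  else "cirrhosis"
}

#' Band the indirect fibrosis scores
#'
#' FIB-4 alone, or FIB-4 combined with NFS when the working aetiology is
#' presumed MASLD/MetALD (`use_nfs = TRUE`). With both scores the merge is
#' maximum-severity: high if either score rules in, low only if both rule
#' out, indeterminate otherwise. Rule-out / rule-in cutoffs come from the
#' thresholds config (FIB-4 low < 1.30, high > 2.67; NFS low < -1.455,
#' high > 0.676 by default).
#'
#' @param fib4 FIB-4 score, or `NA` if not computable.
#' @param nfs NFS score, or `NA`; consulted only when `use_nfs`.
#' @param use_nfs Logical; `TRUE` for presumed MASLD/MetALD.
#' @param thresholds Thresholds list.
#' @return One of `"low"`, `"indeterminate"`, `"high"`, `"not_computable"`.
#' @export
band_indirect <- function(fib4, nfs = NA_real_, use_nfs = FALSE,
                          thresholds = ilft_thresholds()) {
  th <- thresholds
  band1 <- function(x, lo, hi) {
    if (!has_value(x)) return(NA_character_)
    if (x > hi) "high" else if (x < lo) "low" else "indeterminate"
  }
  fb <- band1(fib4, th$fib4_low, th$fib4_high)
  if (is.na(fb)) return("not_computable")
  if (!isTRUE(use_nfs)) return(fb)
  nb <- band1(nfs, th$nfs_low, th$nfs_high)
  if (is.na(nb)) return("not_computable")
  if (fb == "high" || nb == "high") "high"
  else if (fb == "low" && nb == "low") "low"
  else "indeterminate"
}

#' Merge indirect banding and reflex ELF into the fibrosis assessment
#'
#' Implements the reflex-ELF resolution of the indeterminate zone and the
#' fail-safe rule-in:
#' * indirect **low** -> `no_significant_fibrosis` (ELF must not be present:
#'   it only reflexes on indeterminate/high scores; supplying it here is a
#'   protocol violation).
#' * indirect **high** -> `significant_fibrosis` regardless of ELF
#'   (fail-safe: a direct marker never overrides an indirect rule-in; ELF
#'   then contributes staging/prognosis only).
#' * indirect **indeterminate** -> resolved by ELF: `significant_fibrosis`
#'   at/above the referral threshold (9.8), `indeterminate_resolved_low`
#'   below it, `indeterminate_unresolved` when ELF is missing.
#' * indirect **not_computable** is handled like indeterminate (reflex ELF
#'   and resolve, else unresolved), with the band retained on the result.
#'
#' `urgent_prognosis` is set exactly when ELF reaches the urgency threshold
#' (13 by default).
#'
#' @param indirect_band Output of [band_indirect()].
#' @param elf ELF score or `NA` for absent.
#' @param thresholds Thresholds list.
#' @param fib4,nfs Optional scores carried onto the result for reporting.
#' @return A `fibrosis_assessment` list: `fib4`, `nfs`, `elf`,
#'   `indirect_band`, `elf_band`, `urgent_prognosis`, `final_category`
#'   (one of `no_significant_fibrosis`, `indeterminate_resolved_low`,
#'   `significant_fibrosis`, `indeterminate_unresolved`).
#' @export
assess_fibrosis <- function(indirect_band, elf = NA_real_,
                            thresholds = ilft_thresholds(),
                            fib4 = NA_real_, nfs = NA_real_) {
  th <- thresholds
  stopifnot(indirect_band %in% c("low", "indeterminate", "high", "not_computable"))
  elf_present <- has_value(elf)
  if (indirect_band == "low" && elf_present) {
    stop(structure(class = c("ilft_validation_error", "error", "condition"),
                   list(message = "protocol violation: ELF present with low indirect fibrosis band",
                        call = NULL, field = "elf")))
  }
  final <- switch(indirect_band,
    low = "no_significant_fibrosis",
    high = "significant_fibrosis",
    {
      # indeterminate or not_computable: ELF resolves
      if (!elf_present) "indeterminate_unresolved"
      else if (elf >= th$elf_referral) "significant_fibrosis"
      else "indeterminate_resolved_low"
    })
  structure(list(
    fib4 = fib4, nfs = nfs, elf = if (elf_present) elf else NA_real_,
    indirect_band = indirect_band,
    elf_band = elf_band(elf, th),
    urgent_prognosis = elf_present && elf >= th$elf_urgent,
    final_category = final
  ), class = "fibrosis_assessment")
}
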