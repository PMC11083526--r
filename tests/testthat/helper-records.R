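# Record builder: a within-limits adult, overridable field by field.
make_record <- function(...) {
  rec <- list(
    patient_id = "t001", age = 50, sex = "male", bmi = 27,
    alcohol_over_14 = FALSE, metabolic_syndrome = FALSE,
    alt = 20, alp = 100, ggt = 30, bilirubin_total = 10, albumin = 44,
    ast = 25, platelets = 300,
    transferrin_saturation = 30, a1at = 1.5,
    hbv_positive = FALSE, hcv_positive = FALSE, autoantibody_positive = FALSE,
    crp = NA_real_, caeruloplasmin = NA_real_,
    direct_bilirubin = NA_real_, haptoglobin = NA_real_,
    ha = NA_real_, piiinp = NA_real_, timp1 = NA_real_)
  over <- list(...)
  rec[names(over)] <- over
  rec
}

outcome_codes <- function(classified) {
  vapply(classified$outcomes, `[[`, character(1), "code")
}

# Independent nested-conditional oracle for the cascade tier, written
# directly from the trigger rules (not via the engine's code path).
cascade_tier_oracle <- function(alt, alp, ggt, bili) {
  if (alt > 30) return("full")
  if (ggt > 60) return("full")
  if (bili > 60) return("full")
  if (alp > 200) return("full")
  alp_ab <- alp > 130
  bili_ab <- bili >= 22
  if (alp_ab && bili_ab) return("full")     # neither is an "only" abnormality
  if (bili_ab) return("limited_bilirubin")
  if (alp_ab) return("alp_advisory")
  "none"
}

referral_severity <- function(referral) {
  match(referral, c("none", "phenotype_dependent", "routine", "urgent"))
}
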