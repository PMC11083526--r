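#' Default decision thresholds for the liver pathway
#'
#' Every cutoff the rules engine consults lives in one flat configuration
#' list so that a site running different upper reference limits (URLs) can
#' substitute its own values. Units are fixed by convention: enzymes in U/L,
#' bilirubin in µmol/L, albumin / haptoglobin / A1AT / caeruloplasmin in g/L,
#' platelets in 10^9/L, CRP in mg/L, transferrin saturation in percent;
#' FIB-4, NFS and ELF are unitless.
#'
#' First-line triggers: ALT is abnormal above `alt_trigger` (30 U/L, a
#' screening threshold deliberately below typical local URLs and not
#' sex-specific); GGT above `ggt_url`; ALP above `alp_url` with a full
#' cascade only above `alp_full_cascade`; total bilirubin is abnormal from
#' `bili_mild_low` (inclusive) with a full cascade above `bili_mild_high`.
#'
#' Fibrosis banding: FIB-4 below `fib4_low` rules out, above `fib4_high`
#' rules in; likewise NFS at `nfs_low` / `nfs_high` (used only for presumed
#' MASLD/MetALD). ELF stage boundaries `elf_mild` / `elf_referral` /
#' `elf_cirrhosis` are 7.7 / 9.8 / 11.3 with `elf_urgent` = 13 carrying
#' prognostic urgency; referral on ELF uses `elf_referral`.
#'
#' @return Named list of thresholds.
#' @examples
#' th <- ilft_thresholds()
#' th$alt_trigger
#' @export
ilft_thresholds <- function() {
  list(
    # first-line cascade triggers (strict ">" unless noted)
    alt_trigger      = 30,    # U/L; not sex-specific
    alt_marked       = 250,   # U/L; at/above -> urgent marked-ALT outcome
    ggt_url          = 60,    # U/L; local URL, site-configurable
    alp_url          = 130,   # U/L; mild elevation above this
    alp_full_cascade = 200,   # U/L; full screen only above this
    bili_mild_low    = 22,    # µmol/L; inclusive lower bound of mild band
    bili_mild_high   = 60,    # µmol/L; full screen above this
    # indirect fibrosis score cutoffs
    fib4_low         = 1.30,
    fib4_high        = 2.67,
    nfs_low          = -1.455,
    nfs_high         = 0.676,
    # ELF calibration and stage boundaries (unitless)
    elf_intercept    = 2.278,
    elf_coef_ha      = 0.851,
    elf_coef_piiinp  = 0.751,
    elf_coef_timp1   = 0.394,
    elf_mild         = 7.7,   # below: absent/mild
    elf_referral     = 9.8,   # at/above: severe; referral threshold
    elf_cirrhosis    = 11.3,  # at/above: cirrhosis
    elf_urgent       = 13,    # at/above: urgent prognosis
    # aetiology screen interpretation
    tsat_cutoff      = 45,    # %; iron overload above this
    a1at_cutoff      = 1.0,   # g/L; deficiency below this
    crp_elevated     = 5,     # mg/L; above this caeruloplasmin is not added
    caeruloplasmin_cutoff = 0.20, # g/L; possible Wilson below this
    crp_age_limit    = 45,    # years; CRP cascades only under this age
    conjugated_fraction   = 0.20, # direct/total below this = unconjugated
    haptoglobin_low  = 0.3,   # g/L; below this suggests haemolysis
    # malignancy alert (all strict)
    malignancy_age   = 40,    # years, over
    malignancy_alp   = 130,   # U/L, over
    malignancy_platelets  = 400   # 10^9/L, over
  )
}

#' Load thresholds from a YAML configuration file
#'
#' Reads a flat YAML mapping and overlays it on [ilft_thresholds()]. Every
#' key in the file must be a known threshold; a key present in the defaults
#' but absent from the file keeps its default. Use
#' `system.file("extdata", "default_thresholds.yaml", package = "ilftr")`
#' as a template.
#'
#' @param path Path to a YAML file of `threshold: value` pairs.
#' @return Named list of thresholds (validated).
#' @export
load_thresholds <- function(path) {
  if (!file.exists(path)) {
    stop("thresholds config not found: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  th <- ilft_thresholds()
  unknown <- setdiff(names(cfg), names(th))
  if (length(unknown)) {
    stop("unknown threshold key(s) in config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  th[names(cfg)] <- cfg
  validate_thresholds(th)
}

#' Validate a thresholds list
#'
#' Checks completeness, numeric finiteness and the ordering constraints the
#' rules rely on (`alp_url < alp_full_cascade`, `bili_mild_low <
#' bili_mild_high`, rule-out below rule-in, ELF stages increasing).
#'
#' @param th Named list as returned by [ilft_thresholds()].
#' @return `th`, invisibly usable, after validation; errors name the key.
#' @export
validate_thresholds <- function(th) {
  needed <- names(ilft_thresholds())
  missing <- setdiff(needed, names(th))
  if (length(missing)) {
    stop("thresholds config missing key(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  for (k in needed) {
    v <- th[[k]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("threshold '", k, "' must be a single finite number", call. = FALSE)
    }
  }
  if (!(th$alp_url < th$alp_full_cascade)) {
    stop("alp_url must be < alp_full_cascade", call. = FALSE)
  }
  if (!(th$bili_mild_low < th$bili_mild_high)) {
    stop("bili_mild_low must be < bili_mild_high", call. = FALSE)
  }
  if (!(th$fib4_low < th$fib4_high)) stop("fib4_low must be < fib4_high", call. = FALSE)
  if (!(th$nfs_low < th$nfs_high)) stop("nfs_low must be < nfs_high", call. = FALSE)
  if (!(th$elf_mild < th$elf_referral && th$elf_referral < th$elf_cirrhosis)) {
    stop("ELF stage boundaries must increase: elf_mild < elf_referral < elf_cirrhosis",
         call. = FALSE)
  }
  th
}
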