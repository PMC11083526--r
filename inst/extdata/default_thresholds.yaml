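# Decision thresholds (defaults; edit for local upper reference limits).
# Units: enzymes U/L, bilirubin umol/L, albumin/haptoglobin/A1AT/
# caeruloplasmin g/L, platelets 10^9/L, CRP mg/L, transferrin saturation %.
# Comparison strictness is fixed by the engine: strict ">" at alt_trigger,
# ggt_url, alp_url, alp_full_cascade, bili_mild_high and the malignancy
# rule; inclusive ">=" at bili_mild_low, alt_marked and the ELF stage
# boundaries; strict "<" at a1at_cutoff and caeruloplasmin_cutoff.

alt_trigger: 30          # U/L; ALT abnormal above this (not sex-specific)
alt_marked: 250          # U/L; at/above -> urgent marked-ALT outcome
ggt_url: 60              # U/L; local GGT upper reference limit
alp_url: 130             # U/L; ALP mildly elevated above this
alp_full_cascade: 200    # U/L; isolated ALP cascades fully only above this
bili_mild_low: 22        # umol/L; mild band starts here (inclusive)
bili_mild_high: 60       # umol/L; full screen above this

fib4_low: 1.30           # FIB-4 rule-out below this
fib4_high: 2.67          # FIB-4 rule-in above this
nfs_low: -1.455          # NFS rule-out below this (presumed MASLD/MetALD only)
nfs_high: 0.676          # NFS rule-in above this

elf_intercept: 2.278     # ELF calibration (manufacturer's published set)
elf_coef_ha: 0.851
elf_coef_piiinp: 0.751
elf_coef_timp1: 0.394
elf_mild: 7.7            # ELF below: absent/mild fibrosis
elf_referral: 9.8        # ELF at/above: severe fibrosis; referral threshold
elf_cirrhosis: 11.3      # ELF at/above: cirrhosis
elf_urgent: 13           # ELF at/above: urgent prognostic outcome

tsat_cutoff: 45          # %; iron overload above this
a1at_cutoff: 1.0         # g/L; possible A1AT deficiency below this
crp_elevated: 5          # mg/L; above this caeruloplasmin is not added
caeruloplasmin_cutoff: 0.20  # g/L; possible Wilson disease below this
crp_age_limit: 45        # years; CRP/caeruloplasmin cascade only under this
conjugated_fraction: 0.20    # direct/total below this = unconjugated pattern
haptoglobin_low: 0.3     # g/L; below this suggests haemolysis

malignancy_age: 40       # years; alert only over this (strict)
malignancy_alp: 130      # U/L (strict)
malignancy_platelets: 400    # 10^9/L (strict)
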