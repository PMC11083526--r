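# ilftr — intelligent liver function testing in R

Abnormal liver function tests (LFTs) are among the commonest abnormal
results in primary care, yet half are never followed up, and chronic
liver disease is routinely diagnosed only at decompensation. `ilftr`
implements the intelligent liver function testing (iLFT) approach to
this problem as a tested, configurable R library and command-line tool:
a rule-based expert system that, given a patient's demographics
(age, sex, BMI, alcohol > 14 units/week, metabolic syndrome) and a
first-line liver panel, decides which reflex assays cascade, computes
non-invasive fibrosis scores, interprets the aetiology screen, and
emits coded diagnostic outcomes with referral advice and an
auto-comment. It is aimed at laboratory scientists, hepatology
researchers and clinical-decision-support developers who need a
transparent, auditable reference implementation of reflex LFT
cascading.

The core logic, in brief:

* **Cascade tiers.** Full aetiology screen if ALT > 30 U/L, GGT > URL
  (60 U/L default), bilirubin > 60 µmol/L or ALP > 200 U/L; a limited
  cascade (direct bilirubin + haptoglobin) for mild isolated bilirubin
  elevations (22–60 µmol/L); a repeat-in-three-months advisory for mild
  isolated ALP (131–200 U/L); nothing otherwise. Multiple mild
  abnormalities escalate to the full screen (fail-safe).
* **Fibrosis.** FIB-4 = age·AST/(platelets·√ALT) banded at 1.30/2.67;
  NFS (the NAFLD fibrosis score) banded at −1.455/0.676, used for
  presumed MASLD/MetALD only; indeterminate or high indirect scores
  reflex the Enhanced Liver Fibrosis (ELF) score,
  2.278 + 0.851·ln HA + 0.751·ln PIIINP + 0.394·ln TIMP‑1, staged at
  7.7 / 9.8 / 11.3 with referral at ≥ 9.8 and an urgent prognostic
  outcome at ≥ 13.
* **Aetiology.** Transferrin saturation > 45% (iron), A1AT < 1.0 g/L,
  HBV/HCV serology, autoantibodies, and an age-gated (< 45), CRP-gated
  caeruloplasmin pathway for Wilson disease; Gilbert logic on the
  limited tier.
* **Outcomes.** A data-driven registry of coded outcomes (`iL…` for
  published codes, `iLX-*` for reconstructed ones) with referral
  policies, current MASLD/MetALD/ALD nomenclature, a marked-ALT
  (≥ 250 U/L) urgent pathway and an ALP > 130 + platelets > 400
  malignancy alert; one request can emit several outcomes, and
  significant fibrosis can never exit without a referral.

Every threshold lives in one YAML config
(`inst/extdata/default_thresholds.yaml`) so other sites' reference
limits can be substituted. A deterministic synthetic-cohort generator
(14 labelled clinical profiles, parameters in
`inst/extdata/profile_params.yaml`) makes every branch testable without
patient data.

## Worked example

```r
library(ilftr)

rec <- list(patient_id = "example-1", age = 58, sex = "female", bmi = 31,
            alcohol_over_14 = FALSE, metabolic_syndrome = TRUE,
            alt = 74, alp = 102, ggt = 68, bilirubin_total = 14, albumin = 43,
            ast = 41, platelets = 172, transferrin_saturation = 28, a1at = 1.6,
            hbv_positive = FALSE, hcv_positive = FALSE,
            autoantibody_positive = FALSE,
            ha = 120, piiinp = 13, timp1 = 260)
r <- classify_record(rec)
```

This 58-year-old with metabolic syndrome and an ALT of 74 U/L cascades
to the full screen (`r$tier` is `"full"`). Her FIB-4 is 1.607 —
between the 1.30 rule-out and 2.67 rule-in cutoffs — and her NFS is
−0.010, also indeterminate, so the ELF score reflexes: 10.469, in the
severe band (≥ 9.8). The aetiology screen is negative, so the
metabolic-syndrome flag determines the presumed aetiology:

```
tier: full
FIB-4: 1.607   NFS: -0.01   ELF: 10.469
indirect band: indeterminate   ELF band: severe
fibrosis category: significant_fibrosis
iL16 | MASLD with significant fibrosis | referral: routine
record referral: routine
```

with the auto-comment

> Pattern consistent with MASLD with evidence of significant fibrosis
> (FIB-4 1.607, NFS -0.01). Lifestyle modification is recommended.
> Consider routine referral to the liver clinic.

Had her ELF been below 9.8, the same record would have resolved to
`indeterminate_resolved_low` and outcome iL17 (MASLD without
significant fibrosis, no referral) — the reflex ELF step exists
precisely to spare such patients a specialist visit.

### Command line

```sh
Rscript inst/cli/ilft.R simulate --n 500 --seed 7 --output cohort
Rscript inst/cli/ilft.R run --input cohort.csv --output results
Rscript inst/cli/ilft.R summarize --input results.json
Rscript inst/cli/ilft.R fixture --full 8096 --limited 707 --none 2240 \
        --referral 2837 --output fixture.csv
```

`run` writes per-record JSON and flat CSV, a cohort summary and a log
of every rule that fired; malformed rows are rejected with line numbers
and a non-zero exit while the rest of the cohort continues.

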