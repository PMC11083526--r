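---
title: "The intelligent liver function testing pathway: rules, scores and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The intelligent liver function testing pathway: rules, scores and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ilftr)
```

`ilftr` implements a rule-based ("expert system") decision pathway for
abnormal liver function tests (LFTs) requested from primary care. The
pathway's job is threefold: decide from the first-line panel whether
second-line (reflex) assays should cascade; quantify the likelihood of
liver fibrosis with non-invasive scores; and return one or more coded
outcomes with a management comment and referral advice. This vignette is
the package's account of the science behind each stage, the parameters
that matter, and the design decisions taken where more than one
reasonable implementation existed.

## The cascade model

The first-line panel is ALT, ALP, GGT, total bilirubin and albumin
(albumin is collected for scoring but deliberately carries no trigger of
its own). Triggers are upper reference limits (URLs), with one
exception: the ALT trigger is a *screening* threshold of 30 U/L, below
typical laboratory URLs, because conventional ALT reference intervals
are inflated by subclinical liver disease in historical reference
populations. The ALT trigger is not sex-specific.

Four tiers partition the input space:

* **full** — ALT > 30 U/L, or GGT above its URL (60 U/L default), or
  bilirubin > 60 µmol/L, or ALP > 200 U/L. The full aetiology screen
  cascades: AST, iron studies, alpha-1 antitrypsin (A1AT), hepatitis B/C
  serology, liver autoantibodies; plus CRP when the patient is under 45,
  with caeruloplasmin added only if CRP is not elevated.
* **limited_bilirubin** — a mild (22–60 µmol/L), *isolated* bilirubin
  elevation: only direct bilirubin and haptoglobin are added, to
  distinguish Gilbert syndrome from haemolysis and conjugated patterns.
* **alp_advisory** — a mild (131–200 U/L), *isolated* ALP elevation: no
  assays are added; the outcome advises a repeat of ALP and GGT in three
  months (mild isolated ALP rises are commonly bone-derived, drug
  reactions or early MASLD).
* **none** — everything within limits.

Boundary semantics are fixed and boundary-tested: strict `>` at the
ALT/GGT/ALP triggers and at bilirubin 60; inclusive `≥ 22` for the mild
bilirubin band (consistent with a URL of 21 µmol/L). Two design rules
close gaps the tier definitions would otherwise leave open. First, if
bilirubin and ALP are *both* mildly elevated and nothing else is,
neither is an "only abnormality", and the record escalates to a full
screen — the pathway's general fail-safe principle is that uncertainty
escalates, never de-escalates. Second, the GGT URL is not part of the
published rule set; 60 U/L is a common UK URL and is configurable, as is
every other threshold, through one YAML file
(`inst/extdata/default_thresholds.yaml`).

```{r cascade}
evaluate_first_line(list(alt = 20, alp = 250, ggt = 30, bilirubin_total = 10),
                    list(age = 50))
```

## Fibrosis scoring

Two *indirect* scores are computed from routine measurements:

* FIB-4 = age·AST / (platelets·√ALT), banded low below 1.30 and high
  above 2.67;
* NFS = −1.675 + 0.037·age + 0.094·BMI + 1.13·dysglycaemia +
  0.99·AST/ALT − 0.013·platelets − 0.66·albumin(g/dL), banded low below
  −1.455 and high above 0.676, and consulted only when the working
  aetiology is presumed MASLD/MetALD.

Three decisions deserve note. The FIB-4/NFS cutoffs are the standard
rule-out/rule-in values from the score validation literature; the
production pathway does not publish its exact cutoffs, so these are
declared assumptions, pinned in config. The NFS dysglycaemia term
expects IFG/diabetes status, but the request form collects only a
metabolic-syndrome tick-box; that flag is used as a proxy and the
approximation is inherited by every NFS-dependent outcome. UK
laboratories report albumin in g/L while the NFS formula expects g/dL;
the ÷10 conversion is internal and unit-tested. When both scores are in
play the merge is maximum-severity: either high bands high, both low
band low, anything else is indeterminate — a rule-in is never overridden.

The *direct* marker is the Enhanced Liver Fibrosis (ELF) score, which
combines hyaluronic acid, PIIINP and TIMP-1:
ELF = 2.278 + 0.851·ln(HA) + 0.751·ln(PIIINP) + 0.394·ln(TIMP-1)
(the manufacturer's calibration; the coefficient set is config-pinned so
a recalibration can be swapped in). Stages are half-open intervals:
absent/mild < 7.7 ≤ moderate < 9.8 ≤ severe < 11.3 ≤ cirrhosis, with
9.8 doubling as the referral threshold and ≥ 13 carrying an urgent
prognostic outcome (high short-term decompensation risk).

ELF reflexes only when the indirect band is indeterminate or high.
The assessment then merges: low rules out; high rules in regardless of
ELF (fail-safe — ELF contributes staging and prognosis only);
indeterminate is resolved by ELF at the 9.8 threshold, or flagged
`indeterminate_unresolved` when ELF is unavailable, which itself maps to
a referral-for-assessment outcome (the pathway's behaviour before
direct markers were available). When AST or platelets are missing the
indirect band is `not_computable`; the policy adopted — one of two
defensible options — is to treat it like the indeterminate band (reflex
ELF and resolve, else refer) while retaining the flag, because silently
defaulting a missing score toward rule-out would invert the fail-safe.

```{r fibrosis}
compute_fib4(61, 60, 40, 150)
assess_fibrosis("indeterminate", elf = 10.2)$final_category
```

## The aetiology screen

Each screened aetiology resolves to positive / negative / not-tested:
iron overload at transferrin saturation > 45%; A1AT deficiency below
1.0 g/L (triggering reflex phenotyping advice); viral hepatitis and
autoantibodies as laboratory-adjudicated flags; and the Wilson pathway,
which is age-gated (under 45) and CRP-gated — caeruloplasmin is an
acute-phase reactant, so it is only added, and only interpretable, when
CRP ≤ 5 mg/L; the possible-Wilson call requires caeruloplasmin
< 0.20 g/L. The interpretation cutoffs are standard clinical values,
config-overridable, and declared as assumptions since the published
rule set does not print them. Ferritin is deliberately absent: iron
interpretation rests on transferrin saturation alone. On the limited
bilirubin tier, a conjugated fraction below 0.20 with haptoglobin
≥ 0.3 g/L yields "likely Gilbert syndrome"; low haptoglobin yields a
haemolysis pattern, and a high conjugated fraction a conjugated
(hepatobiliary) pattern.

A "negative liver screen" is implemented as *all cascaded findings
negative* — the published material never defines it numerically, so this
interpretation is explicit in the code and tests.

## Outcomes, precedence and nomenclature

Outcomes are data, not code: a tab-delimited registry maps each code to
its category (aetiological / descriptive / advisory / alert), referral
policy (none < phenotype_dependent < routine < urgent) and comment
template. Ten codes (`iL01`–`iL28` as published) carry their published
referral flags; the rest of the production pathway's 33 outcomes are
unpublished, so reconstructed outcomes use an `iLX-*` namespace that
cannot be mistaken for official codes.

A single request can emit several outcomes. Assembly order on a full
cascade: specific aetiological findings first; then a presumed
steatotic-liver-disease outcome from the lifestyle flags (alcohol +
metabolic syndrome → MetALD, alcohol → ALD, metabolic → MASLD, each
split by fibrosis category — MetALD uses the same NFS-enabled banding as
MASLD since a metabolic component is present); then, only when neither
flags nor findings explain the abnormality, a descriptive outcome keyed
to the abnormal-analyte pattern, falling back to an explicit generic
descriptive outcome for unmapped patterns (never a silent drop). The
marked-ALT rule (ALT ≥ 250 U/L, an urgent possible-acute-liver-injury
outcome) is a reconstruction implied by the "< 250 U/L" qualifier on the
most frequent published outcome. The malignancy alert (ALP > 130 U/L
and platelets > 400 ×10⁹/L, over 40, all strict) appends independently.
Lifestyle outcomes are emitted *alongside* specific aetiologies rather
than suppressed — the published data show more outcomes than cascades,
and alcohol misuse does not stop mattering because A1AT is low. Finally
the fail-safe: a significant-fibrosis category that would otherwise
leave the record without any referral-carrying outcome appends one, so
no significant-fibrosis record can ever exit with referral "none".

The 2023 steatotic liver disease renaming (NAFLD → MASLD, combined
category → MetALD) is the default vocabulary; a `legacy_nomenclature`
switch rewrites descriptions for regression comparison, demonstrating
that renames are registry edits, not engine changes.

## The synthetic cohort generator

No patient-level dataset is publicly deposited, so the package ships a
generator whose purpose is *branch coverage with known truth*, not
epidemiological realism. Each of 14 profiles (normal, ALD, MASLD,
MetALD, Gilbert, hepatitis B/C, iron, A1AT, autoimmune, Wilson,
malignancy-alert, marked-ALT, indeterminate-fibrosis) draws every
analyte from a truncated normal whose bounds are chosen so the profile's
intended branch fires essentially always — e.g. the ALD box keeps FIB-4
below 1.30 at its worst corner, and the indeterminate-fibrosis box keeps
FIB-4 inside (1.30, 2.67) everywhere. All parameters live in
`inst/extdata/profile_params.yaml`, not in code. True labels are
written to a sidecar file the classifier never reads; label-recovery of
at least 95% per profile on a 5000-record mixed cohort is a *generator
construction property* the tests verify, not a claim about classifier
accuracy on real patients. Real cohorts differ in every way that
matters for external validity: analyte correlations, mixed aetiologies,
boundary-straddling values, missingness and requesting behaviour. The
default eight-profile mixture (25% normal, 15% ALD, 15% MASLD, 10%
Gilbert, 10% iron, 10% A1AT, 10% malignancy-alert, 5% hepatitis C) is a
fixed, round-number case mix chosen for branch coverage.

```{r cohort}
coh <- generate_cohort(cohort_spec(5, seed = 7))
vapply(coh$records, function(r) classify_record(r)$tier, "")
```

## Reporting and numerical choices

Cohort summaries count cascade tiers over requests, outcomes over the
(larger) outcome total, and per-code shares against both denominators,
matching the two-denominator convention of published outcome tables.
Percentages round half-away-from-zero to one decimal — base R's
round-half-even would disagree at exact halves — and a zero denominator
yields an explicit undefined marker rather than an error. Summaries are
invariant to record order, with outcome rows sorted by descending count
and an alphabetical tie-break. The exact-marginals fixture
(`fixture_marginals()`) deterministically emits any requested tier
counts, with an option to engineer a chosen number of full-cascade
records into a referral via indeterminate FIB-4 resolved by reflex ELF —
referral thus arises from the pathway itself, never from a flag.

Problem sizes used by the test suite were chosen to keep the full run
around a minute on one CPU: 10,000 random inputs for score-formula
equivalence at 1e−9 relative tolerance, a 450-case threshold-straddling
grid for the cascade oracle, 5000 records for cohort-scale label
recovery, and the 11,043-record marginals fixture for the published
cascade and referral proportions.

## Known limitations

* The engine is a faithful rule system, not a learned model; its
  clinical validity is bounded by the rules it encodes.
* Unpublished production details — the full 33-outcome list, exact
  FIB-4/NFS cutoffs, the GGT URL, all aetiology-interpretation cutoffs —
  are reconstructed as declared, configurable assumptions.
* Virology and autoantibody results are modelled as adjudicated
  booleans; titres and confirmatory cascades are out of scope, as are
  A1AT phenotype interpretation, imaging/elastography, and any
  order-communications or LIMS integration.
* Cohort-level outcome *distributions* from the real service are not
  reproducible without its clinical data; the package reproduces the
  printed marginal proportions from engineered inputs and verifies the
  rule logic by construction instead.
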