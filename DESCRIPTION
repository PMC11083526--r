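Package: ilftr
Title: Intelligent Liver Function Testing: Reflex Cascades, Fibrosis Scores
    and Coded Diagnostic Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A rule-based clinical decision-support engine for abnormal liver
    function tests in primary care. Given a patient's demographics and a
    first-line liver panel, the package decides which reflex (cascade) tier
    fires and which second-line assays are added, computes the FIB-4, NAFLD
    fibrosis score (NFS) and Enhanced Liver Fibrosis (ELF) scores with
    rule-in/rule-out banding and reflex ELF resolution of the indeterminate
    zone, interprets the aetiology screen (iron studies, alpha-1 antitrypsin,
    viral serology, autoantibodies, the CRP-gated caeruloplasmin pathway and
    the Gilbert-syndrome logic), and emits one or more coded diagnostic
    outcomes with referral advice, urgency and auto-comment text, including a
    malignancy alert and current steatotic liver disease (MASLD / MetALD /
    ALD) nomenclature. A deterministic synthetic-cohort generator and
    cohort-level reporting (cascade rates, outcome frequency tables, referral
    proportions) make every pathway branch testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
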