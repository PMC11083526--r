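# Synthetic-cohort profile parameters.
#
# Every analyte is drawn from a normal distribution truncated to [min, max]
# (inverse-CDF sampling; all values positive by truncation). Units follow
# the record schema: enzymes U/L, bilirubin umol/L, albumin/haptoglobin/
# A1AT/caeruloplasmin g/L, platelets 10^9/L, CRP mg/L, transferrin
# saturation %, BMI kg/m^2, age years. `conjugated_fraction` is a pseudo-
# analyte: direct bilirubin = fraction * total. `flags` are Bernoulli
# probabilities. `omit` lists analytes left unmeasured (NA) for the
# profile. `expected_code` is the outcome family the profile is engineered
# to trigger; truncation bounds are chosen so the branch fires with
# probability ~1 under default thresholds.
#
# `base` supplies the within-limits defaults; profiles override only what
# drives their branch.

base:
  analytes:
    age:                    {mean: 48,   sd: 12,   min: 25,   max: 74}
    bmi:                    {mean: 26,   sd: 3,    min: 19,   max: 38}
    alt:                    {mean: 18,   sd: 5,    min: 5,    max: 28}
    alp:                    {mean: 80,   sd: 18,   min: 40,   max: 125}
    ggt:                    {mean: 30,   sd: 10,   min: 8,    max: 55}
    bilirubin_total:        {mean: 10,   sd: 4,    min: 2,    max: 20}
    albumin:                {mean: 43,   sd: 2,    min: 38,   max: 48}
    ast:                    {mean: 22,   sd: 4,    min: 12,   max: 30}
    platelets:              {mean: 260,  sd: 40,   min: 160,  max: 390}
    transferrin_saturation: {mean: 27,   sd: 6,    min: 12,   max: 42}
    a1at:                   {mean: 1.5,  sd: 0.2,  min: 1.1,  max: 2.4}
    crp:                    {mean: 2,    sd: 1,    min: 0.2,  max: 4.8}
    caeruloplasmin:         {mean: 0.30, sd: 0.04, min: 0.22, max: 0.45}
    conjugated_fraction:    {mean: 0.10, sd: 0.03, min: 0.03, max: 0.18}
    haptoglobin:            {mean: 1.2,  sd: 0.3,  min: 0.5,  max: 2.2}
    ha:                     {mean: 30,   sd: 8,    min: 12,   max: 55}
    piiinp:                 {mean: 6,    sd: 1.2,  min: 3.5,  max: 8.5}
    timp1:                  {mean: 80,   sd: 15,   min: 45,   max: 115}
  flags:
    alcohol_over_14: 0
    metabolic_syndrome: 0
    hbv_positive: 0
    hcv_positive: 0
    autoantibody_positive: 0
  p_male: 0.5

profiles:
  normal:
    expected_code: iLX-NORMAL
  ald:
    expected_code: iL05
    flags: {alcohol_over_14: 1}
    analytes:
      # FIB-4 stays below 1.30 across the whole truncation box
      age:       {mean: 38,  sd: 5,  min: 26,  max: 45}
      alt:       {mean: 85,  sd: 12, min: 60,  max: 120}
      ast:       {mean: 35,  sd: 3,  min: 28,  max: 42}
      platelets: {mean: 330, sd: 25, min: 285, max: 395}
      ggt:       {mean: 90,  sd: 25, min: 40,  max: 180}
  masld:
    expected_code: iL17
    flags: {metabolic_syndrome: 1}
    analytes:
      # both FIB-4 < 1.30 and NFS < -1.455 across the box
      age:       {mean: 34,  sd: 5,   min: 25,   max: 42}
      bmi:       {mean: 31,  sd: 1.2, min: 28.5, max: 33.5}
      alt:       {mean: 95,  sd: 15,  min: 70,   max: 128}
      ast:       {mean: 31,  sd: 3,   min: 25,   max: 38}
      platelets: {mean: 345, sd: 22,  min: 302,  max: 398}
      albumin:   {mean: 45,  sd: 1.4, min: 42,   max: 48}
  metald:
    expected_code: iLX-METALD-NF
    flags: {alcohol_over_14: 1, metabolic_syndrome: 1}
    analytes:
      age:       {mean: 34,  sd: 5,   min: 25,   max: 42}
      bmi:       {mean: 31,  sd: 1.2, min: 28.5, max: 33.5}
      alt:       {mean: 95,  sd: 15,  min: 70,   max: 128}
      ast:       {mean: 31,  sd: 3,   min: 25,   max: 38}
      platelets: {mean: 345, sd: 22,  min: 302,  max: 398}
      albumin:   {mean: 45,  sd: 1.4, min: 42,   max: 48}
      ggt:       {mean: 90,  sd: 25,  min: 40,   max: 180}
  gilbert:
    expected_code: iL06
    analytes:
      bilirubin_total:     {mean: 38,   sd: 6,     min: 26,   max: 54}
      conjugated_fraction: {mean: 0.10, sd: 0.025, min: 0.04, max: 0.17}
  viral_b:
    expected_code: iLX-VIRAL-B
    flags: {hbv_positive: 1}
    analytes:
      age:       {mean: 38,  sd: 5,  min: 26,  max: 45}
      alt:       {mean: 85,  sd: 12, min: 60,  max: 120}
      ast:       {mean: 35,  sd: 3,  min: 28,  max: 42}
      platelets: {mean: 330, sd: 25, min: 285, max: 395}
  viral_c:
    expected_code: iLX-VIRAL-C
    flags: {hcv_positive: 1}
    analytes:
      age:       {mean: 38,  sd: 5,  min: 26,  max: 45}
      alt:       {mean: 85,  sd: 12, min: 60,  max: 120}
      ast:       {mean: 35,  sd: 3,  min: 28,  max: 42}
      platelets: {mean: 330, sd: 25, min: 285, max: 395}
  iron:
    expected_code: iLX-IRON
    analytes:
      age:       {mean: 38,  sd: 5,  min: 26,  max: 45}
      alt:       {mean: 85,  sd: 12, min: 60,  max: 120}
      ast:       {mean: 35,  sd: 3,  min: 28,  max: 42}
      platelets: {mean: 330, sd: 25, min: 285, max: 395}
      transferrin_saturation: {mean: 62, sd: 7, min: 48, max: 80}
  a1at:
    expected_code: iL01
    analytes:
      age:       {mean: 38,   sd: 5,    min: 26,  max: 45}
      alt:       {mean: 85,   sd: 12,   min: 60,  max: 120}
      ast:       {mean: 35,   sd: 3,    min: 28,  max: 42}
      platelets: {mean: 330,  sd: 25,   min: 285, max: 395}
      a1at:      {mean: 0.75, sd: 0.08, min: 0.5, max: 0.92}
  autoimmune:
    expected_code: iLX-AUTOIMMUNE
    flags: {autoantibody_positive: 1}
    analytes:
      age:       {mean: 38,  sd: 5,  min: 26,  max: 45}
      alt:       {mean: 85,  sd: 12, min: 60,  max: 120}
      ast:       {mean: 35,  sd: 3,  min: 28,  max: 42}
      platelets: {mean: 330, sd: 25, min: 285, max: 395}
  wilson:
    expected_code: iLX-WILSON
    analytes:
      # under 45 so CRP cascades; CRP kept unelevated; caeruloplasmin low
      age:            {mean: 30,   sd: 5,    min: 20,   max: 42}
      alt:            {mean: 85,   sd: 12,   min: 60,   max: 120}
      ast:            {mean: 35,   sd: 3,    min: 28,   max: 42}
      platelets:      {mean: 330,  sd: 25,   min: 285,  max: 395}
      caeruloplasmin: {mean: 0.13, sd: 0.02, min: 0.08, max: 0.17}
  malignancy_alert:
    expected_code: iLX-MALIGNANCY
    analytes:
      age:       {mean: 58,  sd: 8,  min: 45,  max: 78}
      alp:       {mean: 260, sd: 30, min: 210, max: 340}
      platelets: {mean: 470, sd: 30, min: 415, max: 580}
  marked_alt:
    expected_code: iLX-ALT-MARKED
    analytes:
      alt: {mean: 320, sd: 40, min: 255, max: 480}
      ast: {mean: 180, sd: 30, min: 120, max: 260}
  indeterminate_fibrosis:
    expected_code: iLX-FIB-INDET
    omit: [ha, piiinp, timp1]
    analytes:
      # FIB-4 confined to the indeterminate zone; no ELF analytes measured
      age:       {mean: 60,  sd: 2.5, min: 55,  max: 65}
      alt:       {mean: 80,  sd: 5,   min: 70,  max: 90}
      ast:       {mean: 46,  sd: 2,   min: 42,  max: 50}
      platelets: {mean: 165, sd: 7,   min: 150, max: 180}
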