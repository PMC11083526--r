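code	category	referral_policy	description	comment_template
iL01	aetiological	phenotype_dependent	Possible alpha-1 antitrypsin deficiency	A1AT level {a1at} g/L is below 1.0 g/L. Reflex A1AT phenotyping has been initiated; referral advice depends on the phenotype result.
iL02	descriptive	none	Abnormal ALT, ALP and GGT and a negative liver screen without significant fibrosis	ALT {alt} U/L, ALP {alp} U/L and GGT {ggt} U/L are elevated with a negative liver screen and no evidence of significant fibrosis. Address metabolic and alcohol risk factors and repeat testing in primary care.
iL04	aetiological	routine	ALD with significant fibrosis	Pattern consistent with alcohol-related liver disease with evidence of significant fibrosis (FIB-4 {fib4}). Alcohol cessation support is recommended.
iL05	aetiological	none	ALD without significant fibrosis	Pattern consistent with alcohol-related liver disease without evidence of significant fibrosis. Manage in primary care with alcohol cessation support; repeat fibrosis assessment if abnormality persists.
iL06	aetiological	none	Likely Gilbert syndrome	Predominantly unconjugated hyperbilirubinaemia (total {bilirubin_total} umol/L, direct {direct_bilirubin} umol/L) without evidence of haemolysis (haptoglobin {haptoglobin} g/L). Likely Gilbert syndrome; a benign finding requiring no further investigation.
iL15	descriptive	none	Abnormal ALT (<250 U/L) and a negative liver screen without significant fibrosis	ALT {alt} U/L is elevated (below 250 U/L) with a negative liver screen and no evidence of significant fibrosis. Address metabolic and alcohol risk factors and repeat LFTs in primary care.
iL16	aetiological	routine	MASLD with significant fibrosis	Pattern consistent with MASLD with evidence of significant fibrosis (FIB-4 {fib4}, NFS {nfs}). Lifestyle modification is recommended.
iL17	aetiological	none	MASLD, simple steatosis without significant fibrosis	Pattern consistent with MASLD (simple steatosis) without evidence of significant fibrosis. Manage cardiometabolic risk factors in primary care; reassess fibrosis in 3 years.
iL21	advisory	none	Mild, isolated elevation in ALP	ALP {alp} U/L is mildly elevated in isolation. Potential causes include bone sources, drug reactions and MASLD. Repeat ALP and GGT testing in three months is recommended.
iL28	descriptive	none	Abnormal ALT and GGT and a negative liver screen without significant fibrosis	ALT {alt} U/L and GGT {ggt} U/L are elevated with a negative liver screen and no evidence of significant fibrosis. Address metabolic and alcohol risk factors and repeat testing in primary care.
iLX-NORMAL	advisory	none	Liver tests within limits	All first-line liver tests fall within the pathway limits. No further testing is required.
iLX-METALD-NF	aetiological	none	MetALD without significant fibrosis	Pattern consistent with combined metabolic dysfunction and alcohol-related steatotic liver disease (MetALD) without evidence of significant fibrosis. Manage risk factors in primary care with alcohol cessation support.
iLX-METALD-F	aetiological	routine	MetALD with significant fibrosis	Pattern consistent with MetALD with evidence of significant fibrosis (FIB-4 {fib4}, NFS {nfs}). Alcohol cessation support and lifestyle modification are recommended.
iLX-VIRAL-B	aetiological	routine	Positive hepatitis B serology	Hepatitis B serology is positive; confirmatory testing follows automatically.
iLX-VIRAL-C	aetiological	routine	Positive hepatitis C serology	Hepatitis C serology is positive; confirmatory testing follows automatically.
iLX-IRON	aetiological	routine	Possible haemochromatosis	Transferrin saturation {transferrin_saturation}% is elevated. Consider hereditary haemochromatosis; HFE genotyping is recommended.
iLX-AUTOIMMUNE	aetiological	routine	Possible autoimmune liver disease	Liver autoantibodies are positive. Consider autoimmune hepatitis, primary biliary cholangitis or SLE.
iLX-WILSON	aetiological	routine	Possible Wilson disease	Caeruloplasmin {caeruloplasmin} g/L is low in a patient under 45 with a normal CRP. Consider Wilson disease.
iLX-ALT-MARKED	alert	urgent	Marked ALT elevation (>=250 U/L)	ALT {alt} U/L indicates possible acute liver injury. Review the patient and consider urgent assessment of synthetic function, drug causes and acute viral hepatitis.
iLX-ELF-URGENT	alert	urgent	Very high ELF score	ELF score {elf} is 13 or above, carrying a high short-term risk of decompensation.
iLX-MALIGNANCY	alert	routine	Elevated ALP with thrombocytosis	The combination of ALP {alp} U/L above 130 U/L and platelets {platelets} x10^9/L above 400 in a patient over 40 is associated with undiagnosed malignancy. Consider malignancy and request appropriate further tests (for example CT chest/abdomen/pelvis, or tests guided by symptoms and signs).
iLX-FIB-INDET	descriptive	routine	Indeterminate fibrosis scores, unresolved	Indirect fibrosis scores are indeterminate and could not be resolved by ELF testing. Referral for further fibrosis assessment is recommended.
iLX-FIB-SIG	descriptive	routine	Significant fibrosis identified	Fibrosis assessment indicates significant fibrosis (FIB-4 {fib4}, ELF {elf}).
iLX-DESC	descriptive	none	Abnormal liver enzymes and a negative liver screen without significant fibrosis	Liver enzymes are abnormal ({abnormal_pattern}) with a negative liver screen and no evidence of significant fibrosis. Repeat testing and risk-factor management in primary care are recommended.
iLX-DESC-F	descriptive	routine	Abnormal liver enzymes and a negative liver screen with significant fibrosis	Liver enzymes are abnormal ({abnormal_pattern}) with a negative liver screen and evidence of significant fibrosis.
iLX-BILI-CONJ	descriptive	routine	Conjugated hyperbilirubinaemia	Direct bilirubin {direct_bilirubin} umol/L of total {bilirubin_total} umol/L indicates a conjugated pattern. Further investigation of hepatobiliary causes is recommended.
iLX-HAEMOLYSIS	descriptive	routine	Possible haemolysis	Haptoglobin {haptoglobin} g/L is low, suggesting haemolysis. Haematological assessment is recommended.
iLX-BILI-UNRES	descriptive	routine	Mild isolated hyperbilirubinaemia, subtype undetermined	Total bilirubin {bilirubin_total} umol/L is mildly elevated but direct bilirubin and haptoglobin results are unavailable, so the pattern could not be subtyped.
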