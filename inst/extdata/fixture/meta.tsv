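key	value
n_samples	162
n_cns_only	114
n_cns_plus_other	48
n_male	81
n_female	81
n_deep_wgs	136
n_lowpass_only	26
n_diagnosed	62
n_aneuploid_patients	18
n_cnv_patients	17
n_small_cnv_patients	3
n_snv_patients	24
n_cnv_events_gt100kb	21
n_snv_variants	26
n_aneuploids_called_lowpass	19
n_cnvs_called_lowpass	342
n_cnv_call_failed	3
n_small_cnv_qc_failed	4
n_carrier_incidental_secondary	8
note_accounting	patient-level accounting: 18 aneuploid + 17 CNV + 3 small-CNV + 24 SNV patients = 62 diagnosed; event-level accounting: 21 CNVs > 100 kb and 26 diagnostic SNVs (four patients carry two CNVs; two patients carry two SNVs; both accountings stored, neither resolved away)
note_curation	synthetic curation: subgroup/sex/phenotype assignment beyond named patients, and critical genes for seven syndromic CNV regions (PAFAH1B1, YWHAE, MNX1, ZIC2, HDAC4, DLL1, ACTB)
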