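patient_id	sex	age_at_diagnosis	treatment	lost_to_followup	relapse	relapse_site	relapse_months	death_months	followup_months	cnv_1p	cnv_3	cnv_6p	cnv_6q	cnv_8p	cnv_8q
UMB-009	F	78.3	brachytherapy	no	yes	Liver	3.1	16.3	16.3	none	LOH	ROH	LOH	LOH	Gain
UMB-003	M	62.5	brachytherapy	no	yes	Liver	6.0	11.5	11.5	none	LOH	none	none	LOH	Gain
UMB-005	M	71.9	brachytherapy	no	yes	Liver	7.5	23.4	23.4	none	LOH	none	none	none	Gain
UMB-004	M	53.5	enucleation	no	yes	Liver	12.3	37.7	37.7	LOH	LOH	none	LOH	LOH	Gain
UMB-006	F	22.3	brachytherapy	no	yes	Liver	24.9	58.9	58.9	none	none	none	none	none	none
UMB-001	M	65.7	brachytherapy	no	yes	Liver	60.0	NA	62.9	none	LOH	none	none	none	none
UMB-002	F	78.1	brachytherapy	no	no	NA	NA	NA	48.2	none	none	none	none	none	none
UMB-011	M	57.5	brachytherapy	no	no	NA	NA	NA	54.5	none	none	ROH	none	none	none
UMB-007	M	59.4	enucleation	yes	lost	NA	NA	NA	6.3	none	LOH	none	LOH	LOH	Gain
UMB-008	F	54.5	enucleation	yes	lost	NA	NA	NA	47.1	LOH	LOH	Gain	none	Gain	Gain
UMB-010	M	76.7	enucleation	yes	lost	NA	NA	NA	12.2	none	none	none	none	none	Gain
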