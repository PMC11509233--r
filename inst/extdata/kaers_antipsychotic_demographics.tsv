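field	category	count
sex	male	2871
sex	female	2126
age_group	<20	83
age_group	20-39	1050
age_group	40-59	1940
age_group	60-79	1089
age_group	80-99	30
causality	certain	74
causality	probable_likely	100
causality	possible	2656
reporter_type	pharma_company	4341
reporter_type	regional_pv_center	893
reporter_type	medical_professional	13
reporter_type	other	2
report_type	study_research	3834
report_type	voluntary	1071
report_type	other	344
disposition	recovered	3435
disposition	not_recovered	793
disposition	recovered_with_sequelae	75
disposition	unknown	946
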