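sample_id	age_at_assessment	self_reported_mi	self_reported_mi_age	self_reported_ops	diabetes	current_smoking	self_reported_high_cholesterol	family_history_father	family_history_mother	family_history_sibling	bmi	on_bp_meds	sbp	dbp
P01	60	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	25	FALSE	120	70
P02	60	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	26	FALSE	118	72
P03	55	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	24	FALSE	125	75
P04	60	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	27	FALSE	130	80
P05	58	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	26	FALSE	122	74
P06	60	TRUE	54	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	25	FALSE	120	70
P07	60	TRUE	54	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	25	FALSE	120	70
P08	60	FALSE	NA	TRUE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	25	FALSE	120	70
P09	55	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	30	FALSE	140	90
P10	55	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	30.1	FALSE	145	80
P11	55	FALSE	NA	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	FALSE	28	TRUE	110	70
P12	62	FALSE	NA	FALSE	TRUE	TRUE	TRUE	TRUE	FALSE	FALSE	31	TRUE	150	95
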