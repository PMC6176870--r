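sample_id	system	code	age_at_record	source
P01	ICD9	410.1	50	hospital
P02	ICD10	I21.4	63	hospital
P03	ICD10	I25.2	70	death
P04	OPCS4	K50.1	52	hospital
P05	OPCS4	K50.2	52	hospital
P05	ICD10	I25.1	50	hospital
P07	ICD9	411	57	hospital
P11	ICD10	E78.0	50	hospital
P12	OPCS4	K40	65	hospital
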