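sex	age_months	overweight_bmi	obese_bmi
F	120	19.86	23.81
F	132	20.55	24.77
F	144	21.20	25.66
F	156	21.85	26.49
F	168	22.45	27.20
F	180	22.98	27.76
M	120	19.84	23.60
M	132	20.40	24.39
M	144	20.97	25.17
M	156	21.56	25.93
M	168	22.17	26.67
M	180	22.77	27.35
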