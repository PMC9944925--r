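name	condition	mutations	activity
d01	optimal	7	0.85
d02	optimal	5	0.95
d03	optimal	7	0.70
d04	optimal	12	1.10
d05	low_mg	9	0.82
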