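glucose_uptake	o2_uptake	co2_production	actinorhodin_production	observed_dilution_rate
0.5	1.8	1.9	2	0.035
0.6	2	2	2	0.045
0.8	2.4	2.5	415	0.06
0.9	2.5	2.7	152	0.072
1.1	3.1	3.1	60	0.092
1.85	6.6	6.7	7	0.115
2.1	7.2	7	5	0.128
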