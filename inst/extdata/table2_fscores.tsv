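#source	published per-reader weighted f-scores of the lagged decision-prediction task
reader	tier	Cn	Cn-1	Cn-2	Cn-3	Cn-4	Cn-5	random_chance
N1	N	0.39	0.47	0.42	0.50	0.53	0.49	0.24
N2	N	0.85	0.90	0.87	0.85	0.89	0.87	0.27
N3	N	0.61	0.67	0.68	0.63	0.60	0.61	0.37
A1	A	0.30	0.39	0.29	0.31	0.34	0.40	0.29
A2	A	0.55	0.47	0.50	0.53	0.46	0.50	0.33
A3	A	0.57	0.59	0.63	0.63	0.68	0.67	0.33
A4	A	0.51	0.43	0.42	0.44	0.42	0.42	0.38
E1	E	0.51	0.57	0.53	0.49	0.52	0.48	0.29
E2	E	0.41	0.43	0.46	0.52	0.45	0.48	0.44
E3	E	0.38	0.51	0.54	0.43	0.50	0.53	0.28
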