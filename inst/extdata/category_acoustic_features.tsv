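category	rms_db	f0_mean	f0_sd	hnr	pssd	pscv	duration_s	centroid_khz
aggressive	-14.9	430	252	0.39	15.72	5.5	0.25	2.69
coo	-9.95	581	54	0.83	13.59	6.8	0.4	2.08
scream	-13.06	684	224	0.67	17.36	2.17	0.8	5.01
animal	-23.45	503	203	0.64	20.76	3.77	1	2.11
nature	-23.57	439	264	0.37	20.84	1.63	1	1.45
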