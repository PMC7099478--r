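model	cell	P0	P_muV	P_sigmaV	P_tauV	P_muV2	P_sigmaV2	P_tauV2	P_muVsigmaV	P_muVtauV	P_sigmaVtauV
adex	RS	-49.8	5.06	-23.4	2.3	-0.41	10.5	-36.6	7.4	1.2	-40.7
adex	FS	-51.5	4.0	-8.35	0.24	-0.50	1.43	-14.7	4.5	2.8	-15.3
hh	RS	-48.1	3.2	10.9	-0.32	0.98	1.1	-1.2e-3	-1.4	3.9	-0.11
hh	FS	-51.2	1.8	-6.1	-0.86	1.6	-0.70	-11	-0.18	1.2	-1.2
ml	RS	339	-218	-570	-1204	41.2	970	1724	297	186	-155
ml	FS	-0.615	-2.56	-17.6	-164	0.83	-55	108	-7.4	24.6	288
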