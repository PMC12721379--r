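ec	species	n_samples_ec_transcribed	n_samples_species_transcribes	prevalence
3.2.1.165	Species_001	12	12	1.000000
3.2.1.165	Species_007	12	12	1.000000
3.2.1.165	Species_016	12	12	1.000000
3.2.1.18	Species_001	12	12	1.000000
3.2.1.18	Species_007	12	12	1.000000
3.2.1.18	Species_017	12	12	1.000000
3.2.1.22	Species_001	12	12	1.000000
3.2.1.22	Species_011	12	12	1.000000
3.2.1.22	Species_017	12	12	1.000000
3.2.1.23	Species_002	12	11	0.916667
3.2.1.23	Species_011	12	12	1.000000
3.2.1.49	Species_002	12	11	0.916667
3.2.1.49	Species_011	12	12	1.000000
3.2.1.49	Species_012	12	12	1.000000
3.2.1.50	Species_006	12	12	1.000000
3.2.1.50	Species_012	12	12	1.000000
3.2.1.51	Species_006	12	12	1.000000
3.2.1.51	Species_012	12	12	1.000000
3.2.1.52	Species_006	12	12	1.000000
3.2.1.52	Species_012	12	11	0.916667
3.2.1.96	Species_006	12	12	1.000000
3.2.1.96	Species_016	12	12	1.000000
3.2.1.97	Species_007	12	12	1.000000
3.2.1.97	Species_016	12	12	1.000000
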