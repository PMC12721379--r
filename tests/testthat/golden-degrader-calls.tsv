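species	tier	transcribed_ecs
Species_001	prevalent_versatile	3.2.1.165;3.2.1.18;3.2.1.22
Species_002	prevalent_versatile	3.2.1.23;3.2.1.49
Species_006	prevalent_versatile	3.2.1.50;3.2.1.51;3.2.1.52;3.2.1.96
Species_007	prevalent_versatile	3.2.1.165;3.2.1.18;3.2.1.97
Species_011	prevalent_versatile	3.2.1.22;3.2.1.23;3.2.1.49
Species_012	prevalent_versatile	3.2.1.49;3.2.1.50;3.2.1.51;3.2.1.52
Species_016	prevalent_versatile	3.2.1.165;3.2.1.96;3.2.1.97
Species_017	prevalent_versatile	3.2.1.18;3.2.1.22
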