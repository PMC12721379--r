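# Mucin glycan degradation enzyme catalog: enzyme-commission numbers with
# CAZy glycoside hydrolase family assignments and detection summaries from
# 574 paired stool metagenomes/metatranscriptomes (prevalence %, mean copies
# per million, number of species mapped). EC 3.1.6.14 is marked inactive:
# reads were found in ~1% of samples and mapped to no reference genome.
# 3.2.1.22/3.2.1.23 are excluded from the versatility screen (galactose is
# widely available from dietary glycans, not specific to mucin).
ec_id	name	enzyme_class	gh_families	versatility_excluded	active	mg_prevalence_pct	mg_mean_cpm	mg_n_species	mt_prevalence_pct	mt_mean_cpm	mt_n_species
3.1.6.14	N-acetylglucosamine-6-sulfatase	sulfatase		FALSE	FALSE	1	0.05	0	1	0.05	0
3.2.1.165	Exo-1,4-beta-D-glucosaminidase	glycosyl_hydrolase	GH2;GH9	FALSE	TRUE	100	51.42	35	42	1.34	20
3.2.1.18	Exo-alpha-sialidase	glycosyl_hydrolase	GH33	FALSE	TRUE	99	19.65	19	43	1.90	13
3.2.1.22	Alpha-galactosidase	glycosyl_hydrolase	GH27;GH36;GH110	TRUE	TRUE	100	398.25	268	87	16.70	164
3.2.1.23	Beta-galactosidase	glycosyl_hydrolase	GH2;GH35;GH42	TRUE	TRUE	100	799.49	322	94	45.70	201
3.2.1.49	Alpha-N-acetylgalactosaminidase	glycosyl_hydrolase	GH27;GH36;GH109	FALSE	TRUE	94	11.20	11	16	0.26	10
3.2.1.50	Alpha-N-acetylglucosaminidase	glycosyl_hydrolase	GH89	FALSE	TRUE	94	39.56	9	34	0.78	9
3.2.1.51	Alpha-L-fucosidase	glycosyl_hydrolase	GH29;GH95	FALSE	TRUE	98	21.87	28	57	3.05	17
3.2.1.52	Beta-N-acetylhexosaminidase	glycosyl_hydrolase	GH20;GH84	FALSE	TRUE	100	187.31	177	85	17.90	85
3.2.1.96	Endo-beta-N-acetylglucosaminidase	glycosyl_hydrolase	GH18;GH85	FALSE	TRUE	99	32.12	36	80	16.98	21
3.2.1.97	Endo-alpha-N-acetylgalactosaminidase	glycosyl_hydrolase	GH101;GH129	FALSE	TRUE	30	0.35	6	5	0.11	4
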