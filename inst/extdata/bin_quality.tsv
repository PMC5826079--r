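bin_id	genome_size_mb	gc_pct	n_cds	n_contigs	completeness_pct	contamination_pct	strain_het_pct	source
CP1_1M	1.39	59	1182	138	42.28	1.81	50	Nakabusa Cone Pool 1
CP2_2F	1.99	59	1734	20	49.46	0	0	Nakabusa Cone Pool 2
CP2_20G	3.09	48	2678	852	78.54	3.55	33.33	Nakabusa Cone Pool 2
CP2_42A	3.3	59	2897	2024	79.44	10.42	16.13	Nakabusa Cone Pool 2
JP1_8	2.21	51	1973	601	58.13	0.13	0	Jinata Pool 1
JP1_16	4.06	44	3238	1764	95.15	17.31	0	Jinata Pool 1
JP1_20	3.36	46	2878	1139	79.09	4.78	20	Jinata Pool 1
JP1_191	0.417	47	334	883	10.63	1.8	0	Jinata Pool 1
JP3_7	3.62	63	3078	1331	87	12.85	7.32	Jinata Pool 3
JP3_13	3.67	60	3116	1259	96.17	10.87	75	Jinata Pool 3
Kouleothrix_aurantiaca	8.7	62	8993	5539	85	0	0	Isolate from wastewater sludge
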