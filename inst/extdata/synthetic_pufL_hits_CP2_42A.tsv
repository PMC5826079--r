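pufL	contig_0042	71.3	262	75	1	5	266	12	273	3.1e-112	331
pufL	contig_0187	38.5	120	70	3	40	158	2	118	2.4e-12	61
pufM	contig_0042	66.0	291	97	2	8	296	301	590	5.5e-108	322
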