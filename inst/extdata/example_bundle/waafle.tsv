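sample_id	n_hgt_contigs	n_contigs	species_richness
DF01|donation1	0	6018	4
DM01|donation1	0	4228	4
TFP01|baseline	0	5021	3
TFP01|week12	0	4988	6
TFP01|week26	2	5161	6
TFP01|week6	0	5637	6
TFT01|baseline	0	4637	3
TFT01|week12	2	5842	4
TFT01|week26	0	4375	3
TFT01|week6	1	5135	3
TMP01|baseline	1	4986	3
TMP01|week12	1	4831	3
TMP01|week26	1	4872	4
TMP01|week6	2	5541	4
TMT01|baseline	0	5636	4
TMT01|week12	3	4849	5
TMT01|week26	3	4504	5
TMT01|week6	2	5326	4
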