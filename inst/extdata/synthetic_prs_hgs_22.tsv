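variant_id	chromosome	position	effect_allele	other_allele	weight	effect_allele_frequency
synhgs_rs103003	5	3042267	T	C	0.0239	0.5368
synhgs_rs242215	9	4561079	C	T	-0.0188	0.7362
synhgs_rs787900	14	15988925	A	G	0.0923	0.2247
synhgs_rs618830	17	29375037	A	G	-0.0021	0.1853
synhgs_rs219546	10	32296525	T	C	-0.0521	0.2609
synhgs_rs423863	15	43460231	A	G	0.0431	0.5723
synhgs_rs514364	20	44735362	G	A	0.0308	0.8354
synhgs_rs866455	2	45778466	C	T	-0.0477	0.7812
synhgs_rs681816	1	58503403	T	C	0.0862	0.487
synhgs_rs141874	22	76992693	G	A	0.0027	0.5749
synhgs_rs395137	17	91935933	G	A	-0.0976	0.1313
synhgs_rs302549	22	103585392	C	T	0.0095	0.2937
synhgs_rs268007	13	113320570	T	C	-0.0626	0.7636
synhgs_rs834400	7	126038705	A	G	0.0384	0.224
synhgs_rs442580	16	135130890	G	A	0.0177	0.8635
synhgs_rs568122	20	146509970	A	G	-0.0241	0.8678
synhgs_rs540581	14	150153625	G	A	-0.0247	0.7838
synhgs_rs712379	1	158775176	A	G	0.0412	0.8903
synhgs_rs149750	19	167770492	C	T	0.0501	0.4891
synhgs_rs297129	16	168432829	T	C	0.0234	0.5779
synhgs_rs594130	12	170286504	T	C	0.0077	0.3085
synhgs_rs573121	16	178045609	A	G	0.041	0.1182
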