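variant_id	chromosome	position	effect_allele	other_allele	weight	effect_allele_frequency
syneoc_rs642437	8	4735290	C	T	0.0959	0.9459
syneoc_rs372248	14	5169051	G	A	0.0349	0.6436
syneoc_rs798680	5	11650109	T	C	-0.0172	0.6558
syneoc_rs149011	6	18445026	C	T	-0.0304	0.6903
syneoc_rs604299	12	38846515	G	A	0.0096	0.4597
syneoc_rs369164	9	45818981	G	A	-0.0441	0.1175
syneoc_rs226256	2	53748883	T	C	0.0211	0.4401
syneoc_rs245333	17	56268724	G	A	-0.0204	0.8402
syneoc_rs259177	9	73540107	G	A	0.007	0.5929
syneoc_rs321963	10	73966468	T	C	0.0303	0.1652
syneoc_rs881409	16	79477022	C	T	-0.0455	0.8052
syneoc_rs816712	20	80063863	T	C	0.1003	0.3237
syneoc_rs539064	19	80692473	T	C	-0.0203	0.2142
syneoc_rs845236	18	94135751	A	G	-0.0171	0.7797
syneoc_rs500747	2	105564900	G	A	0.0587	0.4743
syneoc_rs284599	22	113240752	A	G	0.0129	0.6694
syneoc_rs434845	6	113680326	C	T	0.0078	0.6615
syneoc_rs770267	12	115779622	A	G	-2e-04	0.6736
syneoc_rs764087	5	115937913	A	G	0.0952	0.3576
syneoc_rs520506	14	120768234	A	G	-0.021	0.7078
syneoc_rs394163	9	122402287	G	A	0.0227	0.4713
syneoc_rs398563	14	124146540	A	G	-0.0583	0.1772
syneoc_rs680773	12	140306932	A	G	-0.0049	0.1863
syneoc_rs848170	12	168406232	C	T	0.0045	0.5222
syneoc_rs356237	15	187680400	C	T	-0.0467	0.0885
syneoc_rs699295	9	188976898	T	C	-0.0071	0.3699
syneoc_rs359219	21	192969075	T	C	-0.0028	0.4009
syneoc_rs633756	4	195040003	G	A	-0.005	0.7894
syneoc_rs512068	10	195700034	A	G	-0.081	0.1014
syneoc_rs250417	7	199854228	A	G	-0.0014	0.6902
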