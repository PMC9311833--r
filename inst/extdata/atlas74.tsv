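id	name	hemisphere	partner_id	class
1	superior_frontal_gyrus_L	left	2	cortical
2	superior_frontal_gyrus_R	right	1	cortical
3	middle_frontal_gyrus_L	left	4	cortical
4	middle_frontal_gyrus_R	right	3	cortical
5	inferior_frontal_gyrus_L	left	6	cortical
6	inferior_frontal_gyrus_R	right	5	cortical
7	rectus_gyrus_L	left	8	cortical
8	rectus_gyrus_R	right	7	cortical
9	medial_fronto_orbital_gyrus_L	left	10	cortical
10	medial_fronto_orbital_gyrus_R	right	9	cortical
11	lateral_fronto_orbital_gyrus_L	left	12	cortical
12	lateral_fronto_orbital_gyrus_R	right	11	cortical
13	precentral_gyrus_L	left	14	cortical
14	precentral_gyrus_R	right	13	cortical
15	postcentral_gyrus_L	left	16	cortical
16	postcentral_gyrus_R	right	15	cortical
17	superior_parietal_lobule_L	left	18	cortical
18	superior_parietal_lobule_R	right	17	cortical
19	supramarginal_gyrus_L	left	20	cortical
20	supramarginal_gyrus_R	right	19	cortical
21	angular_gyrus_L	left	22	cortical
22	angular_gyrus_R	right	21	cortical
23	precuneus_L	left	24	cortical
24	precuneus_R	right	23	cortical
25	cingulate_gyrus_L	left	26	cortical
26	cingulate_gyrus_R	right	25	cortical
27	cuneus_L	left	28	cortical
28	cuneus_R	right	27	cortical
29	lingual_gyrus_L	left	30	cortical
30	lingual_gyrus_R	right	29	cortical
31	superior_occipital_gyrus_L	left	32	cortical
32	superior_occipital_gyrus_R	right	31	cortical
33	middle_occipital_gyrus_L	left	34	cortical
34	middle_occipital_gyrus_R	right	33	cortical
35	inferior_occipital_gyrus_L	left	36	cortical
36	inferior_occipital_gyrus_R	right	35	cortical
37	fusiform_gyrus_L	left	38	cortical
38	fusiform_gyrus_R	right	37	cortical
39	superior_temporal_gyrus_L	left	40	cortical
40	superior_temporal_gyrus_R	right	39	cortical
41	middle_temporal_gyrus_L	left	42	cortical
42	middle_temporal_gyrus_R	right	41	cortical
43	inferior_temporal_gyrus_L	left	44	cortical
44	inferior_temporal_gyrus_R	right	43	cortical
45	parahippocampal_gyrus_L	left	46	cortical
46	parahippocampal_gyrus_R	right	45	cortical
47	entorhinal_area_L	left	48	cortical
48	entorhinal_area_R	right	47	cortical
49	insular_cortex_L	left	50	cortical
50	insular_cortex_R	right	49	cortical
51	hippocampus_L	left	52	subcortical
52	hippocampus_R	right	51	subcortical
53	amygdala_L	left	54	subcortical
54	amygdala_R	right	53	subcortical
55	caudate_nucleus_L	left	56	subcortical
56	caudate_nucleus_R	right	55	subcortical
57	putamen_L	left	58	subcortical
58	putamen_R	right	57	subcortical
59	globus_pallidus_L	left	60	subcortical
60	globus_pallidus_R	right	59	subcortical
61	thalamus_L	left	62	subcortical
62	thalamus_R	right	61	subcortical
63	nucleus_accumbens_L	left	64	subcortical
64	nucleus_accumbens_R	right	63	subcortical
65	red_nucleus_L	left	66	subcortical
66	red_nucleus_R	right	65	subcortical
67	substantia_nigra_L	left	68	subcortical
68	substantia_nigra_R	right	67	subcortical
69	midbrain_L	left	70	subcortical
70	midbrain_R	right	69	subcortical
71	cerebellum_L	left	72	subcortical
72	cerebellum_R	right	71	subcortical
73	pons	midline	73	subcortical
74	medulla	midline	74	subcortical
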