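region_id,region_label
1,caudate_nucleus_l
2,caudate_nucleus_r
3,nucleus_accumbens_l
4,nucleus_accumbens_r
5,putamen_l
6,putamen_r
7,pallidum_l
8,pallidum_r
9,substantia_nigra_l
10,substantia_nigra_r
11,thalamus_l
12,thalamus_r
13,amygdala_l
14,amygdala_r
15,hippocampus_l
16,hippocampus_r
17,parahippocampal_ambient_gyrus_l
18,parahippocampal_ambient_gyrus_r
19,insula_l
20,insula_r
21,cingulate_gyrus_anterior_l
22,cingulate_gyrus_anterior_r
23,cingulate_gyrus_posterior_l
24,cingulate_gyrus_posterior_r
25,presubgenual_frontal_cortex_l
26,presubgenual_frontal_cortex_r
27,subgenual_frontal_cortex_l
28,subgenual_frontal_cortex_r
29,subcallosal_area_l
30,subcallosal_area_r
31,superior_temporal_gyrus_anterior_l
32,superior_temporal_gyrus_anterior_r
33,medial_orbital_gyrus_l
34,medial_orbital_gyrus_r
35,anterior_orbital_gyrus_l
36,anterior_orbital_gyrus_r
37,lateral_orbital_gyrus_l
38,lateral_orbital_gyrus_r
39,posterior_orbital_gyrus_l
40,posterior_orbital_gyrus_r
41,superior_frontal_gyrus_l
42,superior_frontal_gyrus_r
43,middle_frontal_gyrus_l
44,middle_frontal_gyrus_r
45,inferior_frontal_gyrus_l
46,inferior_frontal_gyrus_r
47,precentral_gyrus_l
48,precentral_gyrus_r
49,straight_gyrus_l
50,straight_gyrus_r
51,frontal_operculum_l
52,frontal_operculum_r
53,frontal_medial_cortex_l
54,frontal_medial_cortex_r
55,superior_temporal_gyrus_posterior_l
56,superior_temporal_gyrus_posterior_r
57,middle_inferior_temporal_gyrus_l
58,middle_inferior_temporal_gyrus_r
59,anterior_temporal_lobe_medial_l
60,anterior_temporal_lobe_medial_r
61,anterior_temporal_lobe_lateral_l
62,anterior_temporal_lobe_lateral_r
63,fusiform_gyrus_l
64,fusiform_gyrus_r
65,posterior_temporal_lobe_l
66,posterior_temporal_lobe_r
67,planum_temporale_l
68,planum_temporale_r
69,lingual_gyrus_l
70,lingual_gyrus_r
71,cuneus_l
72,cuneus_r
73,lateral_occipital_lobe_l
74,lateral_occipital_lobe_r
75,postcentral_gyrus_l
76,postcentral_gyrus_r
77,superior_parietal_gyrus_l
78,superior_parietal_gyrus_r
79,inferior_lateral_parietal_lobe_l
80,inferior_lateral_parietal_lobe_r
81,precuneus_l
82,precuneus_r
83,brainstem
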