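# Published nearest-centroid classification of the 21-AK validation cohort:
# per-sample histopathological grade, Euclidean distances to the reference
# NL and L centroids in signature-PCA space, and the published subclass.
sample_id	grade	dist_to_NL	dist_to_L	classification
001_C_AK	AK_I	6.58	19.58	AK_NL
006_A_AK	AK_II	25.09	3.19	AK_L
016_B_AK	AK_I	6.60	19.09	AK_NL
017_A_AK	AK_I	2.62	25.89	AK_NL
028_F_AK	AK_II	28.06	8.21	AK_L
029_C_AK	AK_II	3.22	21.54	AK_NL
041_A_AK	AK_III	4.73	23.30	AK_NL
048_F_AK	AK_I	5.37	19.38	AK_NL
056_B_AK	AK_I	17.39	7.48	AK_L
075_U_AK	AK_I	3.87	21.06	AK_NL
077_B_AK_1	AK_I	4.37	20.82	AK_NL
077_B_AK_2	AK_I	11.55	13.42	AK_NL
082_al_AK	AK_III	18.73	8.62	AK_L
082_B_AK_1	AK_I	13.85	11.14	AK_L
082_B_AK_2	AK_I	13.87	11.08	AK_L
090_A_AK	AK_I	5.98	19.69	AK_NL
109_C_AK_1	AK_I	0.26	24.91	AK_NL
109_C_AK_2	AK_II	13.58	11.31	AK_L
115_F_AK	AK_II	18.38	6.72	AK_L
119_C_AK_1	AK_I	14.99	11.23	AK_L
119_C_AK_2	AK_I	10.21	16.26	AK_NL
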