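trait	loci	a_effects	d_effects	i_effects	R2_a	R2_d	R2_i	total_R2
Body weight	8	7	0	1	26.35	0	2.71	29.06
Muscle mass	7	6	1	0	19.08	4.03	0	23.11
Fat mass	5	4	0	0	39.36	0	0	39.36
Lean mass	7	7	0	0	15.28	0	0	15.28
Glycolytic potential	1	0	0	1	0	0	4.66	4.66
M. quadriceps	5	4	1	0	6.15	1.25	0	7.40
M. longissimus	5	5	0	0	14.60	0	0	14.60
Glycogen content	1	0	0	1	0	0	4.05	4.05
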