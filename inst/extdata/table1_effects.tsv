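qtl	trait	chromosome	pos_Mb	pos_cM	ci_lo_cM	ci_hi_cM	mLOD	aLOD	dLOD	iLOD	mLOD_sig	aLOD_sig	dLOD_sig	iLOD_sig
Mc1.1	Body weight	1	34.6	13.3	13.33	44.4	4.91	4.89	0.88	0.45	TRUE	TRUE	FALSE	FALSE
Mc1.1	Lean mass	1	34.6	13.3	13.33	44.4	3.6	3.53	1.03	0.24	TRUE	TRUE	FALSE	FALSE
Mc1.1	Glycolytic potential	1	34.6	13.3	13.33	13.33	0.92	0.56	1.68	0.09	FALSE	FALSE	TRUE	FALSE
Mc1.1	Fat mass	1	34.6	13.3	13.33	40.2	2.28	3.21	0.81	0.13	TRUE	TRUE	FALSE	FALSE
Mc1.1	M. quadriceps	1	34.6	13.3	13.33	13.33	1.56	2.02	0.31	0.39	TRUE	TRUE	FALSE	FALSE
Mc1.1	M. longissimus	1	34.6	13.3	13.33	26.7	1.13	1.87	0.16	0.09	FALSE	TRUE	FALSE	FALSE
Mc1.1	Muscle mass	1	34.6	13.3	13.33	13.33	1.44	2.17	0.21	0.02	TRUE	TRUE	FALSE	FALSE
Mc2.1	M. longissimus	2	82.0	49.1	49.1	54.1	3.08	3.55	1.23	1.23	TRUE	TRUE	FALSE	FALSE
Mc2.1	Lean mass	2	82.0	49.1	49.1	54.1	2.86	3.53	1.47	0.96	TRUE	TRUE	TRUE	FALSE
Mc2.1	M. quadriceps	2	82.0	49.1	49.1	54.1	4.02	4.59	1.06	1.15	TRUE	TRUE	FALSE	FALSE
Mc2.1	Body weight	2	82.0	49.1	49.1	54.1	1.86	2.72	1.24	0.45	TRUE	TRUE	FALSE	FALSE
Mc2.1	Muscle mass	2	82.0	49.1	49.1	54.1	4.35	4.94	1.46	1.26	TRUE	TRUE	TRUE	FALSE
Mc6.1	M. longissimus	6	12.1	5.3	1.8	11.2	3.30	3.39	0.51	1.36	TRUE	TRUE	FALSE	TRUE
Mc8.1	M. longissimus	8	79.4	36.3	33.1	36.3	2.74	3.69	1.14	0.20	TRUE	TRUE	FALSE	FALSE
Mc8.1	Muscle mass	8	79.4	36.3	33.1	36.3	2.94	3.97	1.12	0.09	TRUE	TRUE	FALSE	FALSE
Mc12.1	Body weight	12	27.3	9.7	9.7	28.7	2.24	0.21	0.34	3.30	TRUE	FALSE	FALSE	TRUE
Mc12.2	Fat mass	12	91.4	43.9	51.4	61.2	2.17	3.30	0.11	0.01	TRUE	TRUE	FALSE	FALSE
Mc15.1	Muscle mass	15	10.3	58.7	58.7	58.7	2.57	0.19	3.32	0.13	TRUE	FALSE	TRUE	FALSE
Mc15.1	M. quadriceps	15	10.3	58.7	50.4	58.7	3.29	0.41	4.08	0.01	TRUE	FALSE	TRUE	FALSE
Mc17.1	Body weight	17	77.6	48.1	58.1	60.9	2.87	3.63	0.07	0.88	TRUE	TRUE	FALSE	FALSE
Mc19.1	Glycolytic potential	19	28.9	23.5	23.5	23.5	3.91	0.49	1.30	3.33	TRUE	FALSE	FALSE	TRUE
Mc19.1	Body weight	19	28.9	23.5	23.53	29.8	1.77	1.23	0.09	1.93	TRUE	FALSE	FALSE	TRUE
Mc19.1	Glycogen content	19	28.9	23.5	23.53	23.53	2.60	0.43	0.50	2.94	TRUE	FALSE	FALSE	TRUE
Mc19.1	Lean mass	19	28.9	23.5	23.53	23.53	2.21	1.5	0.01	2.20	TRUE	FALSE	FALSE	TRUE
Mc19.1	M. longissimus	19	28.9	23.5	23.53	29.8	1.91	0.39	0.06	2.78	TRUE	FALSE	FALSE	TRUE
Mc19.1	Muscle mass	19	28.9	23.5	23.53	29.8	2.07	0.40	0.05	2.82	TRUE	FALSE	FALSE	TRUE
Mc19.1	M. quadriceps	19	28.9	23.5	23.53	38.8	1.69	0.39	0.54	1.87	TRUE	FALSE	FALSE	TRUE
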