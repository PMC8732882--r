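label	pct_a	pct_c	pct_g	pct_t	pct_at	at_skew	gc_skew	length_bp
ribosomal RNA	37.92	21.54	17.74	22.80	60.72	0.2490	-0.0967	2526
12S ribosomal RNA	36.87	22.92	17.92	22.29	59.16	0.2465	-0.1224	960
16S ribosomal RNA	38.57	20.69	17.62	23.12	61.69	0.2504	-0.0801	1566
protein-coding genes	31.84	29.35	13.28	25.53	57.37	0.1100	-0.3770	11396
ND1	33.02	29.99	12.23	24.76	57.78	0.1430	-0.4207	957
ND2	37.63	30.80	9.14	22.43	60.06	0.2531	-0.5423	1039
COX1	28.43	27.21	15.51	27.85	56.28	0.0103	-0.2739	1551
COX2	32.16	28.95	13.74	25.15	57.31	0.1223	-0.3563	684
ATP8	38.81	29.85	7.46	23.88	62.69	0.2382	-0.6001	201
ATP6	33.33	32.89	10.72	23.06	56.39	0.1821	-0.5084	681
COX3	26.79	30.99	16.33	25.89	52.68	0.0171	-0.3098	784
ND3	34.29	31.70	10.95	23.06	57.35	0.1958	-0.4865	347
ND4L	31.98	29.97	11.45	26.60	58.58	0.0918	-0.4471	297
ND4	33.67	31.57	11.25	23.51	57.18	0.1777	-0.4745	1378
ND5	34.93	30.41	9.88	24.78	59.71	0.1700	-0.5096	1812
ND6	16.38	8.57	32.57	42.48	58.86	-0.4434	0.5834	525
CYTB	30.53	31.67	13.86	23.94	54.47	0.1210	-0.3912	1140
transfer RNA	36.46	20.94	15.38	27.22	63.68	0.1451	-0.1531	1495
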