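rank	mirna	control_tmm	lowhz_tmm	highhz_tmm	lowhz_fc	highhz_fc
1	miR-206-3p	342,377	397,949	478,669	1.16	1.40
2	miR-378a-3p	71,599	80,637	86,447	1.13	1.21
3	miR-1a-3p	56,905	36,453	41,928	0.64	0.74
4	let-7c-5p	40,238	37,980	34,416	0.94	0.85
5	miR-21a-5p	31,768	29,417	27,469	0.93	0.87
6	let-7f-5p	31,190	25,783	25,425	0.83	0.82
7	miR-378d	22,959	26,441	24,844	1.15	1.08
8	let-7a-5p	16,117	12,524	11,483	0.78	0.72
9	let-7b-5p	12,007	11,423	9488	0.95	0.79
10	let-7i-5p	10,359	11,983	8541	1.16	0.83
11	miR-378c	10,216	11,490	11,533	1.13	1.13
12	miR-26a-5p	9825	9084	8425	0.93	0.86
13	miR-486a-5p	18,428	8002	8326	0.43	0.45
14	miR-486b-5p	18,782	7780	7910	0.41	0.42
15	miR-128-3p	6499	6320	7012	0.97	1.08
16	miR-99a-5p	6839	6513	6647	0.95	0.97
17	miR-320-3p	6323	4783	6680	0.76	1.06
18	miR-143-3p	5294	4638	3689	0.88	0.70
19	miR-99b-5p	5231	3024	3406	0.58	0.65
20	miR-532-5p	4598	5431	5716	1.18	1.24
21	let-7d-5p	4963	2986	3090	0.60	0.62
22	miR-196a-5p	3870	2744	2609	0.72	0.64
23	miR-27b-3p	3768	3595	3290	0.95	0.87
24	let-7g-5p	3461	2957	2393	0.85	0.69
25	miR-24-3p	3483	3962	5168	1.14	1.48
26	miR-30d-5p	3346	2937	2891	0.88	0.86
27	miR-378b	3332	3073	3340	0.92	1.00
28	miR-615-3p	2998	1179	1362	0.39	0.46
29	miR-501-3p	2668	2068	3223	0.78	1.21
30	miR-27a-3p	2743	2396	1911	0.87	0.70
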