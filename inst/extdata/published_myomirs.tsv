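rank	mirna	control_tmm	lowhz_tmm	highhz_tmm	lowhz_fc	highhz_fc	function_note
1	miR-206-3p	342,377	397,949	478,669	1.16	1.40	Differentiation
3	miR-1a-3p	56,905	36,453	41,928	0.64	0.74	Differentiation
13	miR-486a-5p	18,428	8002	8326	0.43	0.45	Migration, Fusion, Differentiation
14	miR-486b-5p	18,782	7780	7910	0.41	0.42	Migration, Fusion, Differentiation
50	miR-133a-3p	1045	2967	2243	2.84	2.15	Proliferation, Fusion, Differentiation
88	miR-133b-3p	234	1662	931	7.08	3.97	Fusion, Differentiation
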