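organism	species	condition	wamt_printed	du_printed	du_discrepant
LR1	Candida zeylanoides	co2_10C	7.7	1.49	FALSE
LR1	Candida zeylanoides	control_10C	8.7	1.44	FALSE
LR1	Candida zeylanoides	control_25C	11.5	1.36	FALSE
WT2	Pichia fermentans	co2_10C	6.4	1.56	FALSE
WT2	Pichia fermentans	control_10C	7.6	1.41	FALSE
WT2	Pichia fermentans	control_25C	9.9	1.39	FALSE
WT5	Stenotrophomyces fumitolerans	co2_10C	7.0	0.94	FALSE
WT5	Stenotrophomyces fumitolerans	control_10C	8.4	0.92	FALSE
WT5	Stenotrophomyces fumitolerans	control_25C	10.0	0.91	FALSE
WR1	Stenotrophomyces fumitolerans	co2_10C	8.3	0.91	FALSE
WR1	Stenotrophomyces fumitolerans	control_10C	8.2	0.91	FALSE
WR1	Stenotrophomyces fumitolerans	control_25C	10.4	0.89	FALSE
WT6	Apiotrichum gracile	co2_10C	8.7	1.57	FALSE
WT6	Apiotrichum gracile	control_10C	17.2	1.13	FALSE
WT6	Apiotrichum gracile	control_25C	14.9	1.30	FALSE
WT7	Candida oleophila	co2_10C	8.9	1.37	TRUE
WT7	Candida oleophila	control_10C	12.6	1.22	FALSE
WT7	Candida oleophila	control_25C	15.2	1.22	FALSE
HT4	Candida sake	co2_10C	8.2	1.45	FALSE
HT4	Candida sake	control_10C	14.6	1.10	FALSE
HT4	Candida sake	control_25C	12.8	1.19	FALSE
M3	Rhodotorula alborubescens	co2_10C	6.4	1.65	FALSE
M3	Rhodotorula alborubescens	control_10C	17.9	1.14	FALSE
M3	Rhodotorula alborubescens	control_25C	19.0	1.06	FALSE
M12	Rhodotorula babjevae	co2_10C	19.2	1.70	TRUE
M12	Rhodotorula babjevae	control_10C	28.7	1.48	TRUE
M12	Rhodotorula babjevae	control_25C	22.1	1.38	TRUE
IF2SW-F4	Penicillium rubens	co2_10C	4.7	1.89	FALSE
IF2SW-F4	Penicillium rubens	control_10C	10.0	1.64	FALSE
IF2SW-F4	Penicillium rubens	control_25C	8.0	1.63	FALSE
DSM 1075	Penicillium rubens	co2_10C	3.6	1.97	FALSE
DSM 1075	Penicillium rubens	control_10C	6.8	1.91	FALSE
DSM 1075	Penicillium rubens	control_25C	7.0	1.72	FALSE
HR2	Penicillium griseofulvum	co2_10C	2.7	1.80	FALSE
HR2	Penicillium griseofulvum	control_10C	6.0	1.74	FALSE
HR2	Penicillium griseofulvum	control_25C	6.8	1.59	FALSE
LT1	Didymella corylicola	co2_10C	6.8	1.59	FALSE
LT1	Didymella corylicola	control_10C	15.5	1.17	FALSE
LT1	Didymella corylicola	control_25C	9.1	1.47	FALSE
KR3	Neurospora tetraspora	co2_10C	1.1	1.96	FALSE
KR3	Neurospora tetraspora	control_10C	7.7	1.59	FALSE
KR3	Neurospora tetraspora	control_25C	14.4	1.32	FALSE
TS1	Penicillium tardochrysogenum	co2_10C	5.4	1.84	FALSE
TS1	Penicillium tardochrysogenum	control_10C	7.9	1.76	FALSE
TS1	Penicillium tardochrysogenum	control_25C	9.4	1.50	FALSE
TS2	Penicillium griseofulvum	co2_10C	2.6	1.81	FALSE
TS2	Penicillium griseofulvum	control_10C	4.9	1.73	FALSE
TS2	Penicillium griseofulvum	control_25C	6.9	1.58	FALSE
M1	Rhizopus oryzae	co2_10C	19.2	1.19	FALSE
M1	Rhizopus oryzae	control_10C	22.0	1.00	FALSE
M1	Rhizopus oryzae	control_25C	20.9	1.10	FALSE
M2	Cladosporium subuliforme	co2_10C	11.7	1.49	FALSE
M2	Cladosporium subuliforme	control_10C	18.1	1.22	FALSE
M2	Cladosporium subuliforme	control_25C	26.1	0.92	FALSE
M4	Alternaria alstroemeriae	co2_10C	8.2	1.59	FALSE
M4	Alternaria alstroemeriae	control_10C	17.5	1.25	FALSE
M4	Alternaria alstroemeriae	control_25C	20.0	1.08	FALSE
M6	Penicillium glandicola	co2_10C	4.1	1.75	FALSE
M6	Penicillium glandicola	control_10C	11.2	1.49	FALSE
M6	Penicillium glandicola	control_25C	16.9	1.17	FALSE
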