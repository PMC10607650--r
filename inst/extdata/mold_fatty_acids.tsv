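organism	condition	n_replicates	C16:0	C16:1 cis 9	C18:0	C18:1 cis 9	C18:2 cis 9, 12	C18:3 cis 9, 12, 15	C18:3 cis 6, 9, 12
IF2SW-F4	co2_10C	3	8.8 ± 0.5		6.5 ± 1.0	11.1 ± 1.7	43.7 ± 3.8	30.0 ± 4.8	
IF2SW-F4	control_10C	3	14.9 ± 0.6	<1	7.2 ± 1.4	10.2 ± 1.2	51.0 ± 2.7	16.7 ± 0.6	
IF2SW-F4	control_25C	3	16.1 ± 1.1		3.6 ± 0.9	8.7 ± 0.5	60.0 ± 2.7	11.6 ± 1.0	
DSM 1075	co2_10C	3	8.9 ± 0.4		6.8 ± 2.9	4.2 ± 2.2	47.3 ± 4.6	32.8 ± 4.5	
DSM 1075	control_10C	3	10.6 ± 1.3	<1	10.1 ± 2.9	2.7 ± 0.9	44.5 ± 6.2	33.0 ± 5.6	
DSM 1075	control_25C	3	16.0 ± 1.6		4.0 ± 0.6	3.5 ± 0.5	61.5 ± 5.2	15.1 ± 3.2	
HR2	co2_10C	3	10.5 ± 1.2	1.6 ± 0.5	2.3 ± 1.1	6.9 ± 1.0	64.2 ± 3.3	14.5 ± 2.3	
HR2	control_10C	3	13.0 ± 0.4	1.6 ± 0.3	4.2 ± 0.8	8.0 ± 0.9	55.7 ± 3.3	17.5 ± 2.2	
HR2	control_25C	3	14.8 ± 0.9	0.8 ± 0.1	2.9 ± 0.3	8.0 ± 0.4	70.2 ± 2.2	3.4 ± 1.1	
LT1	co2_10C	3	14.8 ± 2.3	3.9 ± 0.7	1.5 ± 0.2	12.9 ± 2.2	58.6 ± 2.3	8.4 ± 2.6	
LT1	control_10C	3	18.8 ± 1.5	8.1 ± 2.2	3.0 ± 1.0	33.8 ± 3.9	33.8 ± 5.0	2.5 ± 0.5	
LT1	control_25C	3	14.4 ± 1.8	1.0 ± 0.6	2.8 ± 0.1	20.7 ± 5.4	57.9 ± 6.5	3.2 ± 1.5	
KR3	co2_10C	3	10.2 ± 1.8	1.5 ± 1.0	1.5 ± 0.4	5.8 ± 0.6	54.3 ± 2.4	26.8 ± 3.5	
KR3	control_10C	3	12.1 ± 1.3	3.2 ± 0.8	4.7 ± 1.8	15.5 ± 3.2	53.2 ± 1.6	11.2 ± 1.3	
KR3	control_25C	3	15.0 ± 1.2	1.5 ± 0.1	8.0 ± 2.8	25.7 ± 3.0	45.0 ± 3.1	4.8 ± 2.2	
TS1	co2_10C	3	11.0 ± 1.1	<1	4.5 ± 0.4	13.4 ± 1.5	42.5 ± 4.2	28.5 ± 6.5	
TS1	control_10C	3	13.8 ± 0.9		5.8 ± 0.9	10.7 ± 1.3	44.0 ± 2.6	25.6 ± 3.3	
TS1	control_25C	3	15.0 ± 0.4		2.5 ± 0.4	23.3 ± 3.0	50.4 ± 6.9	8.8 ± 3.3	
TS2	co2_10C	3	10.3 ± 0.8	1.7 ± 0.9	2.5 ± 1.1	6.2 ± 1.4	64.6 ± 4.8	14.7 ± 2.3	
TS2	control_10C	3	12.9 ± 0.6	1.6 ± 0.4	2.6 ± 0.8	8.1 ± 0.8	60.8 ± 3.5	14.0 ± 4.2	
TS2	control_25C	3	14.6 ± 1.0	0.8 ± 0.1	3.0 ± 0.6	8.6 ± 0.7	70.2 ± 3.0	2.7 ± 0.9	
M1	co2_10C	3	25.5 ± 4.4	8.0 ± 2.9	2.1 ± 0.3	35.1 ± 4.1	11.6 ± 2.0		17.7 ± 4.8
M1	control_10C	3	20.3 ± 0.4	5.0 ± 1.0	6.5 ± 2.5	50.4 ± 1.6	8.8 ± 2.4		9.0 ± 2.0
M1	control_25C	3	22.0 ± 3.5	0.9 ± 0.4	6.1 ± 1.1	42.1 ± 1.5	19.4 ± 1.5		9.5 ± 1.4
M2	co2_10C	3	20.6 ± 2.2	<1	2.4 ± 0.4	16.2 ± 0.9	49.9 ± 2.1	10.9 ± 0.8	
M2	control_10C	2	22.8 ± 1.6		5.4 ± 2.8	28.2 ± 0.2	37.3 ± 0.1	6.3 ± 0.8	
M2	control_25C	3	29.1 ± 2.4		8.4 ± 1.8	33.7 ± 0.8	27.9 ± 4.0	0.9 ± 0.2	
M4	co2_10C	3	14.6 ± 1.5	0.9 ± <0.1	5.0 ± 1.0	8.3 ± 1.6	63.7 ± 1.3	7.5 ± 2.0	
M4	control_10C	3	24.1 ± 1.3	1.3 ± <0.1	6.2 ± 1.1	16.9 ± 0.6	47.6 ± 3.2	4.0 ± 0.2	
M4	control_25C	3	22.3 ± 2.2	1.5 ± 0.1	6.2 ± 0.6	33.9 ± 2.3	35.8 ± 0.6	0.3 ± <0.1	
M6	co2_10C	3	12.0 ± 0.7	2.8 ± 0.3	2.4 ± 0.4	7.7 ± 1.3	61.3 ± 2.0	13.9 ± 2.7	
M6	control_10C	3	12.9 ± 0.6	1.2 ± 0.1	8.3 ± 0.2	17.0 ± 1.7	50.6 ± 0.9	10.0 ± 2.5	
M6	control_25C	3	16.4 ± 1.4	1.4 ± 0.1	6.9 ± 1.4	36.7 ± 2.1	37.3 ± 1.5	1.4 ± 0.5	
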