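organism	condition	n_replicates	C14:0	C16:0	C16:1 cis 9	C18:0	C18:1 cis 9	C18:1 cis 11	C18:2 cis 9, 12	C18:3 cis 9, 12, 15	C18:0 3OH
LR1	co2_10C	3		10.4 ± 0.5	8.9 ± 1.8	<1	38.7 ± 3.1	nd	24.8 ± 1.9	17.3 ± 2.6	
LR1	control_10C	3	<1	11.5 ± 1.5	8.4 ± 2.1		39.6 ± 3.1	nd	25.8 ± 0.5	14.7 ± 4.0	
LR1	control_25C	3		15.1 ± 0.6	4.5 ± 0.3		41.3 ± 1.7		27.0 ± 0.3	12.0 ± 1.3	
WT2	co2_10C	3		11.4 ± 1.6	19.8 ± 1.7	0.5 ± 0.2	22.9 ± 2.1	nd	22.9 ± 1.3	22.4 ± 0.4	
WT2	control_10C	3	<1	11.1 ± 0.9	23.1 ± 0.4	1.0 ± 0.1	24.9 ± 1.2	nd	27.1 ± 1.0	12.8 ± 0.5	
WT2	control_25C	3		14.8 ± 0.4	15.7 ± 1.6	2.2 ± 0.3	21.4 ± 1.3		35.6 ± 0.2	10.3 ± 0.3	
WT5	co2_10C	3		5.6 ± 0.7	74.2 ± 2.6	<1	16.4 ± 2.0	3.8 ± 0.7	nd	nd	
WT5	control_10C	3	<1	8.3 ± 0.3	74.5 ± 0.8		13.5 ± 0.3	3.8 ± 0.7	nd	nd	
WT5	control_25C	3		9.3 ± 1.5	65.5 ± 3.3		18.2 ± 1.9	7.0 ± 1.0			
WR1	co2_10C	3		8.6 ± 0.5	75.6 ± 0.1	<1	13.1 ± 0.2	2.7 ± 0.3	nd	nd	
WR1	control_10C	3	<1	9.0 ± 0.5	79.7 ± 4.6		9.2 ± 3.5	2.9 ± 0.8	nd	nd	
WR1	control_25C	3		10.5 ± 0.4	66.4 ± 1.2		17.2 ± 1.0	5.9 ± 0.4			
WT6	co2_10C	3		16.2 ± 1.0	1.4 ± 0.3	2.4 ± 2.8	19.6 ± 1.0	nd	47.2 ± 4.2	14.0 ± 1.7	
WT6	control_10C	3	<1	19.1 ± 1.8	2.3 ± 0.4	2.3 ± 0.4	47.5 ± 3.0	nd	22.9 ± 3.0	5.9 ± 1.4	
WT6	control_25C	3		20.8 ± 1.1	0.8 ± 0.3	3.9 ± 1.2	24.0 ± 1.7		46.4 ± 2.8	4.2 ± 3.9	
WT7	co2_10C	3		12.4 ± 0.5	12.4 ± 1.1	0.3 ± 0.1	35.6 ± 0.4	nd	19.1 ± 0.9	20.1 ± 0.3	
WT7	control_10C	3	<1	14.3 ± 0.5	15.7 ± 1.0	0.8 ± 0.1	41.9 ± 3.8	nd	16.8 ± 1.3	10.3 ± 2.7	
WT7	control_25C	3		14.7 ± 0.4	1.8 ± 0.1	3.7 ± 0.3	47.8 ± 0.7		23.7 ± 0.4	8.2 ± 0.8	
HT4	co2_10C	3		11.1 ± 0.5	11.5 ± 2.7	0.7 ± 0.3	34.0 ± 8.8	nd	28.7 ± 6.8	14.0 ± 4.5	
HT4	control_10C	3	<1	14.3 ± 1.2	14.7 ± 0.1	1.1 ± 0.1	50.5 ± 3.4	nd	13.7 ± 3.1	5.8 ± 1.6	
HT4	control_25C	3		12.3 ± 0.7	10.5 ± 0.2	1.5 ± 0.3	48.0 ± 4.6		23.0 ± 3.1	4.7 ± 1.3	
M3	co2_10C	3		10.4 ± 0.5	0.9 ± 0.1	1.9 ± 0.1	28.5 ± 0.8	nd	39.1 ± 1.1	19.2 ± 0.4	
M3	control_10C	3	<1	20.4 ± 1.3	1.4 ± 0.2	2.4 ± 0.5	46.8 ± 2.3	nd	20.9 ± 2.1	8.1 ± 1.4	
M3	control_25C	3		18.1 ± 0.5	0.4 ± 0.1	4.0 ± 0.2	54.3 ± 0.8		17.6 ± 0.6	5.6 ± 0.4	
M12	co2_10C	3	1.0 ± <0.1	13.7 ± 0.3	2.1 ± 0.2	1.4 ± 0.2	25.8 ± 0.9		25.6 ± 0.2	18.9 ± 0.3	11.5 ± 0.5
M12	control_10C	3	1.0 ± 0.2	16.9 ± 0.9	3.2 ± 0.5	1.0 ± 0.4	36.5 ± 2.8	nd	15.5 ± 0.8	9.6 ± 2.3	16.1 ± 1.3
M12	control_25C	3	1.1 ± 0.1	17.7 ± 1.2	1.2 ± 0.1	1.7 ± 0.2	39.0 ± 3.3		20.2 ± 2.9	10.3 ± 1.9	8.5 ± 0.5
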