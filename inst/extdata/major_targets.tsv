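uniprot	gene	degree	betweenness	avg_shortest_path	closeness
Q9Y6L6	SLCO1B1	12	0.09496758	2.69078947	0.37163814
Q9NPD5	SLCO1B3	11	0.04862563	3.28289474	0.30460922
P43166	CA7	11	0.04690937	2.40131579	0.41643836
P22748	CA4	11	0.04164377	2.45394737	0.4075067
P15692	VEGFA	11	0.11260667	2.79605263	0.35764706
Q8TCC7	SLC22A8	10	0.03755913	3.23026316	0.3095723
P15121	AKR1B1	10	0.02861805	2.70394737	0.36982968
P08183	ABCB1	10	0.06692038	2.67763158	0.37346437
Q14765	STAT4	9	0.000474	4.08552632	0.24476651
P46721	SLCO1A2	9	0.000474	4.08552632	0.24476651
P40763	STAT3	9	0.000474	4.08552632	0.24476651
P20813	CYP2B6	9	0.000474	4.08552632	0.24476651
P10632	CYP2C8	9	0.05421697	2.75657895	0.3627685
P05023	ATP1A1	9	0.000474	4.08552632	0.24476651
P04798	CYP1A1	9	0.000474	4.08552632	0.24476651
P02766	TTR	9	0.02882135	2.53289474	0.39480519
P08684	CYP3A4	8	0.01906502	3.15131579	0.31732777
P07550	ADRB2	8	0.04366511	3.20394737	0.31211499
P07451	CA3	8	0.03416389	2.45394737	0.4075067
Q9UNQ0	ABCG2	7	0.0203742	2.74342105	0.36450839
Q9ULX7	CA14	7	0.02057174	2.625	0.38095238
P31645	SLC6A4	7	0.0021531	3.83552632	0.26072041
P23975	SLC6A2	7	0.0021531	3.83552632	0.26072041
O43570	CA12	7	0.01886671	2.66447368	0.37530864
Q14524	SCN5A	6	0.000151	4.09868421	0.24398074
P24462	CYP3A7	6	0.000151	4.09868421	0.24398074
P20815	CYP3A5	6	0.000151	4.09868421	0.24398074
P10635	CYP2D6	6	0.000151	4.09868421	0.24398074
P08588	ADRB1	6	0.000151	4.09868421	0.24398074
P08254	MMP3	6	0.00514916	2.95394737	0.33853007
P00918	CA2	6	0.01628126	2.67763158	0.37346437
O15244	SLC22A2	6	0.000151	4.09868421	0.24398074
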