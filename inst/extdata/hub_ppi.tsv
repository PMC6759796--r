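node1	node2	score
VEGFA	KDR	0.999
VEGFA	FLT1	0.999
VEGFA	NRP2	0.998
JAK2	STAT3	0.998
EGFR	STAT3	0.998
CYP1A1	AHR	0.997
JAK1	STAT3	0.997
ATP1A1	ATP1B1	0.997
IL6	STAT3	0.997
VEGFA	HIF1A	0.996
VEGFA	STAT3	0.994
NRP2	FLT1	0.988
FLT1	KDR	0.988
HIF1A	STAT3	0.986
STAT4	JAK2	0.984
NRP2	KDR	0.983
STAT4	JAK1	0.983
VEGFA	EGFR	0.979
IL6	JAK2	0.975
HIF1A	EGFR	0.973
IL6	JAK1	0.968
JAK1	EGFR	0.966
VEGFA	IL6	0.959
JAK2	JAK1	0.943
STAT4	STAT3	0.938
JAK2	EGFR	0.928
CYP1A1	CYP2B6	0.928
IL6	EGFR	0.921
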