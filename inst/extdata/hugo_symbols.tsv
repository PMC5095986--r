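symbol	chromosome	transcript	protein
ABL1	9	NM_005157.6	NP_005148.2
ALK	2	NM_004304.5	NP_004295.2
BRAF	7	NM_004333.6	NP_004324.2
BRCA1	17	NM_007294.4	NP_009225.1
BRCA2	13	NM_000059.4	NP_000050.3
CTNNB1	3	NM_001904.4	NP_001895.1
EGFR	7	NM_005228.5	NP_005219.2
ERBB2	17	NM_004448.4	NP_004439.2
FLT3	13	NM_004119.3	NP_004110.2
IDH1	2	NM_005896.4	NP_005887.2
JAK2	9	NM_004972.4	NP_004963.1
KIT	4	NM_000222.3	NP_000213.1
KRAS	12	NM_033360.4	NP_203524.1
MET	7	NM_000245.4	NP_000236.2
NRAS	1	NM_002524.5	NP_002515.1
PIK3CA	3	NM_006218.4	NP_006209.2
PTEN	10	NM_000314.8	NP_000305.3
RET	10	NM_020975.6	NP_066124.1
SMAD4	18	NM_005359.6	NP_005350.1
TP53	17	NM_000546.6	NP_000537.3
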