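e1	10001	0	LOXL1 causes glaucoma	1	5	LOXL1	14	21	glaucoma	PA	I
e2	10002	1	BRCA1 is not linked to ovarian cancer	1	5	BRCA1	24	37	ovarian cancer	NA	FI
e3	10003	2	TP53 may influence breast cancer	1	4	TP53	20	32	breast cancer	SA
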