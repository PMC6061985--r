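Y	TNF	asthma	TNF polymorphism is associated with asthma risk
N	CHI3L1	atopy	CHI3L1 was not associated with atopy in children
Y	LOXL1	exfoliation glaucoma	Variants of LOXL1 confer susceptibility to exfoliation glaucoma
F	HIF1A	colorectal carcinoma	HIF1A and colorectal carcinoma were studied
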