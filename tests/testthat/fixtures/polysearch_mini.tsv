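d1	R1	SOD1	amyotrophic lateral sclerosis	Mutations in SOD1 cause amyotrophic lateral sclerosis
d2	R0	APOE	diabetes	APOE and diabetes were mentioned in the survey
d3	R2	IL6	sepsis	IL6 levels are associated with sepsis outcome
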