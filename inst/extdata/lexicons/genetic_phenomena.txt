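# genetic phenomena signalling a mechanistic gene-disease link
mutation
mutations
haplotype
haplotypes
transcriptional
phosphorylation
methylation
altered expression
polymorphism
polymorphisms
genotype
allele
deletion
amplification
overexpression
snp
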