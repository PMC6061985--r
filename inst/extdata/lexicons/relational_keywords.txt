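# single tokens that typically name the relational concept between a gene
# and a disease mention; scanned left-to-right between the two entities
polymorphism
polymorphisms
mutation
mutations
variant
variants
allele
alleles
genotype
genotypes
haplotype
haplotypes
association
associations
susceptibility
risk
expression
overexpression
deletion
insertion
amplification
methylation
phosphorylation
linkage
predictor
marker
biomarker
snp
snps
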