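# relational trigger words (single tokens)
associated
association
correlated
correlation
linked
involved
implicated
related
contributes
contribute
confers
confer
predisposes
predispose
causes
cause
caused
induces
induce
increases
decreases
susceptibility
regulates
mediates
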