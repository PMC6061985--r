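# action-verb phrases; multi-word entries match consecutive tokens
binds
docks to
associated with
interacts with
involved in
implicated in
linked to
correlated with
caused by
contributes to
confers
regulates
activates
inhibits
predisposes to
leads to
mediates
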