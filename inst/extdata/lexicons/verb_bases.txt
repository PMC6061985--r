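# base forms used by the rule-based POS fallback to recognise inflected verbs
bind
dock
associate
interact
involve
implicate
link
correlate
cause
contribute
confer
predispose
regulate
activate
inhibit
lead
mediate
induce
increase
decrease
suggest
conclude
indicate
show
find
report
observe
reveal
demonstrate
examine
study
measure
treat
express
detect
identify
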