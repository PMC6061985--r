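# context-specific relation templates
cause
effect
treat
indicative
has symptoms
associated with
overexpressed in
location of
predispose
risk of
marker of
protects against
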