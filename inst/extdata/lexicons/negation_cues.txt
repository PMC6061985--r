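# negation cues; a cue shortly before a trigger/action phrase flips the
# sentence from an asserted relation to a false association
not
no
hardly
unlikely
rarely
neither
nor
without
absence
lack
lacked
failed
cannot
no evidence
no confirmation
no significant
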