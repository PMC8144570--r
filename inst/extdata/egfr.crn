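0 -> A : mass_action(10)
2A -> A + A_P : mass_action(0.03)
A_P -> 0 : mass_action(0.3)
A_P -> A : mass_action(2)
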