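A -> A_P : mass_action(0.001)
A + A_P -> 2A_P : mass_action(1)
A_P -> A : mass_action(5)
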