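2A -> A + A_P : mass_action(0.3)
A_P -> A_PP : mass_action(0.1)
A_P -> A : mass_action(2)
A_PP -> A_P : mass_action(1)
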