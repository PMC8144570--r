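G_act -> G_act + A : mass_action(10)
G_rep -> G_rep + A : mass_action(1.5)
2A -> A + A_P : mass_action(0.2)
A_P -> A : mass_action(1)
A_P -> 0 : mass_action(0.2)
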