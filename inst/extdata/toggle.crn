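Ga_act -> Ga_act + A : mass_action(10)
Ga_rep -> Ga_rep + A : mass_action(1.5)
2A -> A + A_P : mass_action(0.2)
A_P -> A : mass_action(1)
A_P -> 0 : mass_action(0.2)
Gb_act -> Gb_act + B : mass_action(10)
Gb_rep -> Gb_rep + B : mass_action(1)
2B -> B + B_P : mass_action(0.3)
B_P -> B : mass_action(2)
B_P -> 0 : mass_action(0.1)
Ga_act + B_P -> Ga_rep : mass_action(1e-05)
Ga_rep -> Ga_act + B_P : mass_action(0.0003)
Gb_act + A_P -> Gb_rep : mass_action(1.3e-05)
Gb_rep -> Gb_act + A_P : mass_action(0.0002)
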