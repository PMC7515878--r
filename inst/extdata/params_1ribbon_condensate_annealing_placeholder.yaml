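# Hand-tuned placeholder coefficients (synthetic, NOT a calibrated set).
# A weaker branching penalty lets monomers condense into a long-lived
# disordered aggregate from which chain structure anneals out only slowly
# (condensate-annealing-like pathway).
phi_e: -6.0
phi_2s: 3.0
phi_NSP1: -2.0
phi_NSP2: 1.0
phi_ESP0: -0.5
phi_ESP1: 4.0
phi_C5: 4.0
phi_C6: 4.0
phi_C7: 4.0
T: 1.0
k_B: 1.0
A: 1.0
ref_measure: counting
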