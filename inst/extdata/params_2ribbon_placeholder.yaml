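# Hand-tuned placeholder coefficients (synthetic, NOT a calibrated set).
# Rewards chordless squares (NSP2) against a convex two-star penalty so
# that ladder (2-ribbon) segments assemble out of a transient chain
# condensate; closed square-rich polyhedra are excluded by the 6-cycle
# penalty.
phi_e: -6.0
phi_2s: 3.0
phi_NSP1: -1.0
phi_NSP2: -5.0
phi_ESP0: -0.5
phi_ESP1: 5.0
phi_C5: 5.0
phi_C6: 2.0
phi_C7: 5.0
T: 1.0
k_B: 1.0
A: 1.0
ref_measure: counting
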