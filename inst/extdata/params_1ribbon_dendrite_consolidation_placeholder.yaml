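# Hand-tuned placeholder coefficients (synthetic, NOT a calibrated set).
# Produces sparse chain growth to high 1-ribbon fibril fraction: dimers and
# short chains extend from their ends while inter-chain junctions are
# strongly disfavoured (dendrite-consolidation-like pathway).
phi_e: -7.5
phi_2s: 5.0
phi_NSP1: -1.5
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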