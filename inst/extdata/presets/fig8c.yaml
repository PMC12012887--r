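# Operon gene-ratio circuit, closed loop (two resource pools).  Run with
# op.gamma_x2 in {0.5, 1, 2, 4} to see the ratio held at the set-point.
circuit: operon_ratio
parameters:
  op: {gamma_x2: 1.0}
initial_state: {mP: 0.05, m1: 0.05, x1: 1.0, x2: 1.0, z1: 1.0, z2: 5.0}
horizon: 2500
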