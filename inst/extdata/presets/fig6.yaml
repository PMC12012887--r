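# Two-strain consortium controller around the single-species growth
# plant f = k N1 - gamma_p1 x1 (time in hours).
circuit: consortium
parameters:
  controller: {mu1: 0.8, theta1: 1.0, rho_xn: 2.0, N_m: 1.0, gamma: 0.1}
  plant: {k: 1.0, gamma_p1: 1.0}
initial_state: {N1: 0.1, N2: 0.1, x1: 0.0}
horizon: 300
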