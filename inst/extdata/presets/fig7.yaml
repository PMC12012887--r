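# Three-strain population control: N1/N2 regulate the density of N3
# through the AHL channels A1 (actuation) and A3 (sensing).
circuit: population_control
parameters:
  params: {mu1: 1.5, theta1: 0.3, rho3: 5.0, rho1: 6.0,
           sigma1: 1.0, sigma3: 1.0, delta1: 3.0, delta3: 3.0,
           N_m: 1.0, N_m3: 2.0, c13: 1.0, c31: 1.0, gamma: 0.05}
initial_state: {N1: 0.1, N2: 0.1, N3: 0.05, a1: 0.0, a3: 0.0}
horizon: 600
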