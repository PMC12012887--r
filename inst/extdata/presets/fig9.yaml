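# Four-strain coculture composition control; rho4 = 16 commands the
# ratio N3/N4 = 2, and the 4-fold rho4 step at t = 600 h retunes it to 4.
circuit: coculture_ratio
parameters:
  params: {rho4: 16.0, gamma: 0.025}
initial_state: {N1: 0.05, N2: 0.05, N3: 0.02, N4: 0.02,
                a1: 0.0, a2: 0.0, a3: 0.0, a4: 0.0}
horizon: 1600
events:
  - {time: 600, parameter: params.rho4, action: scale, value: 4}
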