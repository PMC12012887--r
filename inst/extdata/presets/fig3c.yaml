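# Minimal autocatalytic motif with a non-competing controller (all
# competition gains zero): perfect adaptation to an expression step.
circuit: minimal_motif
parameters:
  controller: {alpha1_star: 0.1, sense_gain: 1.0, k_star: 0.2,
               w_z1: 0.0, w_bar_lin: 0.0, w_bar_quad: 0.0}
  plant: {b_p1_star: 0.02, gamma_p1: 2.0, w_x1: 0.0}
  pool: {R_tot: 100.0, Q0: 0.0}
initial_state: {x1: 0.1, z1: 0.1}
horizon: 60
events:
  - {time: 15, parameter: controller.k_star, action: scale, value: 2}
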