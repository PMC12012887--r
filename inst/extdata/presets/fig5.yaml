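# Embedded gene-expression control with external zeroth-order resource
# loads; the aggregate load Q0 (nominal 1e-3) is stepped ten-fold.
circuit: embedded_gene_expression
parameters:
  controller: {alpha1_star: 4.0, alpha2_star: 0.25, gamma_c2: 0.25,
               sense_gain: 1.0, k_star: 1.0, w1: 1.0, w2: 1.0}
  plant: {b_p1_star: 0.5, gamma_p1: 0.5, w_x1: 0.0}
  pool: {R_tot: 100.0, Q0: 0.0}
  loads: {L: 1, Q0_per_module: 1.0e-3}
initial_state: {x1: 0.0, z1: 0.1, z2: 50.0}
horizon: 120
events:
  - {time: 15, parameter: pool.Q0, action: scale, value: 10}
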