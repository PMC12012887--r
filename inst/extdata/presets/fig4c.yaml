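# Layered autocatalytic motif, actuation-gain step 1 -> 50 at t = 15.
# alpha2_star = 0.25, gamma_c2 = 0.25, w1 = w2 = 1, R_tot = 100;
# initial conditions x1 = 0, z1 = 0.1, z2 = 50.
circuit: layered_motif
parameters:
  controller: {alpha1_star: 4.0, alpha2_star: 0.25, gamma_c2: 0.25,
               sense_gain: 1.0, k_star: 1.0, w1: 1.0, w2: 1.0}
  plant: {b_p1_star: 0.5, gamma_p1: 0.5, w_x1: 0.0}
  pool: {R_tot: 100.0, Q0: 1.0e-3}
initial_state: {x1: 0.0, z1: 0.1, z2: 50.0}
horizon: 80
events:
  - {time: 15, parameter: controller.k_star, action: set, value: 50}
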