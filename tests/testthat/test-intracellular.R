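nominal_plant <- function() gene_expression_plant(0.5, 0.5)
nominal_pool <- function(Q0 = 1e-3) resource_pool("R", 100, Q0)

test_that("feasibility conditions hold nominally and behave in the high-gain limit", {
  ctl <- fig4c_controller()
  f <- feasibility_conditions(nominal_plant(), ctl, nominal_pool())
  expect_true(all(f))
  ## k* -> Inf: capacity condition reduces to R_tot > r*
  sp <- layered_setpoint(ctl)
  ctl_hi <- fig4c_controller(k_star = 1e12)
  f_hi <- feasibility_conditions(nominal_plant(), ctl_hi,
                                 resource_pool("R", sp$r_star * 1.01))
  expect_true(f_hi[["capacity"]])
  f_lo <- feasibility_conditions(nominal_plant(), ctl_hi,
                                 resource_pool("R", sp$r_star * 0.99))
  expect_false(f_lo[["capacity"]])
})

test_that("violating the flux condition removes the strictly positive equilibrium", {
  ## large basal rate: the actuated branch would need negative flux
  plant <- gene_expression_plant(b_p1_star = 10, gamma_p1 = 0.5)
  ctl <- fig4c_controller()
  expect_false(feasibility_conditions(plant, ctl, nominal_pool())[["flux"]])
  eq <- embedded_equilibrium(plant, ctl, nominal_pool())
  expect_lt(eq[["z1"]], 0)
  m <- layered_motif_circuit(ctl, nominal_pool(), plant)
  rep <- find_positive_equilibrium(m, fig4c_init, max_horizon = 5e4)
  expect_false(isTRUE(rep$positive) && isTRUE(rep$found))
})

test_that("stability criterion is the half-rate inequality and is sufficient only", {
  ctl <- fig4c_controller()               # gamma_c2 = 0.25
  expect_true(stability_criterion(gene_expression_plant(0.5, 0.5), ctl))
  expect_false(stability_criterion(gene_expression_plant(0.5, 0.25), ctl))
})

test_that("embedded circuit with no loads reduces exactly to the layered motif", {
  ctl <- fig4c_controller()
  emb <- embedded_circuit(nominal_plant(), ctl, nominal_pool(),
                          external_loads(L = 0))
  lay <- layered_motif_circuit(ctl, nominal_pool(), nominal_plant())
  tt <- seq(0, 30, by = 0.5)
  tr1 <- simulate_circuit(emb, fig4c_init, 30, times = tt)
  tr2 <- simulate_circuit(lay, fig4c_init, 30, times = tt)
  expect_equal(tr1$state, tr2$state, tolerance = 1e-12)
})

test_that("load modules act only through the aggregate Q0", {
  ctl <- fig4c_controller()
  emb <- embedded_circuit(nominal_plant(), ctl, resource_pool("R", 100, 0),
                          external_loads(L = 4, Q0_per_module = 2.5e-4))
  lay <- layered_motif_circuit(ctl, nominal_pool(1e-3), nominal_plant())
  tt <- seq(0, 30, by = 0.5)
  expect_equal(simulate_circuit(emb, fig4c_init, 30, times = tt)$state,
               simulate_circuit(lay, fig4c_init, 30, times = tt)$state,
               tolerance = 1e-12)
})

test_that("the embedded loop rejects ten-fold load steps (output returns to Sigma)", {
  ctl <- fig4c_controller()
  m <- embedded_circuit(nominal_plant(), ctl, resource_pool("R", 100, 0),
                        external_loads(L = 1, Q0_per_module = 1e-3))
  sigma <- layered_setpoint(ctl)$sigma
  pre <- steady_state(m, fig4c_init)
  expect_equal(unname(pre$state[["x1"]]), sigma, tolerance = 1e-6)
  for (f in c(10, 0.1)) {
    post <- steady_after(m, "pool.Q0", f, pre$state, action = "scale")
    expect_true(post$converged)
    expect_equal(adaptation_error(pre$state[["x1"]], post$state[["x1"]]), 1,
                 tolerance = 1e-4)
  }
})

test_that("open-loop operon ratio follows the translation/degradation formula", {
  p <- operon_params(eta1_star = 2, eta2_star = 1, gamma_x1 = 0.5,
                     gamma_x2 = 1)
  expect_equal(operon_open_loop_ratio(p), 2 * 1 / (1 * 0.5))
  expect_equal(operon_open_loop_ratio(operon_params(gamma_x1 = 1,
                                                    gamma_x2 = 1)), 1)
  ## doubling gamma_x2 doubles the ratio
  expect_equal(operon_open_loop_ratio(operon_params(gamma_x2 = 2)),
               2 * operon_open_loop_ratio(operon_params(gamma_x2 = 1)))
  expect_error(operon_params(gamma_x2 = 0), "> 0")
  ## simulated open loop (controller absorbed at zero) matches the formula
  m <- operon_circuit(operon_params(gamma_x2 = 2))
  ss <- steady_state(m, c(mP = 0, m1 = 0, x1 = 0, x2 = 0, z1 = 0, z2 = 0))
  expect_equal(unname(ss$state[["x1"]] / ss$state[["x2"]]),
               operon_open_loop_ratio(operon_params(gamma_x2 = 2)),
               tolerance = 1e-6)
})

test_that("both operon proteins read the same transcript state", {
  m <- operon_circuit(operon_params())
  s <- c(mP = 1, m1 = 0, x1 = 0, x2 = 0, z1 = 0, z2 = 0)
  d1 <- layeredIFC:::model_rhs(m, 0, s)
  s2 <- s; s2[["mP"]] <- 2
  d2 <- layeredIFC:::model_rhs(m, 0, s2)
  ## with equal translation rates, raising mP raises both production terms
  ## in proportion (identical marginal response to the shared transcript)
  r2_1 <- layeredIFC:::model_derived(m, s)[["r2"]]
  r2_2 <- layeredIFC:::model_derived(m, s2)[["r2"]]
  expect_equal((d2[["x1"]] - d1[["x1"]]) / (2 * r2_2 - r2_1),
               (d2[["x2"]] - d1[["x2"]]) / (2 * r2_2 - r2_1))
})

test_that("closed-loop operon ratio is invariant across gamma_x2 while resources co-adjust", {
  sp <- operon_ratio_setpoint(operon_params())
  ratios <- c(); prods <- c()
  for (g2 in c(0.5, 1, 2, 4)) {
    p <- operon_params(gamma_x2 = g2)
    eq <- operon_equilibrium(p)
    expect_false(is.null(eq))
    m <- operon_circuit(p)
    ls <- local_stability(m, eq)
    expect_true(ls$stable)
    ss <- steady_state(m, 0.4 * eq)
    expect_true(ss$converged)
    ratios <- c(ratios, ss$state[["x1"]] / ss$state[["x2"]])
    prods <- c(prods, prod(ss$derived[c("r1", "r2")]))
  }
  expect_lt(stats::sd(ratios) / mean(ratios), 1e-3)
  expect_equal(unname(ratios), rep(sp$gamma, 4), tolerance = 1e-6)
  ## r1* r2* is proportional to the commanded ratio (constant here)
  expect_lt(diff(range(prods)) / mean(prods), 1e-6)
  expect_equal(mean(prods), sp$r1r2_star, tolerance = 1e-6)
})

test_that("the mRNA quasi-steady-state reduction preserves the steady state", {
  p_full <- operon_params(gamma_x2 = 1)
  p_qss <- operon_params(gamma_x2 = 1, mrna_qss = TRUE)
  eq <- operon_equilibrium(p_full)
  ss_full <- steady_state(operon_circuit(p_full), 0.5 * eq)
  ss_qss <- steady_state(operon_circuit(p_qss),
                         0.5 * eq[c("x1", "x2", "z1", "z2")])
  expect_equal(ss_full$state[c("x1", "x2", "z1", "z2")],
               ss_qss$state[c("x1", "x2", "z1", "z2")], tolerance = 1e-6)
  expect_error(operon_circuit(p_full, resource_pool("R1", 10),
                              resource_pool("R1", 10)), "distinct")
})
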