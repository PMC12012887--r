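test_that("zero controller states are absorbing in both motifs", {
  mm <- minimal_motif_circuit(minimal_motif_params(1, 1, 1, w_z1 = 1),
                              resource_pool("R", 10))
  d <- layeredIFC:::model_rhs(mm, 0, c(x1 = 3, z1 = 0))
  expect_equal(unname(d[["z1"]]), 0)
  lm <- fig4c_circuit()
  d2 <- layeredIFC:::model_rhs(lm, 0, c(x1 = 5, z1 = 0, z2 = 0))
  expect_equal(unname(d2[["z1"]]), 0)
  expect_equal(unname(d2[["z2"]]), 0)
  d3 <- layeredIFC:::model_rhs(lm, 0, c(x1 = 5, z1 = 1, z2 = 0))
  expect_equal(unname(d3[["z2"]]), 0)
})

test_that("non-competing minimal motif adapts perfectly to an actuation step", {
  ctl <- minimal_motif_params(0.1, 1, 0.2, w_z1 = 0, w_bar_lin = 0,
                              w_bar_quad = 0)
  m <- minimal_motif_circuit(ctl, resource_pool("R", 100),
                             gene_expression_plant(0.02, 2))
  pre <- steady_state(m, c(x1 = 0.1, z1 = 0.1))
  ## set-point in the resource-unlimited regime: alpha1* R_eff / sense_gain
  expect_equal(unname(pre$state[["x1"]]), 0.1 * 100 / 1, tolerance = 1e-6)
  post <- steady_after(m, "controller.k_star", 2, pre$state)
  expect_equal(adaptation_error(pre$state[["x1"]], post$state[["x1"]]), 1,
               tolerance = 1e-6)
  ## and to an expression (basal-rate) step
  post2 <- steady_after(m, "plant.b_p1_star", 0.01, pre$state)
  expect_equal(adaptation_error(pre$state[["x1"]], post2$state[["x1"]]), 1,
               tolerance = 1e-6)
})

test_that("competing minimal motif mis-adapts, less so as gains shrink", {
  devs <- vapply(c(1, 0.1, 0.01), function(sc) {
    ctl <- minimal_motif_params(0.1, 1, 0.2, w_z1 = 10 * sc,
                                w_bar_lin = 0.5 * sc, w_bar_quad = 0.05 * sc)
    m <- minimal_motif_circuit(ctl, resource_pool("R", 100),
                               gene_expression_plant(0.02, 2))
    pre <- steady_state(m, c(x1 = 0.1, z1 = 0.1))
    post <- steady_after(m, "controller.k_star", 1.2, pre$state,
                         action = "scale")
    abs(adaptation_error(pre$state[["x1"]], post$state[["x1"]]) - 1)
  }, 0)
  expect_gt(devs[[1L]], 0.01)
  expect_true(all(diff(devs) < 0))
})

test_that("layered set-point is pinned by controller parameters alone", {
  ctl <- fig4c_controller()
  sp <- layered_setpoint(ctl)
  ## r* Sigma = gamma_c2 / alpha2* exactly; 0.25/0.25 parameter pair gives 1
  expect_equal(sp$r_star * sp$sigma, ctl$gamma_c2 / ctl$alpha2_star)
  expect_equal(sp$r_star * sp$sigma, 1.0)
  ## scaling gamma_c2 and alpha2* together leaves both targets unchanged
  ctl2 <- layered_motif_params(4, 0.25 * 3, 0.25 * 3, 1, 1, 1, 1)
  sp2 <- layered_setpoint(ctl2)
  expect_equal(sp2$sigma, sp$sigma)
  expect_equal(sp2$r_star, sp$r_star)
  ## retuning r* alone: scale gamma_c2/alpha2* while holding
  ## alpha1* gamma_c2 / alpha2* fixed
  ctl3 <- layered_motif_params(4 / 3, 0.25, 0.25 * 3, 1, 1, 1, 1)
  sp3 <- layered_setpoint(ctl3)
  expect_equal(sp3$sigma, sp$sigma)
  expect_equal(sp3$r_star, sp$r_star * 3)
})

test_that("simulated layered equilibrium satisfies the resource-balance product", {
  m <- fig4c_circuit()
  rep <- find_positive_equilibrium(m, fig4c_init)
  expect_true(rep$found && rep$positive)
  r <- layeredIFC:::model_derived(m, rep$state)[["r"]]
  expect_lt(abs(0.25 * rep$state[["x1"]] * r - 0.25), 1e-8)
})

test_that("layered steady output equals the closed-form set-point across random stable parameterizations", {
  for (seed in 1:6) {
    cfg <- generate_fixture("layered_motif", seed, "stable_layered")
    r <- build_run(cfg)
    ctl <- do.call(layered_motif_params, cfg$parameters$controller)
    sp <- layered_setpoint(ctl)
    eq <- embedded_equilibrium(do.call(gene_expression_plant,
                                       cfg$parameters$plant), ctl,
                               resource_pool("R", cfg$parameters$pool$R_tot,
                                             cfg$parameters$pool$Q0))
    ss <- steady_state(r$model, eq[c("x1", "z1", "z2")] * c(0.5, 2, 0.7))
    expect_true(ss$converged)
    expect_equal(unname(ss$state[["x1"]]), sp$sigma, tolerance = 1e-4)
  }
})

test_that("layered motif rejects steps in process and resource parameters (RPA)", {
  m <- fig4c_circuit()
  pre <- steady_state(m, fig4c_init)
  sigma <- layered_setpoint(fig4c_controller())$sigma
  steps <- list(c("controller.k_star", 50, "set"),
                c("plant.gamma_p1", 2, "scale"),
                c("plant.b_p1_star", 2, "scale"),
                c("pool.Q0", 100, "scale"),
                c("pool.R_tot", 1.5, "scale"),
                c("pool.R_tot", 0.5, "scale"),
                c("controller.w1", 2, "scale"),
                c("controller.w2", 0.5, "scale"))
  for (s in steps) {
    post <- steady_after(m, s[[1L]], as.numeric(s[[2L]]), pre$state,
                         action = s[[3L]])
    expect_true(post$converged)
    expect_equal(adaptation_error(pre$state[["x1"]], post$state[["x1"]]), 1,
                 tolerance = 1e-4)
    expect_equal(unname(post$state[["x1"]]), sigma, tolerance = 1e-4)
  }
})
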