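test_that("consortium controller populations are absorbing at zero", {
  m <- consortium_circuit()
  d <- layeredIFC:::model_rhs(m, 0, c(N1 = 0, N2 = 0, x1 = 2))
  expect_equal(unname(d[c("N1", "N2")]), c(0, 0))
})

test_that("symmetric coculture branches are exchangeable (relabelling symmetry)", {
  p <- coculture_params(rho1 = 5, rho2 = 5, rho3 = 4, rho4 = 4,
                        theta3 = 3, theta4 = 3, sigma = rep(1, 4),
                        delta = c(3, 3, 4, 4))
  m <- coculture_circuit(p)
  swap <- function(s) s[c("N2", "N1", "N4", "N3", "a2", "a1", "a4", "a3")]
  y0 <- c(N1 = .1, N2 = .02, N3 = .05, N4 = .15,
          a1 = 0, a2 = .01, a3 = .02, a4 = 0)
  y0s <- stats::setNames(swap(y0), names(y0))
  tt <- seq(0, 50, by = 1)
  tr <- simulate_circuit(m, y0, 50, times = tt)
  trs <- simulate_circuit(m, y0s, 50, times = tt)
  expect_equal(unname(tr$state[, c("N1", "N3", "a1", "a3")]),
               unname(trs$state[, c("N2", "N4", "a2", "a4")]),
               tolerance = 1e-10)
})

test_that("consortium steady output matches the closed-form set-point", {
  ctl <- consortium_params()
  m <- consortium_circuit(ctl)
  ss <- steady_state(m, c(N1 = 0.1, N2 = 0.1, x1 = 0))
  expect_true(ss$converged)
  expect_equal(unname(ss$state[["x1"]]), consortium_setpoint(ctl),
               tolerance = 1e-8)
  ## and is insensitive to the plant gain and carrying capacity
  for (chg in list(c("plant.k", 2), c("plant.gamma_p1", 0.5),
                   c("controller.N_m", 1.5))) {
    post <- steady_after(m, chg[[1L]], as.numeric(chg[[2L]]), ss$state,
                         action = "scale")
    expect_equal(unname(post$state[["x1"]]), consortium_setpoint(ctl),
                 tolerance = 1e-6)
  }
})

test_that("saturating growth induction reproduces first-order results at low occupancy", {
  lin <- consortium_circuit(consortium_params())
  K <- 100  # half-saturation far above the operating range (~0.16)
  hill <- consortium_circuit(consortium_params(
    growth_response = response_fn("hill", Vmax = 2 * K, K = K, n = 1)))
  s1 <- steady_state(lin, c(N1 = .1, N2 = .1, x1 = 0))
  s2 <- steady_state(hill, c(N1 = .1, N2 = .1, x1 = 0))
  expect_equal(unname(s2$state[["x1"]]), unname(s1$state[["x1"]]),
               tolerance = 0.02)
})

test_that("population-control circuit has the closed-form regulated state", {
  p <- population_control_params()
  eq <- population_control_equilibrium(p)
  m <- population_control_circuit(p)
  ss <- steady_state(m)
  expect_true(ss$converged)
  expect_equal(ss$state, eq, tolerance = 1e-7)
  ## all populations extinct: population derivatives vanish, AHLs decay
  d <- layeredIFC:::model_rhs(m, 0, c(N1 = 0, N2 = 0, N3 = 0, a1 = 1, a3 = 1))
  expect_equal(unname(d[c("N1", "N2", "N3")]), c(0, 0, 0))
  expect_true(all(d[c("a1", "a3")] < 0))
})

test_that("regulated AHL level ignores N3-side parameters but tracks controller gains", {
  p <- population_control_params()
  a3_nom <- population_control_equilibrium(p)[["a3"]]
  m <- population_control_circuit(p)
  for (nm in c("N_m3", "c13", "c31")) for (f in c(0.5, 1.5)) {
    post <- steady_after(m, paste0("params.", nm), f, NULL, action = "scale",
                         max_horizon = 5e4)
    expect_true(post$converged)
    expect_true(all(post$state > 1e-9))       # coexistence maintained
    expect_equal(unname(post$state[["a3"]]) / a3_nom, 1, tolerance = 1e-3)
  }
  ## controller-side sensitivity: rho3 moves the set-point by > 1%
  post <- steady_after(m, "params.rho3", 1.5, NULL, action = "scale",
                       max_horizon = 5e4)
  expect_gt(abs(post$state[["a3"]] / a3_nom - 1), 0.01)
  ## and monotonically (grid over rho3 at fixed gamma)
  a3s <- vapply(seq(2, 10, length.out = 5), function(r3)
    population_control_equilibrium(population_control_params(rho3 = r3))[["a3"]],
    0)
  expect_true(all(diff(a3s) < 0))
})

test_that("populations and AHLs stay non-negative along trajectories", {
  m <- population_control_circuit(population_control_params())
  tr <- simulate_circuit(m, horizon = 400, n_out = 201)
  expect_true(all(tr$state >= 0))
  cc <- coculture_circuit(coculture_params())
  tr2 <- simulate_circuit(cc, horizon = 600, n_out = 201)
  expect_true(all(tr2$state >= 0))
})

test_that("coculture ratio set-point has the printed scaling and symmetry", {
  p <- coculture_params()
  sp <- coculture_ratio_setpoint(p)
  ## rho4 x4 doubles the commanded ratio
  p4 <- p; p4$rho4 <- 4 * p$rho4
  expect_equal(coculture_ratio_setpoint(p4)$gamma, 2 * sp$gamma)
  ## symmetric branches command ratio 1
  psym <- coculture_params(rho3 = 4, rho4 = 4, theta3 = 3, theta4 = 3,
                           delta = c(3, 3, 4, 4))
  expect_equal(coculture_ratio_setpoint(psym)$gamma, 1)
  ## inadmissible references are flagged with the violated inequality
  expect_error(coculture_ratio_setpoint(
    coculture_params(rho3 = 0.1, rho4 = 0.1, theta3 = 3, theta4 = 3),
    check_admissible = TRUE), "rho3")
  expect_error(coculture_ratio_setpoint(
    coculture_params(gamma = 5), check_admissible = TRUE), "dilution")
})

test_that("coculture converges to the commanded ratio from varied initial compositions", {
  p <- coculture_params()
  gam <- coculture_ratio_setpoint(p)$gamma
  m <- coculture_circuit(p)
  ics <- list(c(.05, .05, .02, .02), c(.1, .02, .1, .01),
              c(.02, .1, .01, .2), c(.08, .08, .3, .05))
  for (ic in ics) {
    y0 <- c(N1 = ic[1], N2 = ic[2], N3 = ic[3], N4 = ic[4],
            a1 = 0, a2 = 0, a3 = 0, a4 = 0)
    ss <- steady_state(m, y0, max_horizon = 5e4)
    expect_true(ss$converged)
    expect_equal(unname(ss$state[["N3"]] / ss$state[["N4"]]), gam,
                 tolerance = 1e-6)
  }
  ## matches the closed-form equilibrium
  expect_equal(steady_state(m, max_horizon = 5e4)$state,
               coculture_equilibrium(p), tolerance = 1e-6)
})

test_that("coculture ratio ignores process-side disturbances but not controller gains", {
  p <- coculture_params()
  gam <- coculture_ratio_setpoint(p)$gamma
  m <- coculture_circuit(p)
  base <- steady_state(m, max_horizon = 5e4)
  for (chg in list(c("params.rho2", 0.5), c("params.rho2", 1.5),
                   c("params.gamma", 0.5), c("params.gamma", 1.5))) {
    post <- steady_after(m, chg[[1L]], as.numeric(chg[[2L]]), base$state,
                         action = "scale", max_horizon = 5e4)
    expect_true(post$converged)
    expect_equal(unname(post$state[["N3"]] / post$state[["N4"]]), gam,
                 tolerance = 1e-3)
  }
  post <- steady_after(m, "params.rho4", 1.5, base$state, action = "scale",
                       max_horizon = 5e4)
  expect_gt(abs(post$state[["N3"]] / post$state[["N4"]] / gam - 1), 0.01)
})

test_that("diluting the controller strains breaks perfect ratiometric adaptation", {
  p <- coculture_params(retentive_controller = FALSE)
  gam <- sqrt(p$rho4 * p$theta4 / (p$rho3 * p$theta3))
  ss <- steady_state(coculture_circuit(p), max_horizon = 5e4)
  expect_true(ss$converged)
  expect_gt(abs(ss$state[["N3"]] / ss$state[["N4"]] / gam - 1), 0.01)
})

test_that("rho4 calibration inverts the ratio formula", {
  p <- coculture_calibrate_rho4(coculture_params(), 2)
  expect_equal(coculture_ratio_setpoint(p)$gamma, 2)
  expect_equal(p$rho4, 16)
  p3 <- coculture_calibrate_rho4(coculture_params(), 3.5)
  expect_equal(coculture_ratio_setpoint(p3)$gamma, 3.5)
})
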