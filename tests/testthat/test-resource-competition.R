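test_that("free-resource formula matches its closed form on reference cases", {
  pool <- resource_pool("R", 100, 0)
  ## no competitors: r = R_eff
  expect_equal(free_resource(pool), 100)
  ## one unimolecular competitor with w = 1 at s = 1 halves the pool
  rx <- competitive_reaction("unimolecular", 1, "s", "p", w_u = 1)
  expect_equal(free_resource(pool, list(rx), list(s = 1)), 50)
  ## nominal zeroth-order load
  pool2 <- resource_pool("R", 100, 1e-3)
  expect_equal(free_resource(pool2), 100 / 1.001)
  ## bimolecular terms: w_ab a b + w_a a
  rb <- competitive_reaction("bimolecular_s2", 1, c("a", "b"), "p",
                             w_ab = 0.5, w_a = 0.2)
  expect_equal(free_resource(pool, list(rb), list(a = 2, b = 3)),
               100 / (1 + 0.5 * 6 + 0.2 * 2))
})

test_that("input and configuration errors are rejected", {
  pool <- resource_pool("R", 100)
  rx <- competitive_reaction("unimolecular", 1, "s", "p", w_u = 1)
  expect_error(free_resource(pool, list(rx), list(s = -1)), ">=")
  foreign <- competitive_reaction("unimolecular", 1, "s", "p", w_u = 1,
                                  pool_id = "other")
  expect_error(free_resource(pool, list(foreign)), "pool")
  expect_error(resource_pool("R", -1), "> 0")
  expect_error(resource_pool("R", 10, -0.1), ">=")
  ## w_a is structurally zero for scenarios 1 and 3
  expect_error(competitive_reaction("bimolecular_s1", 1, c("a", "b"), "p",
                                    w_a = 0.1), "zero")
  expect_error(competitive_reaction("bimolecular_s3", 1, c("a", "b"), "p",
                                    w_a = 0.1), "zero")
  expect_silent(competitive_reaction("bimolecular_s4", 1, c("a", "b"), "p",
                                     w_a = 0.1))
  ## substrate arity must match the kind
  expect_error(competitive_reaction("unimolecular", 1, c("a", "b"), "p"),
               "substrate")
})

test_that("production rate laws cover all kinds and missing substrates error", {
  ru <- competitive_reaction("unimolecular", 2, "s", "p")
  expect_equal(production_rate(ru, list(s = 3), r = 0.5), 3)
  rb <- competitive_reaction("bimolecular_s1", 5, c("a", "b"), "p")
  expect_equal(production_rate(rb, list(a = 0, b = 7), r = 2), 0)
  rz <- competitive_reaction("zeroth", 1, character(0), "p")
  expect_equal(production_rate(rz, r = 42), 42)
  expect_error(production_rate(ru, list(), r = 1), "missing substrate")
})

test_that("r is monotone decreasing in substrates and gains, increasing in R_tot", {
  set.seed(1)
  for (i in 1:25) {
    w <- runif(1, .1, 2); s <- runif(1, .1, 5); Rt <- runif(1, 10, 200)
    pool <- resource_pool("R", Rt, runif(1, 0, 1))
    rx <- function(wu) competitive_reaction("unimolecular", 1, "s", "p",
                                            w_u = wu)
    r0 <- free_resource(pool, list(rx(w)), list(s = s))
    expect_lt(free_resource(pool, list(rx(w)), list(s = s * 1.3)), r0)
    expect_lt(free_resource(pool, list(rx(w * 1.3)), list(s = s)), r0)
    pool_up <- resource_pool("R", Rt * 1.3, pool$Q0)
    expect_gt(free_resource(pool_up, list(rx(w)), list(s = s)), r0)
  }
})

test_that("the resource-unlimited regime is recovered as gains -> 0", {
  pool <- resource_pool("R", 80, 0.2)
  for (w in 10^seq(-1, -8, by = -1)) {
    rx <- competitive_reaction("unimolecular", 1, "s", "p", w_u = w)
    r <- free_resource(pool, list(rx), list(s = 4))
    expect_lt(abs(r - pool$R_eff), pool$R_eff * w * 4 * 1.01)
  }
  rx0 <- competitive_reaction("unimolecular", 1, "s", "p", w_u = 0)
  expect_equal(free_resource(pool, list(rx0), list(s = 4)), pool$R_eff)
})

test_that("smallest expansion has the expected species and conserves resource", {
  pool <- resource_pool("R", 1, 0)
  rx <- list(competitive_reaction("unimolecular", 1, "s", "p", pool_id = "R"))
  ex <- expand_to_mass_action(pool, rx,
                              list(list(bind = 1, unbind = 2, cat = 0.01)),
                              epsilon = 0.1)
  expect_setequal(ex$species, c("R", "s", "C1", "p"))
  expect_length(ex$reactions, 3L)
  y0 <- ex$circuit$default_state; y0[["s"]] <- 2
  tr <- simulate_circuit(ex$circuit, y0, horizon = 5)
  expect_lt(max(abs(tr$derived[, "R_total"] - 1)), 1e-8)
  expect_error(expand_to_mass_action(pool, rx,
                                     list(list(bind = 1, unbind = 2, cat = 1)),
                                     epsilon = -1), "> 0")
})

test_that("two reactions sharing the pool converge to the reduced prediction as epsilon shrinks", {
  net <- list(pool = resource_pool("R", 0.05, 0),
              reactions = list(
                competitive_reaction("unimolecular", 1, "s1", "p1", pool_id = "R"),
                competitive_reaction("unimolecular", 1, "s2", "p2", pool_id = "R")),
              rates = list(list(bind = 1, unbind = 2, cat = 0.02),
                           list(bind = 0.5, unbind = 1, cat = 0.01)),
              substrates = list(s1 = 3, s2 = 5),
              products = c("p1", "p2"))
  errs <- vapply(c(1, 1e-1, 1e-3), function(eps)
    oracle_error(net, eps)$err, 0)
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[[3L]], 0.02)
})

test_that("induced gains follow the binding/unbinding lumping scaled by 1 + Q0", {
  pool <- resource_pool("R", 1, 0.5)
  rx <- list(competitive_reaction("unimolecular", 1, "s", "p", pool_id = "R"),
             competitive_reaction("bimolecular_s2", 1, c("a", "b"), "q",
                                  pool_id = "R"))
  er <- list(list(bind = 2, unbind = 4, cat = 0.1),
             list(bind = 1, unbind = 2, cat = 0.1, bind2 = 3, unbind2 = 6))
  ex <- expand_to_mass_action(pool, rx, er, epsilon = 1e-2)
  ind <- induced_reactions(ex, rx)
  expect_equal(ind[[1L]]$w_u, (2 / 4) / 1.5)
  expect_equal(ind[[1L]]$beta_star, 0.1 * 0.5)
  expect_equal(ind[[2L]]$w_a, (1 / 2) / 1.5)
  expect_equal(ind[[2L]]$w_ab, (1 / 2) * (3 / 6) / 1.5)
  ## scenarios 3/4 keep the reduced law but have no elementary expansion
  r3 <- competitive_reaction("bimolecular_s3", 1, c("a", "b"), "p")
  expect_error(expand_to_mass_action(pool, list(r3),
                                     list(list(bind = 1, unbind = 1, cat = 1))),
               "not provided")
})
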