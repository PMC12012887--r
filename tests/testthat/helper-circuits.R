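## Shared builders for the test suite.

fig4c_controller <- function(k_star = 1)
  layered_motif_params(alpha1_star = 4, alpha2_star = 0.25, gamma_c2 = 0.25,
                       sense_gain = 1, k_star = k_star, w1 = 1, w2 = 1)

fig4c_circuit <- function(...)
  layered_motif_circuit(fig4c_controller(...), resource_pool("R", 100, 1e-3))

fig4c_init <- c(x1 = 0, z1 = 0.1, z2 = 50)

## steady state after changing one parameter path, starting from a state
steady_after <- function(model, path, value, from, action = "set", ...) {
  m <- model
  m$params <- layeredIFC:::param_set(m$params, path,
    if (action == "set") value else layeredIFC:::param_get(m$params, path) * value)
  steady_state(m, from, ...)
}

## seeded random resource-limited network (<= 3 reactions) with its
## elementary rates and substrate concentrations; rates respect the
## framework's assumptions (production step slowest, weak pre-dimerisation,
## substrates in excess of the pool).
random_network <- function(seed) {
  set.seed(seed)
  n <- sample(1:3, 1)
  kinds <- sample(c("zeroth", "unimolecular", "bimolecular_s1",
                    "bimolecular_s2"), n, replace = TRUE)
  rx <- list(); er <- list(); subs <- list()
  for (i in seq_len(n)) {
    k <- kinds[[i]]
    if (k == "zeroth") {
      rx[[i]] <- competitive_reaction(k, 1, character(0), paste0("p", i),
                                      pool_id = "R")
      er[[i]] <- list(bind = runif(1, .1, .5), unbind = runif(1, 1, 3),
                      cat = runif(1, .005, .02))
    } else if (k == "unimolecular") {
      s <- paste0("s", i)
      rx[[i]] <- competitive_reaction(k, 1, s, paste0("p", i), pool_id = "R")
      er[[i]] <- list(bind = runif(1, .2, 1), unbind = runif(1, 1, 3),
                      cat = runif(1, .005, .02))
      subs[[s]] <- runif(1, 1, 5)
    } else {
      a <- paste0("a", i); b <- paste0("b", i)
      rx[[i]] <- competitive_reaction(k, 1, c(a, b), paste0("p", i),
                                      pool_id = "R")
      er[[i]] <- if (k == "bimolecular_s1")
        list(bind = runif(1, .001, .004), unbind = runif(1, 1, 3),
             cat = runif(1, .005, .02), bind2 = runif(1, .2, 1),
             unbind2 = runif(1, 1, 3))
      else
        list(bind = runif(1, .2, 1), unbind = runif(1, 1, 3),
             cat = runif(1, .005, .02), bind2 = runif(1, .01, .05),
             unbind2 = runif(1, 1, 3))
      subs[[a]] <- runif(1, 1, 4); subs[[b]] <- runif(1, 1, 4)
    }
  }
  list(pool = resource_pool("R", runif(1, .005, .02), runif(1, 0, .01)),
       reactions = rx, rates = er, substrates = subs,
       products = paste0("p", seq_len(n)))
}

## sup-norm relative error between reduced and full product trajectories
## (comparison excludes the initial fast layer of duration 10 * epsilon)
oracle_error <- function(net, epsilon, horizon = 20, n_out = 81) {
  ex <- expand_to_mass_action(net$pool, net$reactions, net$rates, epsilon)
  red <- reduced_counterpart(ex, net$substrates,
                             induced_reactions(ex, net$reactions))
  y0 <- ex$circuit$default_state
  for (nm in names(net$substrates)) y0[[nm]] <- net$substrates[[nm]]
  tt <- seq(0, horizon, length.out = n_out)
  trf <- simulate_circuit(ex$circuit, y0, horizon, times = tt)
  trr <- simulate_circuit(red, horizon = horizon, times = tt)
  keep <- tt >= 10 * epsilon
  err <- max(abs(trf$state[keep, net$products, drop = FALSE] -
                   trr$state[keep, net$products, drop = FALSE])) /
    max(abs(trr$state[keep, net$products, drop = FALSE]))
  cons <- max(abs(trf$derived[, "R_total"] - net$pool$R_tot)) / net$pool$R_tot
  list(err = err, conservation = cons)
}
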