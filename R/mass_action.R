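## Full elementary mass-action expansion of a set of resource-limited
## catalytic production reactions.  Serves as the validation oracle for the
## reduced quasi-steady-state rate laws: binding/unbinding steps are sped
## up by a factor 1/epsilon, and as epsilon -> 0 the full network's product
## trajectories converge to the reduced-model prediction.

#' Expand competitive reactions to an elementary mass-action network
#'
#' Builds the explicit reaction network underlying the reduced rate laws:
#' free resource \code{R}, resource-binding complexes (\code{C} per
#' reaction, plus the pre-complex of bimolecular scenarios), reversible
#' binding/unbinding steps (rates multiplied by \code{1/epsilon}) and the
#' catalytic production step releasing substrates and resource.  Total
#' resource (free + complexed) is conserved by construction.
#'
#' Supported kinds: \code{zeroth}, \code{unimolecular},
#' \code{bimolecular_s1} (substrates pre-dimerise, the dimer binds R),
#' \code{bimolecular_s2} (substrate a binds R first, then b joins).
#' The zeroth-order load of the pool itself (\code{Q0}) is represented by
#' one lumped load reaction when \code{Q0 > 0}.
#'
#' @param pool a \code{\link{resource_pool}}.
#' @param reactions list of \code{\link{competitive_reaction}}s drawing
#'   from \code{pool}.
#' @param elementary_rates list (one element per reaction) of named lists
#'   with fields \code{bind}, \code{unbind}, \code{cat} and, for
#'   bimolecular kinds, \code{bind2}, \code{unbind2}.
#' @param epsilon positive time-scale separation factor applied to all
#'   binding/unbinding rates (as \code{rate / epsilon}).
#' @return Object of class \code{mass_action_expansion} with fields
#'   \code{species}, \code{reactions} (elementary steps),
#'   \code{circuit} (a \code{\link{circuit_model}} whose states are all
#'   species), \code{gains} (the competition gains and beta implied by the
#'   elementary rates under the standard lumping), and \code{pool}.
#' @export
expand_to_mass_action <- function(pool, reactions, elementary_rates,
                                  epsilon = 1e-3) {
  check_scalar(epsilon, "epsilon", lower = 0, strict_lower = TRUE)
  check_reaction_pool(reactions, pool)
  if (length(elementary_rates) != length(reactions))
    stop_input("need one elementary rate set per reaction")

  R <- "R"
  steps <- list()      # each: list(reactants = named counts, products, rate)
  species <- R
  complexes <- character(0)  # R-containing species for the conservation law
  gains <- list()
  q0_sum <- pool$Q0

  add <- function(re, pr, rate) {
    steps[[length(steps) + 1L]] <<- list(reactants = re, products = pr,
                                         rate = rate)
  }
  cnt <- function(...) {
    v <- c(...)
    stats::setNames(as.numeric(v), names(v))
  }

  for (i in seq_along(reactions)) {
    rx <- reactions[[i]]
    er <- elementary_rates[[i]]
    need <- c("bind", "unbind", "cat")
    if (rx$kind %in% c("bimolecular_s1", "bimolecular_s2"))
      need <- c(need, "bind2", "unbind2")
    if (!all(need %in% names(er)))
      stop_input(sprintf("reaction %d (%s): elementary rates %s required", i,
                         rx$kind, paste(need, collapse = ", ")))
    P <- rx$product
    C <- paste0("C", i)
    kb <- er$bind / epsilon; ku <- er$unbind / epsilon; kc <- er$cat
    if (rx$kind == "zeroth") {
      ## R <-> C ; C -> P + R
      add(cnt(R = 1), cnt(stats::setNames(1, C)), kb)
      add(cnt(stats::setNames(1, C)), cnt(R = 1), ku)
      add(cnt(stats::setNames(1, C)), cnt(stats::setNames(c(1, 1), c(P, R))), kc)
      species <- c(species, C, P); complexes <- c(complexes, C)
      q0 <- er$bind / er$unbind
      q0_sum <- q0_sum + q0
      gains[[i]] <- list(kind = rx$kind, beta = kc * q0, q0 = q0)
    } else if (rx$kind == "unimolecular") {
      S <- rx$substrates[[1L]]
      add(cnt(stats::setNames(c(1, 1), c(S, R))), cnt(stats::setNames(1, C)), kb)
      add(cnt(stats::setNames(1, C)), cnt(stats::setNames(c(1, 1), c(S, R))), ku)
      add(cnt(stats::setNames(1, C)),
          cnt(stats::setNames(c(1, 1, 1), c(S, P, R))), kc)
      species <- c(species, S, C, P); complexes <- c(complexes, C)
      wu <- er$bind / er$unbind
      gains[[i]] <- list(kind = rx$kind, beta = kc * wu, w_u = wu)
    } else if (rx$kind == "bimolecular_s1") {
      ## A + B <-> S ; S + R <-> C ; C -> P + A + B + R
      A <- rx$substrates[[1L]]; B <- rx$substrates[[2L]]
      Sb <- paste0("S", i)
      kb2 <- er$bind2 / epsilon; ku2 <- er$unbind2 / epsilon
      add(cnt(stats::setNames(c(1, 1), c(A, B))), cnt(stats::setNames(1, Sb)), kb)
      add(cnt(stats::setNames(1, Sb)), cnt(stats::setNames(c(1, 1), c(A, B))), ku)
      add(cnt(stats::setNames(c(1, 1), c(Sb, R))), cnt(stats::setNames(1, C)), kb2)
      add(cnt(stats::setNames(1, C)), cnt(stats::setNames(c(1, 1), c(Sb, R))), ku2)
      add(cnt(stats::setNames(1, C)),
          cnt(stats::setNames(c(1, 1, 1, 1), c(P, A, B, R))), kc)
      species <- c(species, A, B, Sb, C, P); complexes <- c(complexes, C)
      wab <- (er$bind / er$unbind) * (er$bind2 / er$unbind2)
      gains[[i]] <- list(kind = rx$kind, beta = kc * wab, w_ab = wab, w_a = 0)
    } else if (rx$kind == "bimolecular_s2") {
      ## A + R <-> CA ; CA + B <-> C ; C -> P + A + B + R
      A <- rx$substrates[[1L]]; B <- rx$substrates[[2L]]
      CA <- paste0("CA", i)
      kb2 <- er$bind2 / epsilon; ku2 <- er$unbind2 / epsilon
      add(cnt(stats::setNames(c(1, 1), c(A, R))), cnt(stats::setNames(1, CA)), kb)
      add(cnt(stats::setNames(1, CA)), cnt(stats::setNames(c(1, 1), c(A, R))), ku)
      add(cnt(stats::setNames(c(1, 1), c(CA, B))), cnt(stats::setNames(1, C)), kb2)
      add(cnt(stats::setNames(1, C)), cnt(stats::setNames(c(1, 1), c(CA, B))), ku2)
      add(cnt(stats::setNames(1, C)),
          cnt(stats::setNames(c(1, 1, 1, 1), c(P, A, B, R))), kc)
      species <- c(species, A, B, CA, C, P)
      complexes <- c(complexes, CA, C)
      wa <- er$bind / er$unbind
      wab <- wa * (er$bind2 / er$unbind2)
      gains[[i]] <- list(kind = rx$kind, beta = kc * wab, w_a = wa, w_ab = wab)
    } else {
      stop_input(sprintf(
        "elementary expansion for kind '%s' is not provided; the reduced rate law is (see competitive_reaction)",
        rx$kind))
    }
  }
  species <- unique(species)

  ## lumped zeroth-order load representing the pool's pre-existing Q0
  if (pool$Q0 > 0) {
    CQ <- "CQ"
    kbq <- pool$Q0 / epsilon   # bind/unbind = Q0 with unbind = 1
    add(cnt(R = 1), cnt(CQ = 1), kbq)
    add(cnt(CQ = 1), cnt(R = 1), 1 / epsilon)
    species <- c(species, CQ); complexes <- c(complexes, CQ)
  }

  ## scale competition gains by the total zeroth-order load
  for (i in seq_along(gains)) {
    g <- gains[[i]]
    for (f in intersect(names(g), c("w_u", "w_ab", "w_a")))
      g[[f]] <- g[[f]] / (1 + q0_sum)
    gains[[i]] <- g
  }

  rhs <- function(t, y, params) {
    dy <- stats::setNames(rep(0, length(species)), species)
    for (st in steps) {
      v <- st$rate
      for (nm in names(st$reactants)) v <- v * y[[nm]]^st$reactants[[nm]]
      for (nm in names(st$reactants)) dy[[nm]] <- dy[[nm]] - st$reactants[[nm]] * v
      for (nm in names(st$products)) dy[[nm]] <- dy[[nm]] + st$products[[nm]] * v
    }
    dy
  }
  default_state <- stats::setNames(rep(0, length(species)), species)
  default_state[["R"]] <- pool$R_tot
  circuit <- circuit_model(
    name = "mass_action_expansion", states = species,
    params = list(epsilon = epsilon),
    rhs = rhs,
    derived = local({
      cx <- complexes
      function(state, params)
        c(R_total = unname(state[["R"]] + sum(state[cx])))
    }),
    default_state = default_state)

  structure(list(species = species, reactions = steps, circuit = circuit,
                 complexes = complexes, gains = gains,
                 Q0_total = q0_sum, pool = pool, epsilon = epsilon),
            class = "mass_action_expansion")
}

#' @export
print.mass_action_expansion <- function(x, ...) {
  cat(sprintf("<mass_action_expansion>  %d species, %d elementary steps, epsilon = %g\n",
              length(x$species), length(x$reactions), x$epsilon))
  invisible(x)
}

#' Reduced-model counterpart of an expanded network
#'
#' Builds the reduced circuit implied by the expansion's lumped gains:
#' substrates held constant (catalytic production does not consume them),
#' products accumulating at the quasi-steady-state rates with the free
#' resource given by \code{\link{free_resource}}.  Used to compare reduced
#' and full trajectories.
#'
#' @param expansion a \code{\link{expand_to_mass_action}} result.
#' @param substrate_concs named substrate concentrations held fixed.
#' @param reactions reduced reactions carrying the induced gains, as
#'   returned by \code{\link{induced_reactions}}.
#' @return A \code{\link{circuit_model}} whose states are the product
#'   species, with derived read-out \code{r}.
#' @export
reduced_counterpart <- function(expansion, substrate_concs, reactions) {
  pool <- resource_pool(expansion$pool$pool_id, expansion$pool$R_tot,
                        expansion$Q0_total)
  products <- vapply(reactions, function(rx) rx$product, "")
  rhs <- function(t, y, params) {
    r <- free_resource(pool, reactions, substrate_concs)
    vapply(reactions, function(rx)
      production_rate(rx, substrate_concs, r), 0)
  }
  circuit_model(name = "reduced_counterpart", states = products,
                params = list(dummy = 0), rhs = rhs,
                derived = function(state, params)
                  c(r = free_resource(pool, reactions, substrate_concs)),
                default_state = stats::setNames(rep(0, length(products)),
                                                products))
}

#' Competitive reactions induced by elementary rates
#'
#' Maps the elementary rate constants of an expansion back to reduced
#' \code{\link{competitive_reaction}} objects via the standard lumping
#' (gain = binding / (unbinding + catalysis), scaled by 1/(1 + Q0)).
#'
#' @param expansion a mass-action expansion.
#' @param reactions the original reactions (for substrate/product labels).
#' @return list of \code{competitive_reaction}s with induced gains.
#' @export
induced_reactions <- function(expansion, reactions) {
  lapply(seq_along(reactions), function(i) {
    rx <- reactions[[i]]
    g <- expansion$gains[[i]]
    competitive_reaction(rx$kind, beta_star = g$beta,
                         substrates = rx$substrates, product = rx$product,
                         w_u = g$w_u %||% 0, w_ab = g$w_ab %||% 0,
                         w_a = g$w_a %||% 0, pool_id = rx$pool_id)
  })
}
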