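#' Shared resource pool
#'
#' Describes one pool of shared production resources (for example the free
#' ribosomes of a cell, its RNA polymerases, or a growth-limiting nutrient
#' in a culture medium).  The pool is characterised by its conserved total
#' concentration \code{R_tot}, the aggregate dimensionless load \code{Q0}
#' contributed by all zeroth-order resource-limited reactions drawing from
#' it, and the implied effective capacity \code{R_eff = R_tot / (1 + Q0)}.
#'
#' @param pool_id character identifier of the pool.
#' @param R_tot total resource concentration (arbitrary units, > 0).
#' @param Q0 aggregate zeroth-order load (dimensionless, >= 0).
#' @return An object of class \code{resource_pool} with fields
#'   \code{pool_id}, \code{R_tot}, \code{Q0} and \code{R_eff}.
#' @examples
#' pool <- resource_pool("ribosomes", R_tot = 100, Q0 = 1e-3)
#' pool$R_eff  # 100 / 1.001
#' @export
resource_pool <- function(pool_id = "R", R_tot, Q0 = 0) {
  check_scalar(R_tot, "R_tot", lower = 0, strict_lower = TRUE)
  check_scalar(Q0, "Q0", lower = 0)
  structure(list(pool_id = as.character(pool_id), R_tot = R_tot, Q0 = Q0,
                 R_eff = R_tot / (1 + Q0)),
            class = "resource_pool")
}

#' @export
print.resource_pool <- function(x, ...) {
  cat(sprintf("<resource_pool '%s'>  R_tot = %g, Q0 = %g, R_eff = %g\n",
              x$pool_id, x$R_tot, x$Q0, x$R_eff))
  invisible(x)
}

reaction_kinds <- c("zeroth", "unimolecular",
                    "bimolecular_s1", "bimolecular_s2",
                    "bimolecular_s3", "bimolecular_s4")

#' Resource-limited competitive production reaction
#'
#' One catalytic production reaction competing for a shared resource pool.
#' The reduced rate law is \code{beta_star * r} (zeroth-order),
#' \code{beta_star * s * r} (unimolecular) or \code{beta_star * a * b * r}
#' (bimolecular), where \code{r} is the free-resource concentration of the
#' pool.  The competition gains \code{w_u}, \code{w_ab} and \code{w_a} are
#' lumped constants quantifying the reaction's occupancy of the pool; they
#' enter the denominator of the free-resource formula (see
#' \code{\link{free_resource}}).  For bimolecular reactions of scenarios 1
#' and 3 the single-substrate gain \code{w_a} is zero by definition.
#'
#' @param kind one of \code{"zeroth"}, \code{"unimolecular"},
#'   \code{"bimolecular_s1"} .. \code{"bimolecular_s4"}.
#' @param beta_star production rate constant (per time, with concentration
#'   powers implied by \code{kind}).
#' @param substrates character vector of substrate names: none for
#'   zeroth-order, one for unimolecular, two (ordered a, b) for bimolecular.
#' @param product name of the product species.
#' @param w_u unimolecular competition gain (>= 0).
#' @param w_ab pairwise bimolecular competition gain (>= 0).
#' @param w_a single-substrate bimolecular gain (>= 0; must be 0 for
#'   scenarios 1 and 3).
#' @param pool_id identifier of the single pool the reaction draws from.
#' @return Object of class \code{competitive_reaction}.
#' @export
competitive_reaction <- function(kind, beta_star, substrates = character(0),
                                 product = "P", w_u = 0, w_ab = 0, w_a = 0,
                                 pool_id = "R") {
  kind <- match.arg(kind, reaction_kinds)
  check_scalar(beta_star, "beta_star", lower = 0)
  check_scalar(w_u, "w_u", lower = 0)
  check_scalar(w_ab, "w_ab", lower = 0)
  check_scalar(w_a, "w_a", lower = 0)
  if (length(pool_id) != 1L)
    stop_input("a reaction draws from exactly one pool")
  n_sub <- switch(kind, zeroth = 0L, unimolecular = 1L, 2L)
  if (length(substrates) != n_sub)
    stop_input(sprintf("kind '%s' requires %d substrate(s), got %d",
                       kind, n_sub, length(substrates)))
  if (kind %in% c("bimolecular_s1", "bimolecular_s3") && w_a != 0)
    stop_input("w_a is defined to be zero for bimolecular scenarios 1 and 3")
  structure(list(kind = kind, beta_star = beta_star,
                 substrates = as.character(substrates),
                 product = as.character(product),
                 w_u = w_u, w_ab = w_ab, w_a = w_a,
                 pool_id = as.character(pool_id)),
            class = "competitive_reaction")
}

check_reaction_pool <- function(reactions, pool) {
  for (rx in reactions) {
    if (!inherits(rx, "competitive_reaction"))
      stop_input("all reactions must be competitive_reaction objects")
    if (rx$pool_id != pool$pool_id)
      stop_input(sprintf(
        "reaction for product '%s' references pool '%s', not '%s'",
        rx$product, rx$pool_id, pool$pool_id))
  }
  invisible(reactions)
}

substrate_conc <- function(concs, name) {
  v <- concs[[name]]
  if (is.null(v))
    stop_input(sprintf("missing substrate concentration '%s'", name))
  check_scalar(v, name, lower = 0)
  v
}

#' Free-resource concentration of a shared pool
#'
#' Evaluates the quasi-steady-state free-resource formula
#' \deqn{r = \frac{R_{tot}/(1+Q_0)}{1 + \sum_i w_i^u s_i^u +
#'   \sum_i (w_i^{ab} a_i b_i + w_i^a a_i)}}
#' for a pool shared by a set of competitive production reactions.  The
#' numerator is the pool's effective capacity; each denominator term is the
#' occupancy contributed by one competing reaction.  With no competitors
#' the formula returns \code{R_eff}; it is strictly decreasing in every
#' substrate concentration and every gain, and strictly increasing in
#' \code{R_tot}.
#'
#' @param pool a \code{\link{resource_pool}}.
#' @param reactions list of \code{\link{competitive_reaction}} objects, all
#'   drawing from \code{pool} (may be empty).
#' @param substrate_concs named list or vector of substrate concentrations
#'   (all >= 0).
#' @return Free-resource concentration, \code{0 < r <= R_eff}.
#' @examples
#' pool <- resource_pool("R", R_tot = 100)
#' rx <- competitive_reaction("unimolecular", beta_star = 1,
#'                            substrates = "s", w_u = 1)
#' free_resource(pool, list(rx), list(s = 1))  # 50
#' @export
free_resource <- function(pool, reactions = list(), substrate_concs = list()) {
  if (!inherits(pool, "resource_pool")) stop_input("'pool' must be a resource_pool")
  check_reaction_pool(reactions, pool)
  concs <- as.list(substrate_concs)
  denom <- 1
  for (rx in reactions) {
    denom <- denom + switch(
      rx$kind,
      zeroth = 0,  # zeroth-order load lives in the pool's Q0
      unimolecular = rx$w_u * substrate_conc(concs, rx$substrates[[1L]]),
      {
        a <- substrate_conc(concs, rx$substrates[[1L]])
        b <- substrate_conc(concs, rx$substrates[[2L]])
        rx$w_ab * a * b + rx$w_a * a
      })
  }
  pool$R_eff / denom
}

#' Reduced production rate of a competitive reaction
#'
#' Rate law of a resource-limited catalytic production reaction given the
#' current free-resource concentration: \code{beta_star * r},
#' \code{beta_star * s * r} or \code{beta_star * a * b * r} depending on
#' the reaction kind.
#'
#' @param reaction a \code{\link{competitive_reaction}}.
#' @param substrate_concs named list/vector of substrate concentrations.
#' @param r free-resource concentration (>= 0).
#' @return Non-negative production rate.
#' @export
production_rate <- function(reaction, substrate_concs = list(), r) {
  if (!inherits(reaction, "competitive_reaction"))
    stop_input("'reaction' must be a competitive_reaction")
  check_scalar(r, "r", lower = 0)
  concs <- as.list(substrate_concs)
  switch(reaction$kind,
         zeroth = reaction$beta_star * r,
         unimolecular =
           reaction$beta_star * substrate_conc(concs, reaction$substrates[[1L]]) * r,
         reaction$beta_star *
           substrate_conc(concs, reaction$substrates[[1L]]) *
           substrate_conc(concs, reaction$substrates[[2L]]) * r)
}
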