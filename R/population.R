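## Generalized Lotka-Volterra realizations of the layered autocatalytic
## controller: two controller strains N1 (killed by the regulated output)
## and N2 (whose intrinsic growth is stimulated by it) compete for a
## growth-limiting resource through a shared carrying capacity.  The
## logistic free-capacity factor phi = 1 - (weighted community)/N_m plays
## the role of the free resource r of the intracellular motif.  Time is in
## hours throughout.

#' Consortium controller parameters
#'
#' @param mu1 intrinsic growth rate of N1 (per hour, > 0).
#' @param theta1 killing gain of the output on N1 (per hour per
#'   concentration, > 0).
#' @param rho_xn growth-stimulation gain of the output on N2 (per hour per
#'   concentration, > 0).
#' @param N_m shared carrying capacity for N1/N2 (> 0).
#' @param gamma dilution rate (per hour, >= 0; the integral action
#'   requires it nonzero for a nontrivial set-point).
#' @param c1 numeric vector of Lotka-Volterra competition coefficients of
#'   the process populations on the controller strains (one per process
#'   population; self coefficients are fixed to 1).
#' @param growth_response optional \code{\link{response_fn}} replacing the
#'   first-order growth induction of N2 (saturation option; default
#'   linear).
#' @export
consortium_params <- function(mu1 = 0.8, theta1 = 1, rho_xn = 2,
                              N_m = 1, gamma = 0.1, c1 = numeric(0),
                              growth_response = NULL) {
  check_scalar(mu1, "mu1", 0, strict_lower = TRUE)
  check_scalar(theta1, "theta1", 0, strict_lower = TRUE)
  check_scalar(rho_xn, "rho_xn", 0, strict_lower = TRUE)
  check_scalar(N_m, "N_m", 0, strict_lower = TRUE)
  check_scalar(gamma, "gamma", 0)
  structure(list(mu1 = mu1, theta1 = theta1, rho_xn = rho_xn, N_m = N_m,
                 gamma = gamma, c1 = c1,
                 growth_response = growth_response),
            class = "consortium_params")
}

#' Single-species growth plant for the consortium
#'
#' Process f(x1, N1) = k N1 - gamma_p1 x1: the output (for example a
#' quorum-sensing molecule) is produced proportionally to the actuating
#' strain's density and decays first order.
#'
#' @param k production gain carried by N1 (> 0).
#' @param gamma_p1 output removal rate (> 0).
#' @export
consortium_plant <- function(k = 1, gamma_p1 = 1) {
  list(states = "x1",
       params = list(k = k, gamma_p1 = gamma_p1),
       populations = character(0),  # no process populations
       rhs = function(x, N1, N2, par) par$k * N1 - par$gamma_p1 * x[["x1"]],
       output = "x1")
}

#' Consortium closed-loop circuit
#'
#' Two controller strains under logistic competition through a shared
#' carrying capacity, closed around an arbitrary process network.  N1 = 0
#' and N2 = 0 are absorbing.  The growth induction of N2 is first-order
#' in the output by default (Hill-saturated if a growth response is
#' supplied).
#'
#' @param controller \code{\link{consortium_params}}.
#' @param process process description (default
#'   \code{\link{consortium_plant}}); its \code{populations} field names
#'   which of its states are process populations entering the shared
#'   competition.
#' @return A \code{\link{circuit_model}} with states (N1, N2, process...)
#'   and derived read-outs \code{phi} (free capacity fraction) and
#'   \code{N_tot}.
#' @export
consortium_circuit <- function(controller = consortium_params(),
                               process = consortium_plant()) {
  stopifnot(inherits(controller, "consortium_params"))
  npop <- length(process$populations)
  if (length(controller$c1) != npop)
    stop_input("length of c1 must match the number of process populations")
  states <- c("N1", "N2", process$states)
  params <- list(controller = unclass(controller), plant = process$params)
  phi_of <- function(state, p) {
    cn <- p$controller
    load <- state[["N1"]] + state[["N2"]]
    if (npop) load <- load + sum(cn$c1 * state[process$populations])
    1 - load / cn$N_m
  }
  induce <- function(xo, cn) {
    if (is.null(cn$growth_response)) cn$rho_xn * xo
    else response_eval(cn$growth_response, xo)
  }
  rhs <- function(t, state, p) {
    cn <- p$controller
    phi <- phi_of(state, p)
    xo <- state[[process$output]]
    dN1 <- state[["N1"]] * (cn$mu1 * phi - cn$theta1 * xo - cn$gamma)
    dN2 <- state[["N2"]] * (induce(xo, cn) * phi - cn$gamma)
    dx <- process$rhs(state[process$states], state[["N1"]], state[["N2"]],
                      p$plant)
    c(dN1, dN2, dx)
  }
  default_state <- stats::setNames(rep(0.1, length(states)), states)
  circuit_model("consortium", states, params, rhs,
                derived = function(state, p)
                  c(phi = phi_of(state, p),
                    N_tot = state[["N1"]] + state[["N2"]] +
                      (if (npop) sum(state[process$populations]) else 0)),
                default_state = default_state)
}

#' Closed-form output set-point of the consortium controller
#'
#' At the strictly positive equilibrium the two controller balance
#' equations give
#' \deqn{x^* = \frac{-\gamma + \sqrt{\gamma^2 + 4\theta_1\mu_1\gamma/
#'   \rho_{xn}}}{2\theta_1},}
#' dependent on controller-strain parameters only (not on the carrying
#' capacity or the process).
#'
#' @param controller \code{\link{consortium_params}}.
#' @export
consortium_setpoint <- function(controller) {
  g <- controller$gamma
  (-g + sqrt(g^2 + 4 * controller$theta1 * controller$mu1 * g /
               controller$rho_xn)) / (2 * controller$theta1)
}

## ---------------------------------------------------------------------

#' Three-strain population-control parameters
#'
#' Controller strains N1, N2 regulate the density of a target strain N3
#' through two orthogonal quorum-sensing channels: N1 secretes A1 which
#' stimulates N3's growth (actuation, gain rho1), N3 secretes A3 which
#' kills N1 and stimulates N2 (sensing, gains theta1 and rho3).  AHLs
#' follow birth-death dynamics with birth proportional to the source-cell
#' density.
#'
#' @param mu1 intrinsic growth rate of N1 (per hour).
#' @param theta1 killing gain of A3 on N1.
#' @param rho3 growth stimulation of N2 by A3.
#' @param rho1 growth stimulation of N3 by A1.
#' @param sigma1,sigma3 AHL secretion rates of A1 (from N1) and A3 (from
#'   N3).
#' @param delta1,delta3 AHL decay rates.
#' @param N_m carrying capacity for N1/N2; \code{N_m3} for N3 (may
#'   differ).
#' @param c13,c31 cross-competition coefficients (process on controller
#'   and controller on process).
#' @param gamma dilution rate (per hour).
#' @param growth_response optional saturating response replacing the
#'   first-order growth induction terms.
#' @export
population_control_params <- function(mu1 = 1.5, theta1 = 0.3, rho3 = 5,
                                      rho1 = 6, sigma1 = 1, sigma3 = 1,
                                      delta1 = 3, delta3 = 3,
                                      N_m = 1, N_m3 = 2, c13 = 1, c31 = 1,
                                      gamma = 0.05,
                                      growth_response = NULL) {
  for (nm in c("mu1", "theta1", "rho3", "rho1", "sigma1", "sigma3",
               "delta1", "delta3", "N_m", "N_m3", "c13", "c31"))
    check_scalar(get(nm), nm, 0, strict_lower = TRUE)
  check_scalar(gamma, "gamma", 0)
  structure(list(mu1 = mu1, theta1 = theta1, rho3 = rho3, rho1 = rho1,
                 sigma1 = sigma1, sigma3 = sigma3, delta1 = delta1,
                 delta3 = delta3, N_m = N_m, N_m3 = N_m3, c13 = c13,
                 c31 = c31, gamma = gamma,
                 growth_response = growth_response),
            class = "population_control_params")
}

#' Three-strain population-control circuit
#'
#' @param params \code{\link{population_control_params}}.
#' @return A \code{\link{circuit_model}} with states (N1, N2, N3, a1, a3)
#'   and derived read-outs \code{phi12}, \code{phi3}, \code{N_tot}.
#' @export
population_control_circuit <- function(params = population_control_params()) {
  stopifnot(inherits(params, "population_control_params"))
  states <- c("N1", "N2", "N3", "a1", "a3")
  rhs <- function(t, state, p) {
    pr <- p$params
    N1 <- state[["N1"]]; N2 <- state[["N2"]]; N3 <- state[["N3"]]
    a1 <- state[["a1"]]; a3 <- state[["a3"]]
    phi12 <- 1 - (N1 + N2 + pr$c13 * N3) / pr$N_m
    phi3 <- 1 - (pr$c31 * (N1 + N2) + N3) / pr$N_m3
    g2 <- if (is.null(pr$growth_response)) pr$rho3 * a3
          else pr$rho3 * response_eval(pr$growth_response, a3)
    g3 <- if (is.null(pr$growth_response)) pr$rho1 * a1
          else pr$rho1 * response_eval(pr$growth_response, a1)
    c(N1 * (pr$mu1 * phi12 - pr$theta1 * a3 - pr$gamma),
      N2 * (g2 * phi12 - pr$gamma),
      N3 * (g3 * phi3 - pr$gamma),
      pr$sigma1 * N1 - pr$delta1 * a1,
      pr$sigma3 * N3 - pr$delta3 * a3)
  }
  default_state <- c(N1 = 0.1, N2 = 0.1, N3 = 0.05, a1 = 0, a3 = 0)
  circuit_model("population_control", states, list(params = unclass(params)),
                rhs,
                derived = function(state, p) {
                  pr <- p$params
                  c(phi12 = 1 - (state[["N1"]] + state[["N2"]] +
                                   pr$c13 * state[["N3"]]) / pr$N_m,
                    N_tot = state[["N1"]] + state[["N2"]] + state[["N3"]])
                },
                default_state = default_state)
}

#' Closed-form equilibrium of the population-control circuit
#'
#' The regulated AHL level
#' \deqn{a_3^* = \frac{-\gamma + \sqrt{\gamma^2 + 4\theta_1\mu_1\gamma/
#'   \rho_3}}{2\theta_1}}
#' and the strain density it encodes (\code{N3* = delta3 a3* / sigma3})
#' depend only on controller-side constants -- not on N3's growth
#' parameters nor on \code{c13}, \code{c31}, \code{N_m3}.
#'
#' @param params \code{\link{population_control_params}}.
#' @return named vector (N1, N2, N3, a1, a3) or NULL when the coexistence
#'   equilibrium is infeasible.
#' @export
population_control_equilibrium <- function(params) {
  pr <- params
  g <- pr$gamma
  a3 <- (-g + sqrt(g^2 + 4 * pr$theta1 * pr$mu1 * g / pr$rho3)) /
    (2 * pr$theta1)
  phi12 <- (pr$theta1 * a3 + g) / pr$mu1
  N3 <- pr$delta3 * a3 / pr$sigma3
  S12 <- pr$N_m * (1 - phi12) - pr$c13 * N3
  phi3 <- 1 - (pr$c31 * S12 + N3) / pr$N_m3
  if (!is.finite(phi3) || phi3 <= 0 || S12 <= 0) return(NULL)
  a1 <- g / (pr$rho1 * phi3)
  N1 <- pr$delta1 * a1 / pr$sigma1
  N2 <- S12 - N1
  out <- c(N1 = N1, N2 = N2, N3 = N3, a1 = a1, a3 = a3)
  if (any(out <= 0)) return(NULL)
  out
}

## ---------------------------------------------------------------------

#' Coculture composition-control parameters
#'
#' Four strains: controller strains N1, N2 (retained in the reactor) and
#' process strains N3, N4 (diluted at rate gamma).  Quorum-sensing wiring:
#' A1 (from N1) stimulates N3, A2 (from N2) stimulates N4 (actuation,
#' gains rho1, rho2); A4 (from N4) stimulates N1 and A3 (from N3)
#' stimulates N2 (sensing, gains rho4, rho3); the toxin channels A3 -> N1
#' and A4 -> N2 (gains theta3, theta4) close the ratio comparison.  The
#' commanded composition is \code{Gamma = N3*/N4*} from
#' \code{\link{coculture_ratio_setpoint}}.
#'
#' @param rho1,rho2 actuation gains (A1 -> N3, A2 -> N4).
#' @param rho3,rho4 sensing gains (A3 -> N2, A4 -> N1).
#' @param theta3,theta4 toxin gains (A3 on N1, A4 on N2).
#' @param sigma,delta length-4 vectors of AHL secretion and decay rates
#'   for A1..A4.
#' @param N_m controller-side carrying capacity; \code{N_mp} process-side.
#' @param gamma dilution rate applied to the process strains (per hour).
#' @param retentive_controller logical; if FALSE the controller strains
#'   are diluted too (demonstrates imperfect ratiometric adaptation).
#' @export
coculture_params <- function(rho1 = 5, rho2 = 5, rho3 = 4, rho4 = 16,
                             theta3 = 3, theta4 = 3,
                             sigma = c(1, 1, 1, 1),
                             delta = c(3, 3, 4, 4),
                             N_m = 1, N_mp = 1, gamma = 0.025,
                             retentive_controller = TRUE) {
  for (nm in c("rho1", "rho2", "rho3", "rho4", "theta3", "theta4",
               "N_m", "N_mp"))
    check_scalar(get(nm), nm, 0, strict_lower = TRUE)
  check_scalar(gamma, "gamma", 0)
  stopifnot(length(sigma) == 4L, length(delta) == 4L,
            all(sigma > 0), all(delta > 0))
  structure(list(rho1 = rho1, rho2 = rho2, rho3 = rho3, rho4 = rho4,
                 theta3 = theta3, theta4 = theta4,
                 sigma = as.numeric(sigma), delta = as.numeric(delta),
                 N_m = N_m, N_mp = N_mp, gamma = gamma,
                 retentive_controller = isTRUE(retentive_controller)),
            class = "coculture_params")
}

#' Four-strain coculture composition-control circuit
#'
#' @param params \code{\link{coculture_params}}.
#' @return A \code{\link{circuit_model}} with states (N1..N4, a1..a4) and
#'   derived read-outs \code{ratio} (N3/N4) and \code{N_tot}.
#' @export
coculture_circuit <- function(params = coculture_params()) {
  stopifnot(inherits(params, "coculture_params"))
  states <- c("N1", "N2", "N3", "N4", "a1", "a2", "a3", "a4")
  rhs <- function(t, state, p) {
    pr <- p$params
    N <- state[c("N1", "N2", "N3", "N4")]
    a <- state[c("a1", "a2", "a3", "a4")]
    tot <- sum(N)
    phic <- 1 - tot / pr$N_m
    phip <- 1 - tot / pr$N_mp
    gctl <- if (pr$retentive_controller) 0 else pr$gamma
    c(N[[1L]] * (pr$rho4 * a[[4L]] * phic - pr$theta3 * a[[3L]] - gctl),
      N[[2L]] * (pr$rho3 * a[[3L]] * phic - pr$theta4 * a[[4L]] - gctl),
      N[[3L]] * (pr$rho1 * a[[1L]] * phip - pr$gamma),
      N[[4L]] * (pr$rho2 * a[[2L]] * phip - pr$gamma),
      pr$sigma * N - pr$delta * a)
  }
  default_state <- c(N1 = 0.05, N2 = 0.05, N3 = 0.02, N4 = 0.02,
                     a1 = 0, a2 = 0, a3 = 0, a4 = 0)
  circuit_model("coculture_ratio", states, list(params = unclass(params)),
                rhs,
                derived = function(state, p)
                  c(ratio = unname(state[["N3"]] / max(state[["N4"]], 1e-300)),
                    N_tot = unname(sum(state[c("N1", "N2", "N3", "N4")]))),
                default_state = default_state)
}

#' Commanded composition ratio of the coculture circuit
#'
#' At the unique strictly positive equilibrium the two controller-strain
#' balances give
#' \deqn{\Gamma = \frac{N_3^*}{N_4^*} = \sqrt{\frac{\rho_4\theta_4}
#'   {\rho_3\theta_3}}\cdot\frac{\delta_3\sigma_4}{\delta_4\sigma_3},}
#' a function of controller parameters only (quadrupling rho4 doubles the
#' ratio).  Admissibility of a commanded ratio additionally requires
#' \code{rho3 * rho4 > theta3 * theta4} (so the controller strains can
#' coexist below capacity) and a slow enough dilution for the process
#' strains to persist; violations are reported.
#'
#' @param params \code{\link{coculture_params}}.
#' @param check_admissible logical; error if the commanded ratio is not
#'   admissible at these parameters.
#' @return list with \code{gamma} (the ratio), \code{phi_c} (free
#'   controller-side capacity at equilibrium) and \code{admissible}.
#' @export
coculture_ratio_setpoint <- function(params, check_admissible = FALSE) {
  pr <- params
  gamma_ratio <- sqrt(pr$rho4 * pr$theta4 / (pr$rho3 * pr$theta3)) *
    (pr$delta[[3L]] * pr$sigma[[4L]]) / (pr$delta[[4L]] * pr$sigma[[3L]])
  phic <- sqrt(pr$theta3 * pr$theta4 / (pr$rho3 * pr$rho4))
  eq <- coculture_equilibrium(params)
  admissible <- phic < 1 && !is.null(eq)
  if (check_admissible && !admissible) {
    if (phic >= 1)
      stop_input("inadmissible reference: rho3 * rho4 <= theta3 * theta4 (sensing gains too weak for coexistence)")
    stop_input("inadmissible reference: no strictly positive equilibrium (dilution too fast for the process strains at this ratio)")
  }
  list(gamma = gamma_ratio, phi_c = phic, admissible = admissible)
}

#' Closed-form positive equilibrium of the coculture circuit
#'
#' @param params \code{\link{coculture_params}}.
#' @return named vector (N1..N4, a1..a4) or NULL if infeasible.
#' @export
coculture_equilibrium <- function(params) {
  pr <- params
  if (!pr$retentive_controller)
    return(NULL)  # closed form assumes retained controller strains
  phic <- sqrt(pr$theta3 * pr$theta4 / (pr$rho3 * pr$rho4))
  if (phic >= 1) return(NULL)
  Tt <- pr$N_m * (1 - phic)
  phip <- 1 - Tt / pr$N_mp
  if (phip <= 0) return(NULL)
  g <- pr$gamma
  N1 <- g * pr$delta[[1L]] / (pr$sigma[[1L]] * pr$rho1 * phip)
  N2 <- g * pr$delta[[2L]] / (pr$sigma[[2L]] * pr$rho2 * phip)
  Gam <- sqrt(pr$rho4 * pr$theta4 / (pr$rho3 * pr$theta3)) *
    (pr$delta[[3L]] * pr$sigma[[4L]]) / (pr$delta[[4L]] * pr$sigma[[3L]])
  rest <- Tt - N1 - N2
  if (rest <= 0) return(NULL)
  N4 <- rest / (1 + Gam)
  N3 <- Gam * N4
  N <- c(N1 = N1, N2 = N2, N3 = N3, N4 = N4)
  a <- pr$sigma * N / pr$delta
  names(a) <- c("a1", "a2", "a3", "a4")
  out <- c(N, a)
  if (any(out <= 0)) return(NULL)
  out
}

#' Calibrate rho4 for a commanded composition ratio
#'
#' Inverts the closed-form ratio expression for rho4 given the target
#' ratio; used for example to command a pre-perturbation ratio of 2 and
#' then step rho4 four-fold to retune the consortium to ratio 4.
#'
#' @param params \code{\link{coculture_params}}.
#' @param target_ratio commanded N3/N4 (> 0).
#' @return \code{coculture_params} with rho4 set accordingly.
#' @export
coculture_calibrate_rho4 <- function(params, target_ratio) {
  check_scalar(target_ratio, "target_ratio", 0, strict_lower = TRUE)
  pr <- params
  scale <- (pr$delta[[3L]] * pr$sigma[[4L]]) / (pr$delta[[4L]] * pr$sigma[[3L]])
  pr$rho4 <- (target_ratio / scale)^2 * pr$rho3 * pr$theta3 / pr$theta4
  pr
}
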