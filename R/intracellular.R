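## Embedded application circuits: gene-expression control under external
## zeroth-order resource loads, and the two-pool operon gene-ratio circuit.

#' External resource load modules
#'
#' L genetic modules coupled to the controlled circuit only through the
#' shared resource pool.  Each module contributes resource occupancy of
#' zeroth-order type only, so their combined effect on the controlled
#' dynamics is the aggregate load Q0 (individual module dynamics are never
#' simulated).
#'
#' @param L number of modules (integer >= 0).
#' @param Q0_per_module zeroth-order occupancy per module (>= 0).
#' @return Object of class \code{external_loads} with the aggregate
#'   \code{Q0}.
#' @export
external_loads <- function(L = 0L, Q0_per_module = 1e-3) {
  if (L < 0 || L != round(L)) stop_input("'L' must be a non-negative integer")
  check_scalar(Q0_per_module, "Q0_per_module", 0)
  structure(list(L = as.integer(L), Q0_per_module = Q0_per_module,
                 Q0 = L * Q0_per_module),
            class = "external_loads")
}

#' Embedded gene-expression control circuit
#'
#' The layered autocatalytic controller closed around a single-gene
#' expression plant inside one cell population, with L external genetic
#' modules drawing on the same resource pool through their aggregate
#' zeroth-order load.  The effective pool load is \code{pool$Q0 +
#' loads$Q0}.  With \code{L = 0} the circuit reduces exactly to the
#' layered motif closed loop.
#'
#' @param plant \code{\link{gene_expression_plant}} description.
#' @param controller \code{\link{layered_motif_params}}.
#' @param pool \code{\link{resource_pool}} (its Q0 is the nominal
#'   zeroth-order load of the controlled circuit itself).
#' @param loads \code{\link{external_loads}}.
#' @return A \code{\link{circuit_model}} with states (x1, z1, z2),
#'   parameter paths \code{plant.*}, \code{controller.*}, \code{pool.*}
#'   and derived read-out \code{r}.
#' @export
embedded_circuit <- function(plant = gene_expression_plant(),
                             controller, pool, loads = external_loads()) {
  pool2 <- resource_pool(pool$pool_id, pool$R_tot, pool$Q0 + loads$Q0)
  m <- layered_motif_circuit(controller, pool2, process = plant)
  m$name <- "embedded_gene_expression"
  m$params$loads <- list(L = loads$L, Q0_per_module = loads$Q0_per_module)
  m
}

#' Closed-form positive equilibrium of the embedded circuit
#'
#' @param plant,controller,pool,loads as in \code{\link{embedded_circuit}}.
#' @return named vector (x1, z1, z2, r); coordinates may be non-positive
#'   when the desired equilibrium is infeasible.
#' @export
embedded_equilibrium <- function(plant = gene_expression_plant(),
                                 controller, pool,
                                 loads = external_loads()) {
  sp <- layered_setpoint(controller)
  sigma <- sp$sigma; r_star <- sp$r_star
  pp <- plant$params
  z1 <- (pp$gamma_p1 * sigma - pp$b_p1_star * r_star) /
    (controller$k_star * r_star)
  R_eff <- pool$R_tot / (1 + pool$Q0 + loads$Q0)
  z2 <- (R_eff / r_star - 1 - controller$w1 * z1 - pp$w_x1 * sigma) /
    controller$w2
  c(x1 = sigma, z1 = z1, z2 = z2, r = r_star)
}

#' Feasibility conditions for the embedded desired equilibrium
#'
#' Evaluates the two printed conditions guaranteeing that the strictly
#' positive (desired) equilibrium exists:
#' \enumerate{
#'   \item \code{gamma_p1 * alpha2_star * Sigma^2 > b_p1_star * gamma_c2}
#'     (the actuation branch must carry positive controller flux), and
#'   \item \code{R_tot > r_star + w1 * gamma_p1 * Sigma / k_star}
#'     (enough resource capacity; in the limit k_star -> Inf this reduces
#'     to \code{R_tot > r_star}).
#' }
#'
#' @param plant,controller,pool as in \code{\link{embedded_circuit}}.
#' @return logical vector \code{c(flux = ..., capacity = ...)}; both TRUE
#'   implies a strictly positive equilibrium exists.
#' @export
feasibility_conditions <- function(plant = gene_expression_plant(),
                                   controller, pool) {
  sp <- layered_setpoint(controller)
  pp <- plant$params
  c(flux = pp$gamma_p1 * controller$alpha2_star * sp$sigma^2 >
      pp$b_p1_star * controller$gamma_c2,
    capacity = pool$R_tot > sp$r_star +
      controller$w1 * pp$gamma_p1 * sp$sigma / controller$k_star)
}

#' Sufficient local-stability criterion of the embedded circuit
#'
#' Returns \code{2 * gamma_c2 <= gamma_p1}.  When TRUE (and the desired
#' equilibrium is feasible) the positive equilibrium is locally
#' asymptotically stable; the criterion is sufficient only, so FALSE
#' requires a numerical check.
#'
#' @param plant \code{\link{gene_expression_plant}}.
#' @param controller \code{\link{layered_motif_params}}.
#' @export
stability_criterion <- function(plant = gene_expression_plant(), controller) {
  2 * controller$gamma_c2 <= plant$params$gamma_p1
}

## ---------------------------------------------------------------------
## Operon gene-ratio circuit (two resource pools)

#' Operon gene-ratio circuit parameters
#'
#' Two genes co-transcribed on one operon (shared transcript m_P), with a
#' ratiometric controller acting through direct transcriptional actuation
#' from Z1 to X1 and competition for both the transcriptional pool R1 and
#' the translational pool R2.
#'
#' @param T_star operon transcription rate (per time per R1 concentration).
#' @param gamma_m transcript removal rate (> 0).
#' @param eta1_star,eta2_star translation rates of X1 and X2 from the
#'   shared transcript (per time per R2 concentration).
#' @param gamma_x1,gamma_x2 protein removal rates (> 0).
#' @param k_act Z1-activated transcription rate of the actuation
#'   transcript m1 (per time per concentration per R1 concentration).
#' @param gamma_m1 actuation-transcript removal rate (> 0).
#' @param eta_act translation rate of the actuation transcript (>= 0).
#' @param alpha1_star,alpha2_star,theta1,theta2 ratiometric controller
#'   constants (see \code{\link{ratiometric_params}}); controller
#'   production requires both pools, so its lumped autocatalysis rate
#'   multiplies \code{r1 * r2}.
#' @param w11,w12 transcription-pool competition gains of z1, z2.
#' @param w2P,w2a,w21,w22 translation-pool competition gains of m_P, m1,
#'   z1, z2.
#' @param mrna_qss logical; if TRUE the two mRNA species are placed at
#'   quasi-steady state (reduction flag).
#' @export
operon_params <- function(T_star = 0.2, gamma_m = 1,
                          eta1_star = 1, eta2_star = 1,
                          gamma_x1 = 2, gamma_x2 = 1,
                          k_act = 0.5, gamma_m1 = 3, eta_act = 12,
                          alpha1_star = 1.44, alpha2_star = 0.16,
                          theta1 = 1, theta2 = 1,
                          w11 = 0.5, w12 = 0.1,
                          w2P = 0.5, w2a = 0.5, w21 = 0.25, w22 = 1,
                          mrna_qss = FALSE) {
  for (nm in c("T_star", "gamma_m", "eta1_star", "eta2_star", "gamma_x1",
               "gamma_x2", "k_act", "gamma_m1", "eta_act", "alpha1_star",
               "alpha2_star", "theta1", "theta2", "w11", "w12", "w2P",
               "w2a", "w21", "w22"))
    check_scalar(get(nm), nm, 0)
  if (gamma_x1 <= 0 || gamma_x2 <= 0)
    stop_input("protein removal rates must be > 0")
  structure(list(T_star = T_star, gamma_m = gamma_m,
                 eta1_star = eta1_star, eta2_star = eta2_star,
                 gamma_x1 = gamma_x1, gamma_x2 = gamma_x2,
                 k_act = k_act, gamma_m1 = gamma_m1, eta_act = eta_act,
                 alpha1_star = alpha1_star, alpha2_star = alpha2_star,
                 theta1 = theta1, theta2 = theta2,
                 w11 = w11, w12 = w12, w2P = w2P, w2a = w2a,
                 w21 = w21, w22 = w22, mrna_qss = mrna_qss),
            class = "operon_params")
}

#' Open-loop steady-state expression ratio of the operon
#'
#' Because both genes read the same transcript, transcriptional
#' competition cancels and the open-loop ratio is
#' \code{eta1_star * gamma_x2 / (eta2_star * gamma_x1)}.
#'
#' @param params \code{\link{operon_params}}.
#' @export
operon_open_loop_ratio <- function(params) {
  stopifnot(inherits(params, "operon_params"))
  if (params$gamma_x1 <= 0 || params$gamma_x2 <= 0)
    stop_input("degradation rates must be positive")
  params$eta1_star * params$gamma_x2 / (params$eta2_star * params$gamma_x1)
}

#' Closed-loop ratio set-point of the operon circuit
#'
#' The controller balance equations give \code{x1*/x2* =
#' sqrt(alpha1_star * theta2 / (alpha2_star * theta1))} and tie the
#' product of the two free resource levels to the ratio:
#' \code{r1* r2* = (theta1 / alpha1_star) * Gamma}.
#'
#' @param params \code{\link{operon_params}}.
#' @return list with \code{gamma} and \code{r1r2_star}.
#' @export
operon_ratio_setpoint <- function(params) {
  stopifnot(inherits(params, "operon_params"))
  gamma <- sqrt(params$alpha1_star * params$theta2 /
                  (params$alpha2_star * params$theta1))
  list(gamma = gamma, r1r2_star = params$theta1 / params$alpha1_star * gamma)
}

#' Operon gene-ratio closed-loop circuit
#'
#' Full model with states (mP, m1, x1, x2, z1, z2), or (x1, x2, z1, z2)
#' under the mRNA quasi-steady-state reduction flag.  Both protein
#' production terms read the same transcript state mP.
#'
#' @param params \code{\link{operon_params}}.
#' @param pool1 transcriptional resource pool (R1).
#' @param pool2 translational resource pool (R2).
#' @return A \code{\link{circuit_model}} with derived read-outs r1, r2.
#' @export
operon_circuit <- function(params = operon_params(),
                           pool1 = resource_pool("R1", 100, 1e-3),
                           pool2 = resource_pool("R2", 100, 1e-3)) {
  stopifnot(inherits(params, "operon_params"))
  if (!inherits(pool1, "resource_pool") || !inherits(pool2, "resource_pool") ||
      pool1$pool_id == pool2$pool_id)
    stop_input("operon circuit needs two distinct resource pools")
  qss <- isTRUE(params$mrna_qss)
  states <- if (qss) c("x1", "x2", "z1", "z2")
            else c("mP", "m1", "x1", "x2", "z1", "z2")
  p <- list(op = unclass(params),
            pool1 = list(R_tot = pool1$R_tot, Q0 = pool1$Q0),
            pool2 = list(R_tot = pool2$R_tot, Q0 = pool2$Q0))
  pools_r <- function(state, p) {
    o <- p$op
    z1 <- state[["z1"]]; z2 <- state[["z2"]]
    r1 <- (p$pool1$R_tot / (1 + p$pool1$Q0)) /
      (1 + o$w11 * z1 + o$w12 * z2)
    mP <- if (qss) o$T_star * r1 / o$gamma_m else state[["mP"]]
    m1 <- if (qss) o$k_act * z1 * r1 / o$gamma_m1 else state[["m1"]]
    r2 <- (p$pool2$R_tot / (1 + p$pool2$Q0)) /
      (1 + o$w2P * mP + o$w2a * m1 + o$w21 * z1 + o$w22 * z2)
    c(r1 = unname(r1), r2 = unname(r2), mP = unname(mP), m1 = unname(m1))
  }
  rhs <- function(t, state, p) {
    o <- p$op
    rr <- pools_r(state, p)
    r1 <- rr[["r1"]]; r2 <- rr[["r2"]]; mP <- rr[["mP"]]; m1 <- rr[["m1"]]
    x1 <- state[["x1"]]; x2 <- state[["x2"]]
    z1 <- state[["z1"]]; z2 <- state[["z2"]]
    dx1 <- (o$eta1_star * mP + o$eta_act * m1) * r2 - o$gamma_x1 * x1
    dx2 <- o$eta2_star * mP * r2 - o$gamma_x2 * x2
    dz1 <- z1 * (o$alpha1_star * x2 * r1 * r2 - o$theta1 * x1)
    dz2 <- z2 * (o$alpha2_star * x1 * r1 * r2 - o$theta2 * x2)
    if (qss) c(dx1, dx2, dz1, dz2)
    else c(o$T_star * r1 - o$gamma_m * mP,
           o$k_act * z1 * r1 - o$gamma_m1 * m1,
           dx1, dx2, dz1, dz2)
  }
  default_state <- stats::setNames(rep(0.1, length(states)), states)
  circuit_model("operon_ratio", states, p, rhs,
                derived = function(state, p) {
                  rr <- pools_r(state, p)
                  c(r1 = rr[["r1"]], r2 = rr[["r2"]])
                },
                default_state = default_state)
}

#' Closed-form positive equilibrium of the operon circuit
#'
#' Solves the steady-state system exactly (one scalar root search in r1).
#'
#' @param params \code{\link{operon_params}}.
#' @param pool1,pool2 the two resource pools.
#' @return named vector (mP, m1, x1, x2, z1, z2) or NULL when no strictly
#'   positive equilibrium exists.
#' @export
operon_equilibrium <- function(params, pool1 = resource_pool("R1", 100, 1e-3),
                               pool2 = resource_pool("R2", 100, 1e-3)) {
  o <- unclass(params)
  sp <- operon_ratio_setpoint(params)
  P <- sp$r1r2_star; Gam <- sp$gamma
  R1e <- pool1$R_eff; R2e <- pool2$R_eff
  eq_at <- function(r1) {
    r2 <- P / r1
    mP <- o$T_star * r1 / o$gamma_m
    x2 <- o$eta2_star * mP * r2 / o$gamma_x2
    x1 <- Gam * x2
    m1 <- (o$gamma_x1 * x1 - o$eta1_star * mP * r2) / (o$eta_act * r2)
    z1 <- o$gamma_m1 * m1 / (o$k_act * r1)
    z2 <- (R1e / r1 - 1 - o$w11 * z1) / o$w12
    c(mP = mP, m1 = m1, x1 = x1, x2 = x2, z1 = z1, z2 = z2, r2 = r2)
  }
  resid <- function(r1) {
    e <- eq_at(r1)
    R2e / e[["r2"]] - (1 + o$w2P * e[["mP"]] + o$w2a * e[["m1"]] +
                         o$w21 * e[["z1"]] + o$w22 * e[["z2"]])
  }
  lo <- P / R2e * 1.000001; hi <- R1e * 0.999999
  if (lo >= hi) return(NULL)
  f_lo <- tryCatch(resid(lo), error = function(e) NA_real_)
  f_hi <- tryCatch(resid(hi), error = function(e) NA_real_)
  if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0) return(NULL)
  r1 <- stats::uniroot(resid, c(lo, hi), tol = 1e-14)$root
  e <- eq_at(r1)
  out <- e[c("mP", "m1", "x1", "x2", "z1", "z2")]
  if (any(out <= 0)) return(NULL)
  out
}
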