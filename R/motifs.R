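## Autocatalytic integral-feedback controller motifs.
##
## The minimal motif is a single controller species Z1 with resource-limited
## positive autoregulation, catalytically degraded by the regulated output:
##   dz1/dt = z1 (alpha1* r  -  theta x_n)
## The layered motif adds a second autocatalytic species Z2 whose
## (bimolecular) autoregulation reads both the output and the free resource
## and which is subject to first-order removal:
##   dz2/dt = z2 (alpha2* x_n r  -  gamma_c2)
## The two layers interact only through the shared resource r.  At the
## strictly positive equilibrium the pair of controller equations pins both
## the output (x_n* = Sigma) and the free resource (r* = gamma_c2 /
## (alpha2* Sigma)) independently of every process- and resource-side
## parameter.

#' Minimal autocatalytic motif parameters
#'
#' @param alpha1_star autocatalysis rate constant of Z1 (per time per
#'   resource concentration, > 0).
#' @param sense_gain catalytic inhibition gain of Z1 by the output
#'   (per time per concentration, > 0).
#' @param k_star actuation gain into the process (> 0).
#' @param w_z1 competition gain of Z1's autocatalysis (>= 0).
#' @param w_bar_lin,w_bar_quad aggregate process-side competition gains:
#'   the linear and quadratic occupancy terms contributed by the process
#'   network to the resource denominator, taken on the process output
#'   aggregate (>= 0).
#' @export
minimal_motif_params <- function(alpha1_star, sense_gain, k_star,
                                 w_z1 = 0, w_bar_lin = 0, w_bar_quad = 0) {
  check_scalar(alpha1_star, "alpha1_star", 0, strict_lower = TRUE)
  check_scalar(sense_gain, "sense_gain", 0, strict_lower = TRUE)
  check_scalar(k_star, "k_star", 0, strict_lower = TRUE)
  check_scalar(w_z1, "w_z1", 0)
  check_scalar(w_bar_lin, "w_bar_lin", 0)
  check_scalar(w_bar_quad, "w_bar_quad", 0)
  structure(list(alpha1_star = alpha1_star, sense_gain = sense_gain,
                 k_star = k_star, w_z1 = w_z1, w_bar_lin = w_bar_lin,
                 w_bar_quad = w_bar_quad),
            class = "minimal_motif_params")
}

#' Layered autocatalytic motif parameters
#'
#' @param alpha1_star Z1 autocatalysis rate (per time per resource
#'   concentration, > 0).
#' @param alpha2_star Z2 bimolecular autocatalysis rate (per time per
#'   concentration per resource concentration, > 0).
#' @param gamma_c2 Z2 first-order removal rate (> 0; the integral action
#'   requires it nonzero).
#' @param sense_gain catalytic inhibition of Z1 by the output (> 0).
#' @param k_star actuation gain (> 0).
#' @param w1,w2 competition gains of Z1 and Z2 (>= 0).
#' @export
layered_motif_params <- function(alpha1_star, alpha2_star, gamma_c2,
                                 sense_gain, k_star, w1 = 0, w2 = 0) {
  check_scalar(alpha1_star, "alpha1_star", 0, strict_lower = TRUE)
  check_scalar(alpha2_star, "alpha2_star", 0, strict_lower = TRUE)
  check_scalar(gamma_c2, "gamma_c2", 0, strict_lower = TRUE)
  check_scalar(sense_gain, "sense_gain", 0, strict_lower = TRUE)
  check_scalar(k_star, "k_star", 0, strict_lower = TRUE)
  check_scalar(w1, "w1", 0)
  check_scalar(w2, "w2", 0)
  structure(list(alpha1_star = alpha1_star, alpha2_star = alpha2_star,
                 gamma_c2 = gamma_c2, sense_gain = sense_gain,
                 k_star = k_star, w1 = w1, w2 = w2),
            class = "layered_motif_params")
}

#' Default single-gene expression plant
#'
#' Birth-death protein expression process f(x1, r) = b_p1* r - gamma_p1 x1
#' with resource-limited basal expression, plus the resource-limited
#' actuation input k* z1 r supplied by the controller.
#'
#' @param b_p1_star resource-limited basal expression rate (>= 0).
#' @param gamma_p1 output removal rate (> 0).
#' @param w_x1 competition gain of the target gene's own occupancy (>= 0;
#'   under the mRNA quasi-steady state of the actuated gene its load is
#'   carried by the controller gain, hence the default 0).
#' @return A process description usable by the motif circuit builders:
#'   list with \code{states}, \code{rhs(x, r, u, par)}, \code{load(x,
#'   par)} (resource occupancy) and \code{output}.
#' @export
gene_expression_plant <- function(b_p1_star = 0.5, gamma_p1 = 0.5,
                                  w_x1 = 0) {
  check_scalar(b_p1_star, "b_p1_star", 0)
  check_scalar(gamma_p1, "gamma_p1", 0, strict_lower = TRUE)
  check_scalar(w_x1, "w_x1", 0)
  list(states = "x1",
       params = list(b_p1_star = b_p1_star, gamma_p1 = gamma_p1,
                     w_x1 = w_x1),
       rhs = function(x, r, u, par) par$b_p1_star * r - par$gamma_p1 * x[["x1"]] + u,
       load = function(x, par) par$w_x1 * x[["x1"]],
       output = "x1")
}

#' Minimal autocatalytic closed loop
#'
#' Assembles the closed-loop circuit of the minimal motif around a process
#' plant.  State zero is absorbing for Z1.  In the resource-unlimited
#' limit (all competition gains zero) the motif achieves robust perfect
#' adaptation of the output at \code{alpha1_star * R_eff / sense_gain};
#' with competition the steady output depends on process parameters and
#' adaptation is imperfect.
#'
#' @param controller \code{\link{minimal_motif_params}}.
#' @param pool \code{\link{resource_pool}}.
#' @param process plant description (default
#'   \code{\link{gene_expression_plant}}).
#' @return A \code{\link{circuit_model}} with states (process..., z1) and
#'   derived read-out \code{r}.
#' @export
minimal_motif_circuit <- function(controller, pool,
                                  process = gene_expression_plant()) {
  stopifnot(inherits(controller, "minimal_motif_params"),
            inherits(pool, "resource_pool"))
  states <- c(process$states, "z1")
  params <- list(controller = unclass(controller),
                 plant = process$params,
                 pool = list(R_tot = pool$R_tot, Q0 = pool$Q0))
  out_nm <- process$output
  free_r <- function(state, p) {
    cn <- p$controller
    xs <- state[process$states]
    xo <- state[[out_nm]]
    denom <- 1 + cn$w_z1 * state[["z1"]] + cn$w_bar_lin * xo +
      cn$w_bar_quad * xo^2 + process$load(xs, p$plant)
    (p$pool$R_tot / (1 + p$pool$Q0)) / denom
  }
  rhs <- function(t, state, p) {
    cn <- p$controller
    r <- free_r(state, p)
    xs <- state[process$states]
    u <- cn$k_star * state[["z1"]] * r
    dx <- process$rhs(xs, r, u, p$plant)
    dz1 <- state[["z1"]] * (cn$alpha1_star * r - cn$sense_gain * state[[out_nm]])
    c(dx, dz1)
  }
  default_state <- stats::setNames(rep(0.1, length(states)), states)
  circuit_model("minimal_motif", states, params, rhs,
                derived = function(state, p) c(r = free_r(state, p)),
                default_state = default_state)
}

#' Layered autocatalytic closed loop
#'
#' Assembles the layered (two-species) autocatalytic integral controller
#' around a process plant.  Both z1 = 0 and z2 = 0 are absorbing; started
#' strictly positive, the stable closed loop steers the output to the
#' set-point \code{layered_setpoint(controller)$sigma} and the free
#' resource to \code{r_star}, independently of process and resource
#' parameters (robust perfect adaptation).
#'
#' @inheritParams minimal_motif_circuit
#' @param controller \code{\link{layered_motif_params}}.
#' @return A \code{\link{circuit_model}} with states (process..., z1, z2)
#'   and derived read-out \code{r}.
#' @export
layered_motif_circuit <- function(controller, pool,
                                  process = gene_expression_plant()) {
  stopifnot(inherits(controller, "layered_motif_params"),
            inherits(pool, "resource_pool"))
  states <- c(process$states, "z1", "z2")
  params <- list(controller = unclass(controller),
                 plant = process$params,
                 pool = list(R_tot = pool$R_tot, Q0 = pool$Q0))
  out_nm <- process$output
  free_r <- function(state, p) {
    cn <- p$controller
    denom <- 1 + cn$w1 * state[["z1"]] + cn$w2 * state[["z2"]] +
      process$load(state[process$states], p$plant)
    (p$pool$R_tot / (1 + p$pool$Q0)) / denom
  }
  rhs <- function(t, state, p) {
    cn <- p$controller
    r <- free_r(state, p)
    xs <- state[process$states]
    u <- cn$k_star * state[["z1"]] * r
    dx <- process$rhs(xs, r, u, p$plant)
    xo <- state[[out_nm]]
    dz1 <- state[["z1"]] * (cn$alpha1_star * r - cn$sense_gain * xo)
    dz2 <- state[["z2"]] * (cn$alpha2_star * xo * r - cn$gamma_c2)
    c(dx, dz1, dz2)
  }
  default_state <- stats::setNames(rep(0.1, length(states)), states)
  default_state[["z2"]] <- 1
  circuit_model("layered_motif", states, params, rhs,
                derived = function(state, p) c(r = free_r(state, p)),
                default_state = default_state)
}

#' Closed-form set-point of the layered motif
#'
#' Solving the two controller equations at a strictly positive equilibrium
#' gives the output set-point
#' \deqn{\Sigma = \sqrt{\alpha_1^\star \gamma_{c2} / (\alpha_2^\star\,
#'   \theta)}}
#' (\eqn{\theta} the sensing gain) and the regulated free-resource level
#' \eqn{r^\star = \gamma_{c2} / (\alpha_2^\star \Sigma)}, so that
#' \eqn{r^\star \Sigma = \gamma_{c2}/\alpha_2^\star} exactly.  Both depend
#' on controller parameters only: the closed loop achieves robust perfect
#' adaptation with parallel regulation of the resource.
#'
#' @param controller \code{\link{layered_motif_params}}.
#' @return Object of class \code{setpoint_report}: list with \code{sigma}
#'   and \code{r_star}.
#' @export
layered_setpoint <- function(controller) {
  stopifnot(inherits(controller, "layered_motif_params"))
  sigma <- sqrt(controller$alpha1_star * controller$gamma_c2 /
                  (controller$alpha2_star * controller$sense_gain))
  r_star <- controller$gamma_c2 / (controller$alpha2_star * sigma)
  structure(list(sigma = sigma, r_star = r_star), class = "setpoint_report")
}

#' @export
print.setpoint_report <- function(x, ...) {
  cat(sprintf("<setpoint_report>  sigma = %g, r_star = %g\n",
              x$sigma, x$r_star))
  invisible(x)
}
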