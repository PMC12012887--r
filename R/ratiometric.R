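## Ratiometric variant of the layered autocatalytic controller: two
## controller species z1, z2 share one resource pool; each is stimulated by
## the opposite process output and catalytically inhibited by its own
## branch's output:
##   dz1/dt = z1 (alpha1* H1(x2) G1(r) - theta1 x1 - gamma_c1)
##   dz2/dt = z2 (alpha2* H2(x1) G2(r) - theta2 x2 - gamma_c2)
## With linear H and G and no controller removal, any strictly positive
## equilibrium satisfies x1*/x2* = Gamma = sqrt(alpha1* theta2 /
## (alpha2* theta1)) (a line through the origin: perfect ratiometric
## control) and r* = sqrt(theta1 theta2 / (alpha1* alpha2*)) (parallel
## resource regulation).  Saturating (Hill) H/G bend the line into a
## monotone nonlinear ratio manifold.

#' Monotone response function (linear or Hill)
#'
#' @param type \code{"linear"} (\code{f(x) = slope * x}) or \code{"hill"}
#'   (\code{f(x) = Vmax x^n / (K^n + x^n)}).
#' @param slope linear slope (> 0).
#' @param Vmax,K,n Hill maximum, half-saturation and coefficient (> 0).
#' @return Object of class \code{response_fn}; callable via
#'   \code{response_eval}.
#' @export
response_fn <- function(type = c("linear", "hill"), slope = 1,
                        Vmax = 1, K = 1, n = 1) {
  type <- match.arg(type)
  if (type == "linear") check_scalar(slope, "slope", 0, strict_lower = TRUE)
  else {
    check_scalar(Vmax, "Vmax", 0, strict_lower = TRUE)
    check_scalar(K, "K", 0, strict_lower = TRUE)
    check_scalar(n, "n", 0, strict_lower = TRUE)
  }
  structure(list(type = type, slope = slope, Vmax = Vmax, K = K, n = n),
            class = "response_fn")
}

#' Evaluate a response function
#' @param f a \code{\link{response_fn}}.
#' @param x non-negative argument (vectorised).
#' @export
response_eval <- function(f, x) {
  if (f$type == "linear") f$slope * x
  else f$Vmax * x^f$n / (f$K^f$n + x^f$n)
}

#' Invert a response function on the positive axis
#' @param f a \code{\link{response_fn}}.
#' @param y value in the range of \code{f} (> 0; for Hill, < Vmax).
#' @export
response_invert <- function(f, y) {
  if (f$type == "linear") return(y / f$slope)
  if (any(y >= f$Vmax))
    stop_input("value outside the range of the saturating response; inverse undefined")
  (y * f$K^f$n / (f$Vmax - y))^(1 / f$n)
}

is_linear <- function(f) f$type == "linear"

#' Ratiometric controller parameters
#'
#' @param alpha1_star,alpha2_star autocatalysis rate constants of Z1 and
#'   Z2 (> 0).
#' @param theta1,theta2 catalytic sensing (inhibition) gains of Z1 by X1
#'   and Z2 by X2 (> 0).
#' @param k1_star,k2_star actuation gains from Z1 into the X1 branch and
#'   Z2 into the X2 branch (>= 0; the actuation wiring is a design choice,
#'   one-sided actuation is allowed).
#' @param gamma_c1,gamma_c2 constant controller removal rates (default 0;
#'   nonzero values give imperfect ratiometric adaptation).
#' @param H1,H2 monotone stimulation responses (of x2 and x1
#'   respectively), \code{\link{response_fn}} objects.
#' @param G1,G2 monotone resource responses (of r).
#' @param w1,w2 competition gains of the controller species (>= 0).
#' @param gamma_ref optional target ratio annotation (informational).
#' @export
ratiometric_params <- function(alpha1_star, alpha2_star, theta1, theta2,
                               k1_star = 1, k2_star = 0,
                               gamma_c1 = 0, gamma_c2 = 0,
                               H1 = response_fn("linear"),
                               H2 = response_fn("linear"),
                               G1 = response_fn("linear"),
                               G2 = response_fn("linear"),
                               w1 = 0, w2 = 0, gamma_ref = NULL) {
  check_scalar(alpha1_star, "alpha1_star", 0, strict_lower = TRUE)
  check_scalar(alpha2_star, "alpha2_star", 0, strict_lower = TRUE)
  check_scalar(theta1, "theta1", 0, strict_lower = TRUE)
  check_scalar(theta2, "theta2", 0, strict_lower = TRUE)
  check_scalar(k1_star, "k1_star", 0)
  check_scalar(k2_star, "k2_star", 0)
  check_scalar(gamma_c1, "gamma_c1", 0)
  check_scalar(gamma_c2, "gamma_c2", 0)
  for (f in list(H1, H2, G1, G2))
    if (!inherits(f, "response_fn"))
      stop_input("H1, H2, G1, G2 must be response_fn objects")
  check_scalar(w1, "w1", 0)
  check_scalar(w2, "w2", 0)
  structure(list(alpha1_star = alpha1_star, alpha2_star = alpha2_star,
                 theta1 = theta1, theta2 = theta2,
                 k1_star = k1_star, k2_star = k2_star,
                 gamma_c1 = gamma_c1, gamma_c2 = gamma_c2,
                 H1 = H1, H2 = H2, G1 = G1, G2 = G2,
                 w1 = w1, w2 = w2, gamma_ref = gamma_ref),
            class = "ratiometric_params")
}

#' Two-gene expression plant for ratiometric control
#'
#' Two independent birth-death expression processes (outputs x1, x2),
#' each with resource-limited basal expression and an actuation input.
#'
#' @param b1_star,b2_star basal expression rates (>= 0).
#' @param gamma1,gamma2 removal rates (> 0).
#' @param w_lin aggregate process-side competition gain on x1 + x2.
#' @export
two_gene_plant <- function(b1_star = 0.1, b2_star = 1,
                           gamma1 = 1, gamma2 = 1, w_lin = 0.2) {
  list(states = c("x1", "x2"),
       params = list(b1_star = b1_star, b2_star = b2_star,
                     gamma1 = gamma1, gamma2 = gamma2, w_lin = w_lin),
       rhs = function(x, r, u, par)
         c(par$b1_star * r - par$gamma1 * x[["x1"]] + u[[1L]],
           par$b2_star * r - par$gamma2 * x[["x2"]] + u[[2L]]),
       load = function(x, par) par$w_lin * (x[["x1"]] + x[["x2"]]),
       outputs = c("x1", "x2"))
}

#' Ratiometric closed loop
#'
#' Assembles the ratiometric controller around a two-output plant.  The
#' actuation hook is u = (k1* z1 r, k2* z2 r), entering the two branches;
#' z1 = z2 = 0 is absorbing.
#'
#' @param controller \code{\link{ratiometric_params}}.
#' @param pool \code{\link{resource_pool}}.
#' @param process two-output plant (default \code{\link{two_gene_plant}}).
#' @return A \code{\link{circuit_model}} with states (process..., z1, z2)
#'   and derived \code{r}.
#' @export
ratiometric_circuit <- function(controller, pool,
                                process = two_gene_plant()) {
  stopifnot(inherits(controller, "ratiometric_params"),
            inherits(pool, "resource_pool"))
  states <- c(process$states, "z1", "z2")
  params <- list(controller = unclass(controller),
                 plant = process$params,
                 pool = list(R_tot = pool$R_tot, Q0 = pool$Q0))
  free_r <- function(state, p) {
    cn <- p$controller
    denom <- 1 + cn$w1 * state[["z1"]] + cn$w2 * state[["z2"]] +
      process$load(state[process$states], p$plant)
    (p$pool$R_tot / (1 + p$pool$Q0)) / denom
  }
  rhs <- function(t, state, p) {
    cn <- p$controller
    r <- free_r(state, p)
    x1 <- state[["x1"]]; x2 <- state[["x2"]]
    u <- c(cn$k1_star * state[["z1"]] * r, cn$k2_star * state[["z2"]] * r)
    dx <- process$rhs(state[process$states], r, u, p$plant)
    dz1 <- state[["z1"]] *
      (cn$alpha1_star * response_eval(cn$H1, x2) * response_eval(cn$G1, r) -
         cn$theta1 * x1 - cn$gamma_c1)
    dz2 <- state[["z2"]] *
      (cn$alpha2_star * response_eval(cn$H2, x1) * response_eval(cn$G2, r) -
         cn$theta2 * x2 - cn$gamma_c2)
    c(dx, dz1, dz2)
  }
  default_state <- stats::setNames(rep(0.1, length(states)), states)
  circuit_model("ratiometric_motif", states, params, rhs,
                derived = function(state, p) c(r = free_r(state, p)),
                default_state = default_state)
}

#' Ratio set-point of the linear ratiometric controller
#'
#' With linear stimulation and resource responses and no controller
#' removal, every strictly positive equilibrium of the ratiometric closed
#' loop satisfies
#' \deqn{x_1^*/x_2^* = \Gamma = \sqrt{\alpha_1^\star c_{H1} c_{G1}\,
#'   \theta_2 / (\alpha_2^\star c_{H2} c_{G2}\, \theta_1)}}
#' (the response slopes fold into the alphas), together with the parallel
#' resource relation \eqn{G_1(r^*) G_2(r^*) \propto} controller constants;
#' for identity G's, \eqn{r^* = \sqrt{\theta_1\theta_2 /
#' (\tilde\alpha_1\tilde\alpha_2)}}.  Depends on controller parameters
#' only.
#'
#' @param controller \code{\link{ratiometric_params}} with all-linear
#'   response tags.
#' @return list with \code{gamma} (the ratio set-point) and \code{r_star}.
#' @export
ratio_setpoint_linear <- function(controller) {
  stopifnot(inherits(controller, "ratiometric_params"))
  if (!all(vapply(controller[c("H1", "H2", "G1", "G2")], is_linear, TRUE)))
    stop_input("ratio_setpoint_linear requires linear response tags; use ratio_manifold for saturating responses")
  if (controller$gamma_c1 != 0 || controller$gamma_c2 != 0)
    stop_input("closed-form ratio set-point assumes no controller removal (gamma_c = 0)")
  a1 <- controller$alpha1_star * controller$H1$slope * controller$G1$slope
  a2 <- controller$alpha2_star * controller$H2$slope * controller$G2$slope
  gamma <- sqrt(a1 * controller$theta2 / (a2 * controller$theta1))
  r_star <- sqrt(controller$theta1 * controller$theta2 / (a1 * a2))
  list(gamma = gamma, r_star = r_star)
}

#' Ratio manifold of the ratiometric controller
#'
#' At any strictly positive equilibrium the two controller balance
#' equations, after eliminating the free resource, tie the two branch
#' steady states together through the smooth curve
#' \deqn{G_1^{-1}\!\left(\frac{\theta_1 x_1^*}{\alpha_1^\star H_1(x_2^*)}\right)
#'  = G_2^{-1}\!\left(\frac{\theta_2 x_2^*}{\alpha_2^\star H_2(x_1^*)}\right),}
#' identifiable from controller parameters alone.  For linear responses it
#' is the line \eqn{x_1^* = \Gamma x_2^*} through the origin; saturating
#' responses make it monotone but nonlinear.
#'
#' @param controller \code{\link{ratiometric_params}}.
#' @param x2_star branch-2 steady state (> 0, vectorised).
#' @return The corresponding \code{x1_star} value(s).
#' @export
ratio_manifold <- function(controller, x2_star) {
  stopifnot(inherits(controller, "ratiometric_params"))
  if (any(x2_star <= 0)) stop_input("x2_star must be > 0")
  if (controller$gamma_c1 != 0 || controller$gamma_c2 != 0)
    stop_input("ratio manifold assumes no controller removal (gamma_c = 0)")
  lin_all <- all(vapply(controller[c("H1", "H2", "G1", "G2")], is_linear, TRUE))
  if (lin_all) {
    return(ratio_setpoint_linear(controller)$gamma * x2_star)
  }
  vapply(x2_star, function(x2) {
    resid <- function(x1) {
      g1 <- response_invert(controller$G1,
                            controller$theta1 * x1 /
                              (controller$alpha1_star *
                                 response_eval(controller$H1, x2)))
      g2 <- response_invert(controller$G2,
                            controller$theta2 * x2 /
                              (controller$alpha2_star *
                                 response_eval(controller$H2, x1)))
      g1 - g2
    }
    ## bracket: resid is increasing in x1 (g1 up, g2 down)
    lo <- x2 * 1e-8; hi <- x2
    while (tryCatch(resid(hi) < 0, error = function(e) TRUE) && hi < x2 * 1e10)
      hi <- hi * 4
    f_lo <- tryCatch(resid(lo), error = function(e) NA_real_)
    f_hi <- tryCatch(resid(hi), error = function(e) NA_real_)
    if (!is.finite(f_lo) || !is.finite(f_hi) || f_lo * f_hi > 0)
      stop_input("ratio manifold not invertible on the requested range (saturation bound exceeded)")
    stats::uniroot(resid, c(lo, hi), tol = 1e-12)$root
  }, 0)
}

#' Residual of the ratio-manifold relation at a state
#'
#' Convenience for testing: evaluates the difference of the two
#' resource-eliminating inverse maps at a candidate equilibrium (zero on
#' the manifold).
#'
#' @param controller \code{\link{ratiometric_params}}.
#' @param x1_star,x2_star candidate branch steady states (> 0).
#' @export
ratio_manifold_residual <- function(controller, x1_star, x2_star) {
  g1 <- response_invert(controller$G1,
                        controller$theta1 * x1_star /
                          (controller$alpha1_star *
                             response_eval(controller$H1, x2_star)))
  g2 <- response_invert(controller$G2,
                        controller$theta2 * x2_star /
                          (controller$alpha2_star *
                             response_eval(controller$H2, x1_star)))
  g1 - g2
}
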