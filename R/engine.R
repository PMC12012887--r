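#' Assemble a circuit model
#'
#' A \code{circuit_model} bundles everything the simulation and analysis
#' layers need: state labels, a nested parameter list, a right-hand-side
#' function and an optional function computing derived read-outs (free
#' resource levels, total population, ...) along a trajectory.
#'
#' @param name short circuit name.
#' @param states character vector of state labels.
#' @param params nested named list of parameters (addressed by dotted paths
#'   such as \code{"controller.k_star"} in disturbance events and scans).
#' @param rhs function \code{(t, state, params)} returning the named vector
#'   of time derivatives.
#' @param derived optional function \code{(state, params)} returning a named
#'   numeric vector of derived quantities.
#' @param default_state named numeric vector of default initial conditions.
#' @return Object of class \code{circuit_model}.
#' @export
circuit_model <- function(name, states, params, rhs, derived = NULL,
                          default_state = NULL) {
  stopifnot(is.character(states), is.function(rhs), is.list(params))
  if (is.null(default_state))
    default_state <- stats::setNames(rep(0, length(states)), states)
  structure(list(name = name, states = states, params = params, rhs = rhs,
                 derived = derived, default_state = default_state),
            class = "circuit_model")
}

#' @export
print.circuit_model <- function(x, ...) {
  cat(sprintf("<circuit_model '%s'>  states: %s\n", x$name,
              paste(x$states, collapse = ", ")))
  invisible(x)
}

## Evaluate the RHS as a plain named vector, validating shape.
model_rhs <- function(model, t, state, params = model$params) {
  d <- model$rhs(t, state, params)
  if (is.list(d)) d <- d[[1L]]
  if (length(d) != length(model$states))
    stop_input("rhs returned wrong length")
  if (any(!is.finite(d)))
    stop_input("rhs returned non-finite derivatives at state: ",
               paste(sprintf("%s=%g", model$states, state), collapse = ", "))
  stats::setNames(as.numeric(d), model$states)
}

model_derived <- function(model, state, params = model$params) {
  if (is.null(model$derived)) return(numeric(0))
  model$derived(state, params)
}

#' Scheduled step disturbance
#'
#' A disturbance event sets or scales one model parameter at a given time;
#' the simulator integrates piecewise between events.  This realises
#' persistent step disturbances such as an actuation-gain step or a sudden
#' change in the zeroth-order resource load.
#'
#' @param time event time.
#' @param parameter dotted path of the target parameter.
#' @param action \code{"set"} or \code{"scale"}.
#' @param value scalar applied according to \code{action}.
#' @export
disturbance <- function(time, parameter, action = c("set", "scale"), value) {
  action <- match.arg(action)
  check_scalar(time, "time")
  check_scalar(value, "value")
  structure(list(time = time, parameter = parameter, action = action,
                 value = value),
            class = "disturbance")
}

apply_event <- function(params, ev) {
  old <- param_get(params, ev$parameter)
  new <- if (ev$action == "set") ev$value else old * ev$value
  list(params = param_set(params, ev$parameter, new), old = old, new = new)
}

#' Simulate a circuit model
#'
#' Deterministic stiff-capable integration (\code{deSolve::ode}, lsoda) of
#' a circuit model over \code{[0, horizon]}, applying scheduled step
#' disturbances.  The output grid always contains every event time; the
#' state is continuous across events while parameters jump.  Small negative
#' undershoots (|x| below the absolute tolerance) are clipped to zero in
#' the returned trajectory only, never inside the solver.
#'
#' @param model a \code{\link{circuit_model}}.
#' @param initial_state named numeric vector (defaults to the model's).
#' @param horizon final time (> 0, or 0 for the initial state only).
#' @param events list of \code{\link{disturbance}} objects.
#' @param times optional explicit output grid (otherwise \code{n_out}
#'   equally spaced points).
#' @param n_out number of output points when \code{times} is NULL.
#' @param rtol,atol relative/absolute integration tolerances.
#' @param method deSolve integration method.
#' @return A \code{trajectory} object: list with \code{times}, matrix
#'   \code{state}, matrix \code{derived}, data frame \code{events_applied}.
#' @export
simulate_circuit <- function(model, initial_state = NULL, horizon,
                             events = list(), times = NULL, n_out = 401L,
                             rtol = 1e-8, atol = 1e-10, method = "lsoda") {
  stopifnot(inherits(model, "circuit_model"))
  check_scalar(horizon, "horizon", lower = 0)
  y0 <- initial_state %||% model$default_state
  y0 <- stats::setNames(as.numeric(y0[model$states]), model$states)
  check_nonneg_state(y0)

  if (horizon == 0) {
    tr <- new_trajectory(model, 0, matrix(y0, nrow = 1,
                                          dimnames = list(NULL, model$states)),
                         model$params, data.frame())
    return(tr)
  }
  if (is.null(times)) times <- seq(0, horizon, length.out = n_out)
  times <- sort(unique(c(0, times[times <= horizon], horizon)))

  evs <- events[order(vapply(events, function(e) e$time, 0))]
  for (e in evs) {
    if (!inherits(e, "disturbance")) stop_input("events must be disturbance objects")
    if (e$time < 0 || e$time > horizon)
      stop_input("event time outside the simulation horizon")
    if (!param_exists(model$params, e$parameter))
      stop_input(sprintf("event targets unknown parameter '%s'", e$parameter))
  }
  break_ts <- vapply(evs, function(e) e$time, 0)
  times <- sort(unique(c(times, break_ts)))

  params <- model$params
  log <- data.frame(time = numeric(0), parameter = character(0),
                    action = character(0), old = numeric(0), new = numeric(0))
  out_all <- NULL; der_all <- NULL
  t0 <- 0; y <- y0; i_ev <- 1L
  seg_starts <- unique(break_ts)
  seg_derived <- function(sol, params) {
    if (is.null(model$derived)) return(NULL)
    d <- apply(sol[, model$states, drop = FALSE], 1L, function(s)
      model$derived(stats::setNames(s, model$states), params))
    if (is.null(dim(d))) matrix(d, ncol = 1L,
                                dimnames = list(NULL, names(model$derived(y, params))))
    else t(d)
  }
  repeat {
    t1 <- if (i_ev <= length(seg_starts)) seg_starts[[i_ev]] else horizon
    if (t1 > t0) {
      tt <- times[times >= t0 & times <= t1]
      if (length(tt) < 2L) tt <- c(t0, t1)
      sol <- deSolve::ode(y = y, times = tt,
                          func = function(t, y, p) list(model_rhs(model, t, y, p)),
                          parms = params, method = method,
                          rtol = rtol, atol = atol, maxsteps = 100000L)
      if (attr(sol, "istate")[1L] < 0)
        stop_input(sprintf(
          "integrator failure in [%g, %g]; last valid state: %s", t0, t1,
          paste(sprintf("%s=%g", model$states, utils::tail(sol, 1)[-1]),
                collapse = ", ")))
      keep <- if (is.null(out_all)) seq_len(nrow(sol)) else seq_len(nrow(sol))[-1L]
      out_all <- rbind(out_all, sol[keep, , drop = FALSE])
      der_all <- rbind(der_all, seg_derived(sol, params)[keep, , drop = FALSE])
      y <- stats::setNames(as.numeric(utils::tail(sol, 1L)[1L, model$states]),
                           model$states)
    }
    if (i_ev > length(seg_starts)) break
    ## apply all events scheduled at t1
    for (e in evs[break_ts == t1]) {
      res <- apply_event(params, e)
      params <- res$params
      log <- rbind(log, data.frame(time = e$time, parameter = e$parameter,
                                   action = e$action, old = res$old,
                                   new = res$new))
    }
    t0 <- t1; i_ev <- i_ev + 1L
    if (t0 >= horizon) break
  }
  state <- as.matrix(out_all[, model$states, drop = FALSE])
  new_trajectory(model, out_all[, 1L], state, params, log, atol = atol,
                 derived = der_all)
}

new_trajectory <- function(model, times, state, final_params, events_applied,
                           atol = 1e-10, derived = NULL) {
  ## clip integrator undershoot in outputs only
  clip <- state < 0 & abs(state) < atol
  state[clip] <- 0
  if (is.null(derived) && !is.null(model$derived)) {
    derived <- t(apply(state, 1L, function(s)
      model$derived(stats::setNames(s, model$states), final_params)))
    if (nrow(derived) != nrow(state)) derived <- t(derived)
  }
  structure(list(model_name = model$name, times = as.numeric(times),
                 state = state, derived = derived,
                 events_applied = events_applied,
                 final_params = final_params),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory '%s'>  %d time points over [%g, %g], states: %s\n",
              x$model_name, length(x$times), min(x$times), max(x$times),
              paste(colnames(x$state), collapse = ", ")))
  if (nrow(x$events_applied)) {
    cat("events applied:\n"); print(x$events_applied)
  }
  invisible(x)
}

#' Tidy data frame view of a trajectory
#'
#' @param x a trajectory.
#' @param row.names,optional,... standard as.data.frame arguments (unused).
#' @return long data frame with columns \code{time}, \code{species},
#'   \code{value} (derived read-outs included).
#' @export
as.data.frame.trajectory <- function(x, row.names = NULL, optional = FALSE, ...) {
  m <- cbind(x$state, x$derived)
  data.frame(time = rep(x$times, ncol(m)),
             species = rep(colnames(m), each = length(x$times)),
             value = as.numeric(m))
}

#' Final state of a trajectory
#' @param traj a trajectory.
#' @return named numeric vector.
#' @export
final_state <- function(traj) {
  stats::setNames(as.numeric(traj$state[nrow(traj$state), ]),
                  colnames(traj$state))
}

#' Export a trajectory and its run manifest
#'
#' Writes the tidy CSV (\code{time, species, value}) and a JSON manifest
#' (model name, events applied, tolerances) reproducing the run.
#'
#' @param traj a trajectory.
#' @param csv_path path of the CSV file.
#' @param manifest_path optional path of a JSON manifest.
#' @export
write_trajectory <- function(traj, csv_path, manifest_path = NULL) {
  utils::write.csv(as.data.frame(traj), csv_path, row.names = FALSE)
  if (!is.null(manifest_path)) {
    manifest <- list(model = traj$model_name,
                     t_range = range(traj$times),
                     n_points = length(traj$times),
                     events_applied = traj$events_applied,
                     final_params = traj$final_params)
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(csv_path)
}

#' Long-horizon steady state of a circuit
#'
#' Integrates in geometrically growing chunks until the normalised
#' derivative norm \code{||dx/dt||_inf / (||x||_inf + 1)} falls below
#' \code{tol}, then (optionally) polishes the state with damped Newton
#' iterations on the RHS.  Gives up after \code{max_horizon} time units
#' (oscillatory attractors and similar non-convergence are reported with
#' \code{converged = FALSE}).
#'
#' @param model a \code{\link{circuit_model}}.
#' @param initial_state starting state (default: model default).
#' @param tol steady-state criterion on the normalised derivative norm.
#' @param max_horizon hard integration budget in model time units.
#' @param polish logical; Newton-polish the detected state.
#' @param rtol,atol integration tolerances.
#' @return list with \code{state}, \code{derived}, \code{converged},
#'   \code{residual} (normalised derivative norm) and \code{t_used}.
#' @export
steady_state <- function(model, initial_state = NULL, tol = 1e-9,
                         max_horizon = 1e6, polish = TRUE,
                         rtol = 1e-10, atol = 1e-12) {
  y <- initial_state %||% model$default_state
  y <- stats::setNames(as.numeric(y[model$states]), model$states)
  check_nonneg_state(y)
  resid <- function(y) {
    d <- model_rhs(model, 0, y)
    max(abs(d)) / (max(abs(y)) + 1)
  }
  t_used <- 0; chunk <- 50
  converged <- resid(y) < tol
  while (!converged && t_used < max_horizon) {
    chunk <- min(chunk * 2, max_horizon - t_used)
    sol <- deSolve::ode(y = y, times = c(0, chunk),
                        func = function(t, y, p) list(model_rhs(model, t, y, p)),
                        parms = model$params, method = "lsoda",
                        rtol = rtol, atol = atol, maxsteps = 100000L)
    y <- stats::setNames(as.numeric(utils::tail(sol, 1L)[1L, model$states]),
                         model$states)
    t_used <- t_used + chunk
    converged <- resid(y) < tol
  }
  if (converged && polish) {
    y_pol <- try(newton_root(function(s) model_rhs(model, 0, s), y),
                 silent = TRUE)
    if (!inherits(y_pol, "try-error") && all(is.finite(y_pol)) &&
        all(y_pol > -atol) && resid(pmax(y_pol, 0)) <= resid(y))
      y <- stats::setNames(pmax(as.numeric(y_pol), 0), model$states)
  }
  list(state = y, derived = model_derived(model, y),
       converged = converged, residual = resid(y), t_used = t_used)
}

## Damped Newton iteration with central-difference Jacobian.
newton_root <- function(f, x0, tol = 1e-13, maxit = 50L) {
  x <- x0
  fx <- f(x)
  for (i in seq_len(maxit)) {
    if (max(abs(fx)) < tol * (1 + max(abs(x)))) break
    J <- numeric_jacobian(f, x)
    step <- try(solve(J, fx), silent = TRUE)
    if (inherits(step, "try-error")) break
    lambda <- 1
    repeat {
      x_new <- x - lambda * step
      f_new <- try(f(x_new), silent = TRUE)
      if (!inherits(f_new, "try-error") && all(is.finite(f_new)) &&
          max(abs(f_new)) < max(abs(fx))) break
      lambda <- lambda / 2
      if (lambda < 1e-6) { x_new <- x; f_new <- fx; break }
    }
    if (identical(x_new, x)) break
    x <- x_new; fx <- f_new
  }
  x
}

## Central-difference Jacobian with step max(h0, h0 * |x_i|).
numeric_jacobian <- function(f, x, h0 = 1e-6) {
  n <- length(x)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    h <- max(h0, h0 * abs(x[[j]]))
    xp <- x; xm <- x
    xp[[j]] <- xp[[j]] + h
    xm[[j]] <- xm[[j]] - h
    J[, j] <- (f(xp) - f(xm)) / (2 * h)
  }
  dimnames(J) <- list(names(x), names(x))
  J
}
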