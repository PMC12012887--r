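## Equilibrium finding, local stability via linearization, and parametric
## stability-region scans.

#' Adaptation error
#'
#' Normalised post-perturbation deviation of a regulated steady state:
#' with d1 the pre-perturbation steady state and d2 the post-minus-pre
#' deviation, e_p = (d1 + d2)/d1 = post/pre.  Perfect adaptation gives
#' e_p = 1.
#'
#' @param pre_steady pre-perturbation steady value (> 0).
#' @param post_steady post-perturbation steady value.
#' @export
adaptation_error <- function(pre_steady, post_steady) {
  if (!is.numeric(pre_steady) || any(pre_steady <= 0))
    stop_input("pre_steady must be > 0")
  post_steady / pre_steady
}

#' Jacobian of a circuit model at a state
#'
#' Central finite differences with step \code{max(1e-6, 1e-6 |x_i|)}.
#'
#' @param model a \code{\link{circuit_model}}.
#' @param state named state vector.
#' @param params optional parameter override.
#' @export
circuit_jacobian <- function(model, state, params = model$params) {
  state <- stats::setNames(as.numeric(state[model$states]), model$states)
  numeric_jacobian(function(s) model_rhs(model, 0, s, params), state)
}

#' Local stability of an equilibrium
#'
#' Eigenvalues of the numerical Jacobian; stable iff the largest real
#' part is below \code{-margin}.  Eigenvalues with |Re| <= margin are
#' reported as marginal and excluded from "stable".  A warning with a
#' condition estimate is emitted for ill-conditioned Jacobians.
#'
#' @param model a \code{\link{circuit_model}}.
#' @param equilibrium named state vector (small RHS residual expected).
#' @param margin stability margin (default 1e-8).
#' @param params optional parameter override.
#' @return list with \code{stable}, \code{marginal}, \code{eigenvalues},
#'   \code{max_re}.
#' @export
local_stability <- function(model, equilibrium, margin = 1e-8,
                            params = model$params) {
  J <- circuit_jacobian(model, equilibrium, params)
  kappa <- tryCatch(kappa(J), error = function(e) Inf)
  if (!is.finite(kappa) || kappa > 1e12)
    warning(sprintf("ill-conditioned Jacobian (condition estimate %.3g)",
                    kappa))
  ev <- eigen(J, only.values = TRUE)$values
  mre <- max(Re(ev))
  list(stable = mre < -margin,
       marginal = abs(mre) <= margin,
       eigenvalues = ev, max_re = mre)
}

#' Find a strictly positive equilibrium
#'
#' Forward-integrates from the seed state until near-stationary, then
#' Newton-polishes the root of the RHS.  When several equilibria exist
#' the one reached by forward integration from the seed is returned (the
#' documented tie-break).  Positivity requires every coordinate above the
#' threshold.
#'
#' @param model a \code{\link{circuit_model}}.
#' @param seed_state starting state (default: model default).
#' @param positivity_threshold coordinates must exceed this for the
#'   equilibrium to count as strictly positive (default 1e-9).
#' @param margin stability margin passed to \code{\link{local_stability}}.
#' @param params optional parameter override.
#' @param max_horizon integration budget.
#' @return Object of class \code{equilibrium_report}: list with
#'   \code{state}, \code{found} (residual small), \code{positive},
#'   \code{stable}, \code{eigenvalues}, \code{residual}.
#' @export
find_positive_equilibrium <- function(model, seed_state = NULL,
                                      positivity_threshold = 1e-9,
                                      margin = 1e-8, params = model$params,
                                      max_horizon = 1e6) {
  m2 <- model
  m2$params <- params
  ss <- steady_state(m2, seed_state, tol = 1e-9, max_horizon = max_horizon)
  res_norm <- function(s) {
    d <- model_rhs(m2, 0, s)
    max(abs(d))
  }
  state <- ss$state
  found <- ss$converged && res_norm(state) < 1e-10 * (1 + max(abs(state)))
  positive <- all(state > positivity_threshold)
  stab <- if (found) local_stability(m2, state, margin = margin)
          else list(stable = NA, eigenvalues = complex(0), max_re = NA_real_)
  structure(list(state = state, found = found, positive = positive,
                 stable = stab$stable, eigenvalues = stab$eigenvalues,
                 max_re = stab$max_re, residual = res_norm(state),
                 converged = ss$converged),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("<equilibrium_report>\n")
  cat("  state:   ", paste(sprintf("%s = %.6g", names(x$state), x$state),
                           collapse = ", "), "\n")
  cat(sprintf("  found: %s  positive: %s  stable: %s  (max Re = %.3g)\n",
              x$found, x$positive, x$stable, x$max_re))
  invisible(x)
}

#' Two-parameter stability-region scan
#'
#' Evaluates, over a grid in two parameter directions, whether a strictly
#' positive stable equilibrium exists, optionally recording a set-point
#' contour (the value of one output coordinate at the equilibrium).
#' Per-cell failures are recorded as unstable/not-found, never aborting
#' the scan; the verdict grid is independent of traversal order.
#'
#' @param model a \code{\link{circuit_model}}.
#' @param axis1,axis2 dotted parameter paths.
#' @param grid1,grid2 numeric grids for the two axes.
#' @param seed_state seed for the equilibrium search (default model
#'   default state).
#' @param contour optional state name whose equilibrium value is recorded.
#' @param positivity_threshold,margin forwarded to the equilibrium search.
#' @param max_horizon per-cell integration budget.
#' @return Object of class \code{stability_map}: list with \code{axis1},
#'   \code{axis2}, \code{grid1}, \code{grid2}, logical matrix
#'   \code{stable}, matrix \code{setpoint} (NA where absent), and
#'   \code{failures} (data frame of cells whose evaluation errored).
#' @export
stability_region_scan <- function(model, axis1, axis2, grid1, grid2,
                                  seed_state = NULL, contour = NULL,
                                  positivity_threshold = 1e-9,
                                  margin = 1e-8, max_horizon = 2e4) {
  stopifnot(param_exists(model$params, axis1),
            param_exists(model$params, axis2))
  nv <- length(grid1); nh <- length(grid2)
  verdict <- matrix(FALSE, nv, nh)
  setp <- matrix(NA_real_, nv, nh)
  fails <- data.frame(i = integer(0), j = integer(0), message = character(0))
  for (i in seq_len(nv)) for (j in seq_len(nh)) {
    p <- param_set(model$params, axis1, grid1[[i]])
    p <- param_set(p, axis2, grid2[[j]])
    rep <- tryCatch(
      find_positive_equilibrium(model, seed_state, positivity_threshold,
                                margin, params = p,
                                max_horizon = max_horizon),
      error = function(e) e)
    if (inherits(rep, "error")) {
      fails <- rbind(fails, data.frame(i = i, j = j,
                                       message = conditionMessage(rep)))
      next
    }
    ok <- isTRUE(rep$found) && isTRUE(rep$positive) && isTRUE(rep$stable)
    verdict[i, j] <- ok
    if (ok && !is.null(contour)) setp[i, j] <- rep$state[[contour]]
  }
  structure(list(axis1 = axis1, axis2 = axis2, grid1 = grid1, grid2 = grid2,
                 stable = verdict, setpoint = setp, failures = fails),
            class = "stability_map")
}

#' @export
print.stability_map <- function(x, ...) {
  cat(sprintf("<stability_map>  %s x %s (%d x %d), %d stable cells\n",
              x$axis1, x$axis2, length(x$grid1), length(x$grid2),
              sum(x$stable)))
  invisible(x)
}

#' Export a stability map as CSV (+ JSON metadata)
#'
#' @param map a \code{stability_map}.
#' @param csv_path CSV destination (long format: axis values, verdict,
#'   contour value).
#' @param meta_path optional JSON metadata destination.
#' @export
write_stability_map <- function(map, csv_path, meta_path = NULL) {
  df <- expand.grid(a1 = map$grid1, a2 = map$grid2)
  names(df) <- c(map$axis1, map$axis2)
  df$stable <- as.vector(map$stable)
  df$setpoint <- as.vector(map$setpoint)
  utils::write.csv(df, csv_path, row.names = FALSE)
  if (!is.null(meta_path))
    jsonlite::write_json(list(axis1 = map$axis1, axis2 = map$axis2,
                              n1 = length(map$grid1), n2 = length(map$grid2),
                              n_stable = sum(map$stable),
                              failures = map$failures),
                         meta_path, auto_unbox = TRUE, digits = NA)
  invisible(csv_path)
}
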