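## Configuration schema, circuit template registry, presets and fixture
## generation -- the engineering shell around the model modules.

response_from_config <- function(x) {
  if (is.null(x)) return(response_fn("linear"))
  if (inherits(x, "response_fn")) return(x)
  do.call(response_fn, x)
}

pool_from_config <- function(x, id = "R") {
  resource_pool(x$pool_id %||% id, R_tot = x$R_tot, Q0 = x$Q0 %||% 0)
}

## Each template: defaults (nested parameter list), build(parameters) ->
## circuit_model, and sample_spec: paths sampled by generate_fixture with
## log-uniform ranges.
circuit_templates <- function() {
  list(
    minimal_motif = list(
      defaults = list(
        controller = list(alpha1_star = 0.1, sense_gain = 1, k_star = 0.2,
                          w_z1 = 10, w_bar_lin = 0.5, w_bar_quad = 0.05),
        plant = list(b_p1_star = 0.02, gamma_p1 = 2, w_x1 = 0),
        pool = list(R_tot = 100, Q0 = 0)),
      build = function(p)
        minimal_motif_circuit(do.call(minimal_motif_params, p$controller),
                              pool_from_config(p$pool),
                              do.call(gene_expression_plant, p$plant)),
      sample = list("controller.alpha1_star" = c(0.05, 0.5),
                    "controller.k_star" = c(0.1, 1),
                    "pool.R_tot" = c(20, 200))),
    layered_motif = list(
      defaults = list(
        controller = list(alpha1_star = 4, alpha2_star = 0.25,
                          gamma_c2 = 0.25, sense_gain = 1, k_star = 1,
                          w1 = 1, w2 = 1),
        plant = list(b_p1_star = 0.5, gamma_p1 = 0.5, w_x1 = 0),
        pool = list(R_tot = 100, Q0 = 1e-3)),
      build = function(p)
        layered_motif_circuit(do.call(layered_motif_params, p$controller),
                              pool_from_config(p$pool),
                              do.call(gene_expression_plant, p$plant)),
      sample = list("controller.alpha1_star" = c(0.5, 8),
                    "controller.alpha2_star" = c(0.05, 1),
                    "controller.sense_gain" = c(0.2, 4),
                    "controller.k_star" = c(0.2, 10),
                    "plant.gamma_p1" = c(0.2, 4),
                    "plant.b_p1_star" = c(0.05, 1),
                    "controller.w1" = c(0.2, 3),
                    "controller.w2" = c(0.2, 3),
                    "pool.R_tot" = c(20, 400))),
    embedded_gene_expression = list(
      defaults = list(
        controller = list(alpha1_star = 4, alpha2_star = 0.25,
                          gamma_c2 = 0.25, sense_gain = 1, k_star = 1,
                          w1 = 1, w2 = 1),
        plant = list(b_p1_star = 0.5, gamma_p1 = 0.5, w_x1 = 0),
        pool = list(R_tot = 100, Q0 = 1e-3),
        loads = list(L = 0, Q0_per_module = 1e-3)),
      build = function(p)
        embedded_circuit(do.call(gene_expression_plant, p$plant),
                         do.call(layered_motif_params, p$controller),
                         pool_from_config(p$pool),
                         do.call(external_loads, p$loads)),
      sample = list("controller.k_star" = c(0.2, 10),
                    "plant.gamma_p1" = c(0.2, 4),
                    "pool.R_tot" = c(20, 400))),
    ratiometric_motif = list(
      defaults = list(
        controller = list(alpha1_star = 1, alpha2_star = 1, theta1 = 1,
                          theta2 = 1, k1_star = 1, k2_star = 0,
                          gamma_c1 = 0, gamma_c2 = 0, w1 = 1, w2 = 1,
                          H1 = list(type = "linear", slope = 1),
                          H2 = list(type = "linear", slope = 1),
                          G1 = list(type = "linear", slope = 1),
                          G2 = list(type = "linear", slope = 1)),
        plant = list(b1_star = 0.1, b2_star = 1, gamma1 = 1, gamma2 = 1,
                     w_lin = 0.2),
        pool = list(R_tot = 100, Q0 = 1e-3)),
      build = function(p) {
        ctl <- p$controller
        for (nm in c("H1", "H2", "G1", "G2"))
          ctl[[nm]] <- response_from_config(ctl[[nm]])
        ratiometric_circuit(do.call(ratiometric_params, ctl),
                            pool_from_config(p$pool),
                            do.call(two_gene_plant, p$plant))
      },
      sample = list("controller.alpha1_star" = c(0.2, 3),
                    "controller.alpha2_star" = c(0.2, 3),
                    "controller.theta1" = c(0.2, 3),
                    "controller.theta2" = c(0.2, 3),
                    "plant.gamma1" = c(0.2, 3),
                    "plant.gamma2" = c(0.2, 3),
                    "plant.b2_star" = c(0.2, 3),
                    "controller.k1_star" = c(0.2, 3))),
    operon_ratio = list(
      defaults = list(
        op = list(T_star = 0.2, gamma_m = 1, eta1_star = 1, eta2_star = 1,
                  gamma_x1 = 2, gamma_x2 = 1, k_act = 0.5, gamma_m1 = 3,
                  eta_act = 12, alpha1_star = 1.44, alpha2_star = 0.16,
                  theta1 = 1, theta2 = 1, w11 = 0.5, w12 = 0.1,
                  w2P = 0.5, w2a = 0.5, w21 = 0.25, w22 = 1,
                  mrna_qss = FALSE),
        pool1 = list(R_tot = 100, Q0 = 1e-3),
        pool2 = list(R_tot = 100, Q0 = 1e-3)),
      build = function(p)
        operon_circuit(do.call(operon_params, p$op),
                       pool_from_config(p$pool1, "R1"),
                       pool_from_config(p$pool2, "R2")),
      sample = list("op.gamma_x2" = c(0.5, 4),
                    "op.T_star" = c(0.1, 0.5))),
    consortium = list(
      defaults = list(
        controller = list(mu1 = 0.8, theta1 = 1, rho_xn = 2, N_m = 1,
                          gamma = 0.1),
        plant = list(k = 1, gamma_p1 = 1)),
      build = function(p)
        consortium_circuit(do.call(consortium_params, p$controller),
                           do.call(consortium_plant, p$plant)),
      sample = list("controller.theta1" = c(0.3, 3),
                    "controller.rho_xn" = c(0.5, 5),
                    "controller.gamma" = c(0.02, 0.3),
                    "plant.k" = c(0.3, 3))),
    population_control = list(
      defaults = list(
        params = list(mu1 = 1.5, theta1 = 0.3, rho3 = 5, rho1 = 6,
                      sigma1 = 1, sigma3 = 1, delta1 = 3, delta3 = 3,
                      N_m = 1, N_m3 = 2, c13 = 1, c31 = 1, gamma = 0.05)),
      build = function(p)
        population_control_circuit(do.call(population_control_params,
                                           p$params)),
      sample = list("params.rho3" = c(2, 10),
                    "params.gamma" = c(0.02, 0.1))),
    coculture_ratio = list(
      defaults = list(
        params = list(rho1 = 5, rho2 = 5, rho3 = 4, rho4 = 16,
                      theta3 = 3, theta4 = 3,
                      sigma = c(1, 1, 1, 1), delta = c(3, 3, 4, 4),
                      N_m = 1, N_mp = 1, gamma = 0.025,
                      retentive_controller = TRUE)),
      build = function(p)
        coculture_circuit(do.call(coculture_params, p$params)),
      sample = list("params.rho4" = c(8, 32),
                    "params.gamma" = c(0.015, 0.04)))
  )
}

#' Available circuit templates
#' @return character vector of template names.
#' @export
list_templates <- function() names(circuit_templates())

get_template <- function(name) {
  tpl <- circuit_templates()[[name]]
  if (is.null(tpl))
    stop_input(sprintf("unknown circuit template '%s'; available: %s", name,
                       paste(list_templates(), collapse = ", ")))
  tpl
}

merge_params <- function(defaults, user, prefix = NULL, violations) {
  for (nm in names(user)) {
    path <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (!nm %in% names(defaults)) {
      violations$bad <- c(violations$bad, path)
      next
    }
    if (is.list(defaults[[nm]]) && !is.list(user[[nm]])) {
      violations$bad <- c(violations$bad,
                          sprintf("%s (expected a mapping)", path))
    } else if (is.list(defaults[[nm]])) {
      res <- merge_params(defaults[[nm]], user[[nm]], path, violations)
      defaults[[nm]] <- res$value
      violations <- res$violations
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  list(value = defaults, violations = violations)
}

config_fields <- c("circuit", "parameters", "initial_state", "horizon",
                   "n_out", "times", "events", "analysis", "seed")

#' Validate and normalise a run configuration
#'
#' Fills defaults from the circuit template and rejects unknown keys,
#' reporting every violation (not just the first).
#'
#' @param cfg named list (as read from YAML/JSON).
#' @return validated \code{run_config} object.
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$circuit)) stop_input("config must name a 'circuit' template")
  bad_top <- setdiff(names(cfg), config_fields)
  tpl <- get_template(cfg$circuit)
  res <- merge_params(tpl$defaults, cfg$parameters %||% list(),
                      violations = list(bad = character(0)))
  bad <- c(if (length(bad_top))
             sprintf("unknown top-level key '%s'", bad_top),
           if (length(res$violations$bad))
             sprintf("unknown parameter path '%s'", res$violations$bad))
  if (length(bad))
    stop_input("invalid configuration:\n  ",
               paste(bad, collapse = "\n  "))
  events <- lapply(cfg$events %||% list(), function(e)
    disturbance(e$time, e$parameter, e$action %||% "set", e$value))
  structure(list(circuit = cfg$circuit, parameters = res$value,
                 initial_state = cfg$initial_state %||% NULL,
                 horizon = cfg$horizon %||% 100,
                 n_out = cfg$n_out %||% 401L,
                 times = cfg$times %||% NULL,
                 events = events,
                 analysis = cfg$analysis %||% list(),
                 seed = cfg$seed %||% NULL),
            class = "run_config")
}

#' Load a run configuration from YAML (or JSON)
#'
#' @param path file path; parsed as YAML (JSON being a YAML subset, both
#'   work).
#' @return validated \code{run_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_input(sprintf("config file '%s' not found", path))
  as_run_config(yaml::read_yaml(path))
}

#' Write a run configuration to YAML
#'
#' The written file round-trips through \code{\link{load_config}} to an
#' identical configuration.
#'
#' @param config a \code{run_config}.
#' @param path destination path.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  x <- list(circuit = config$circuit, parameters = config$parameters,
            initial_state = config$initial_state, horizon = config$horizon,
            n_out = config$n_out, times = config$times,
            events = lapply(config$events, unclass),
            analysis = config$analysis, seed = config$seed)
  x <- x[!vapply(x, is.null, TRUE)]
  x <- x[!(names(x) %in% c("analysis")) | vapply(x, length, 0L) > 0]
  writeLines(yaml::as.yaml(x, precision = 17L), path)
  invisible(path)
}

#' Build the circuit model described by a configuration
#'
#' @param config a \code{run_config} (or path to one).
#' @return list with \code{model}, \code{initial_state}, \code{horizon},
#'   \code{events}, \code{times}, \code{n_out}.
#' @export
build_run <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "run_config"))
  tpl <- get_template(config$circuit)
  model <- tpl$build(config$parameters)
  init <- model$default_state
  for (nm in names(config$initial_state %||% list())) {
    if (!nm %in% names(init))
      stop_input(sprintf("initial_state names unknown species '%s'", nm))
    init[[nm]] <- config$initial_state[[nm]]
  }
  list(model = model, initial_state = init, horizon = config$horizon,
       events = config$events, times = config$times, n_out = config$n_out)
}

#' Run the simulation described by a configuration
#'
#' @param config a \code{run_config} or path.
#' @param ... forwarded to \code{\link{simulate_circuit}}.
#' @return a \code{trajectory}.
#' @export
run_config <- function(config, ...) {
  r <- build_run(config)
  simulate_circuit(r$model, r$initial_state, r$horizon, events = r$events,
                   times = r$times, n_out = r$n_out, ...)
}

#' Load a shipped circuit preset
#'
#' Presets reproduce the package's reference simulations (step response of
#' the layered motif, non-adapting minimal motif, embedded control under
#' load steps, consortium and coculture runs, ...).  Printed literature
#' values are used where available; remaining rates are the package's
#' documented defaults.
#'
#' @param name preset name, e.g. \code{"fig4c"}; see
#'   \code{list.files(system.file("extdata", "presets", package =
#'   "layeredIFC"))}.
#' @return validated \code{run_config}.
#' @export
load_preset <- function(name) {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "layeredIFC")
  if (path == "")
    stop_input(sprintf("no preset '%s'", name))
  load_config(path)
}

#' Generate a reproducible random parameterization
#'
#' Samples the template's documented parameter ranges log-uniformly under
#' a fixed seed, optionally rejecting draws violating constraints:
#' \describe{
#'   \item{feasible_layered}{both \code{\link{feasibility_conditions}}
#'     hold (layered/embedded templates).}
#'   \item{stable_layered}{feasible and \code{2 gamma_c2 <= gamma_p1}
#'     (enforced by resampling gamma_c2 below gamma_p1/2).}
#'   \item{stable}{a strictly positive, locally stable equilibrium exists
#'     numerically (any template).}
#' }
#'
#' @param template circuit template name.
#' @param seed integer seed.
#' @param constraints character vector of constraint names.
#' @param budget maximum number of rejection-sampling attempts.
#' @return \code{run_config} with attribute \code{"rejections"}.
#' @export
generate_fixture <- function(template, seed, constraints = character(0),
                             budget = 300L) {
  tpl <- get_template(template)
  known <- c("feasible_layered", "stable_layered", "stable")
  bad <- setdiff(constraints, known)
  if (length(bad))
    stop_input("unknown constraints: ", paste(bad, collapse = ", "))
  set.seed(as.integer(seed))
  layered_like <- template %in% c("layered_motif", "embedded_gene_expression")
  if (any(constraints %in% c("feasible_layered", "stable_layered")) &&
      !layered_like)
    stop_input("layered feasibility constraints apply to layered/embedded templates only")
  rejections <- 0L
  for (i in seq_len(budget)) {
    p <- tpl$defaults
    for (path in names(tpl$sample)) {
      rg <- tpl$sample[[path]]
      v <- exp(stats::runif(1, log(rg[[1L]]), log(rg[[2L]])))
      p <- param_set(p, path, v)
    }
    if ("stable_layered" %in% constraints)
      p <- param_set(p, "controller.gamma_c2",
                     stats::runif(1, 0.1, 1) * param_get(p, "plant.gamma_p1") / 2)
    ok <- TRUE
    if (layered_like &&
        any(constraints %in% c("feasible_layered", "stable_layered"))) {
      ctl <- do.call(layered_motif_params, p$controller)
      plant <- do.call(gene_expression_plant, p$plant)
      pool <- pool_from_config(p$pool)
      feas <- feasibility_conditions(plant, ctl, pool)
      ok <- all(feas)
      if (ok && "stable_layered" %in% constraints)
        ok <- stability_criterion(plant, ctl)
      if (ok) {
        eq <- embedded_equilibrium(plant, ctl, pool)
        ok <- all(eq > 0)
      }
    }
    if (ok && "stable" %in% constraints) {
      model <- tpl$build(p)
      rep <- tryCatch(find_positive_equilibrium(model, max_horizon = 2e4),
                      error = function(e) NULL)
      ok <- !is.null(rep) && isTRUE(rep$found) && isTRUE(rep$positive) &&
        isTRUE(rep$stable)
    }
    if (ok) {
      cfg <- as_run_config(list(circuit = template, parameters = p,
                                seed = as.integer(seed)))
      attr(cfg, "rejections") <- rejections
      return(cfg)
    }
    rejections <- rejections + 1L
  }
  stop_input(sprintf(
    "could not satisfy constraints within %d attempts (%d rejections)",
    budget, rejections))
}
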