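## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_input(sprintf("'%s' must be a finite numeric scalar", name))
  if (strict_lower && x <= lower)
    stop_input(sprintf("'%s' must be > %g (got %g)", name, lower, x))
  if (!strict_lower && x < lower)
    stop_input(sprintf("'%s' must be >= %g (got %g)", name, lower, x))
  if (x > upper)
    stop_input(sprintf("'%s' must be <= %g (got %g)", name, upper, x))
  invisible(x)
}

check_nonneg_state <- function(state) {
  if (any(!is.finite(state)))
    stop_input("state contains non-finite values")
  if (any(state < 0))
    stop_input("state must be componentwise non-negative; offending: ",
               paste(names(state)[state < 0], collapse = ", "))
  invisible(state)
}

## Get / set a parameter inside a nested list by a dotted path such as
## "controller.k_star" or a flat name such as "k_star".
param_get <- function(params, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- params
  for (k in keys) {
    if (!is.list(node) || is.null(node[[k]]))
      stop_input(sprintf("unknown parameter path '%s'", path))
    node <- node[[k]]
  }
  node
}

param_set <- function(params, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  set_rec <- function(node, keys) {
    k <- keys[[1L]]
    if (!is.list(node) || is.null(node[[k]]))
      stop_input(sprintf("unknown parameter path '%s'", path))
    if (length(keys) == 1L) node[[k]] <- value
    else node[[k]] <- set_rec(node[[k]], keys[-1L])
    node
  }
  set_rec(params, keys)
}

param_exists <- function(params, path) {
  ok <- TRUE
  tryCatch(param_get(params, path), error = function(e) ok <<- FALSE)
  ok
}

## Flatten a nested parameter list to dotted paths (used by config
## validation and fixtures).
param_paths <- function(params, prefix = NULL) {
  out <- character(0)
  for (nm in names(params)) {
    path <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    if (is.list(params[[nm]]))
      out <- c(out, param_paths(params[[nm]], path))
    else out <- c(out, path)
  }
  out
}
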